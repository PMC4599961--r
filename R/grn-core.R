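# Genotype -> phenotype map and phenotype-level comparisons.
#
# A genotype is an N x N real matrix W; w_ij is the regulatory effect of the
# product of gene j on the cis-regulation of gene i (positive = activation,
# negative = repression, zero = no interaction). Expression states live in
# [0,1]^N and evolve by the synchronous map S(t+1) = sigma(W (2 S(t) - 1))
# with sigma(x) = 1/(1 + exp(-a x)): the regulatory input is centered at the
# basal expression point 0.5, so sigma(-x) = 1 - sigma(x) makes the inverted
# state 1 - S* a steady state whenever S* is. The steady state reached (if
# any) is the phenotype; genes with an all-zero W row have no inputs and sit
# at the basal level sigma(0) = 0.5 exactly.

#' Dynamics parameters for the expression map
#'
#' @param gain Sigmoid steepness `a` in `sigma(x) = 1/(1+exp(-a*x))`. The
#'   default 20 makes converged non-basal expression levels effectively
#'   binary (within 0.01 of 0 or 1 for input magnitudes >= 0.25).
#' @param max_steps Maximum number of synchronous update steps.
#' @param conv_tol Convergence tolerance on the L-infinity step change.
#' @param conv_window Number of consecutive steps that must stay below
#'   `conv_tol` before the state is declared steady. Oscillators (limit
#'   cycles) therefore never converge and are treated as non-viable.
#' @return A list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(gain = 20, max_steps = 100L, conv_tol = 1e-4,
                            conv_window = 10L) {
  stopifnot(gain > 0, max_steps > 0, conv_tol > 0, conv_window > 0,
            conv_window < max_steps)
  structure(list(gain = gain, max_steps = as.integer(max_steps),
                 conv_tol = conv_tol, conv_window = as.integer(conv_window)),
            class = "dynamics_params")
}

validate_network <- function(W) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W))
    stop("a regulatory network must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(W)))
    stop("regulatory network contains non-finite entries", call. = FALSE)
  invisible(W)
}

#' Fraction of nonzero interactions in a network
#' @param W Square numeric matrix.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(W) {
  validate_network(W)
  mean(W != 0)
}

#' Genes with no regulatory inputs (all-zero W row)
#' @param W Square numeric matrix.
#' @return Logical vector of length N; `TRUE` marks basal genes. Self-loops
#'   count as inputs.
#' @export
basal_genes <- function(W) {
  validate_network(W)
  rowSums(W != 0) == 0
}

#' Develop a genotype to its phenotype
#'
#' Iterates `S(t+1) = sigma(W (2 S(t) - 1))` from the initial expression
#' state `s0` until the state is steady (see [dynamics_params()]) or
#' `max_steps` is exhausted.
#'
#' @param W Square numeric genotype matrix.
#' @param s0 Initial expression vector, entries in `[0, 1]`; length N.
#' @param params A [dynamics_params()] object.
#' @return A list of class `"grn_dev"` with elements `phenotype` (final state;
#'   only meaningful as a phenotype when `converged`), `converged`, `steps`,
#'   and `basal` (logical mask of input-free genes, which sit at exactly 0.5).
#' @examples
#' develop(matrix(0, 3, 3), c(1, 0, 1))  # all basal: phenotype (0.5, 0.5, 0.5)
#' @export
develop <- function(W, s0, params = dynamics_params()) {
  validate_network(W)
  if (length(s0) != nrow(W))
    stop("initial state length does not match network size", call. = FALSE)
  if (any(s0 < 0 | s0 > 1))
    stop("initial expression levels must lie in [0, 1]", call. = FALSE)
  r <- cpp_develop(W, as.numeric(s0), params$gain, params$max_steps,
                   params$conv_tol, params$conv_window, integer(0), numeric(0))
  structure(list(phenotype = if (r$converged) r$phenotype else NULL,
                 state = r$phenotype, converged = r$converged,
                 steps = r$steps, basal = basal_genes(W)),
            class = "grn_dev")
}

#' @export
print.grn_dev <- function(x, ...) {
  if (x$converged) {
    cat("steady state reached in", x$steps, "steps\n")
    cat("phenotype:", format(round(x$phenotype, 4)), "\n")
  } else {
    cat("no steady state within", x$steps, "steps (non-viable)\n")
  }
  if (any(x$basal)) cat("basal genes:", which(x$basal), "\n")
  invisible(x)
}

#' Distance between two expression vectors
#'
#' Three conventions are used at different sites of the model: the fitness
#' functions use the RMS form `sqrt(sum((x-y)^2)/N)`; environmental robustness
#' uses the mean absolute difference `sum(|x-y|)/N`; the phenotype-inversion
#' test uses the plain L1 sum.
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric One of `"rms"`, `"l1_mean"`, `"l1_sum"`.
#' @return Non-negative scalar.
#' @export
phenotype_distance <- function(x, y, metric = c("rms", "l1_mean", "l1_sum")) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    stop("expression vectors have different lengths", call. = FALSE)
  d <- x - y
  switch(metric,
         rms = sqrt(mean(d^2)),
         l1_mean = mean(abs(d)),
         l1_sum = sum(abs(d)))
}

#' Phenotype inversion test
#'
#' A mutant phenotype counts as an inversion of the reference when the L1
#' distance over the non-basal genes exceeds `p_flip * (N - Nb)`, where `Nb`
#' is the number of basal genes of the *reference* network. An all-basal
#' reference can never be inverted.
#'
#' @param ref,mut Converged [develop()] results of equal size.
#' @param p_flip Inversion threshold per non-basal gene, in `(0, 1]`.
#' @return Logical scalar.
#' @export
is_inversion <- function(ref, mut, p_flip = 0.9) {
  stopifnot(inherits(ref, "grn_dev"), inherits(mut, "grn_dev"))
  if (!ref$converged || !mut$converged)
    stop("inversion test requires two converged phenotypes", call. = FALSE)
  if (length(ref$phenotype) != length(mut$phenotype))
    stop("phenotypes have different lengths", call. = FALSE)
  stopifnot(p_flip > 0, p_flip <= 1)
  nb <- ref$basal
  n_active <- sum(!nb)
  if (n_active == 0L) return(FALSE)
  d <- sum(abs(ref$phenotype[!nb] - mut$phenotype[!nb]))
  d > p_flip * n_active
}

#' Host x parasite expression comparison
#'
#' Rescales both expression vectors from `[0,1]` to `[-1,+1]` and multiplies
#' gene-wise: negative values mean divergent expression (host "winning"),
#' positive values similar expression (parasite "winning"); basal genes (0.5)
#' map to 0.
#'
#' @param host,parasite Expression vectors of equal length.
#' @return Numeric vector in `[-1, 1]`.
#' @export
signed_product <- function(host, parasite) {
  if (length(host) != length(parasite))
    stop("expression vectors have different lengths", call. = FALSE)
  (2 * host - 1) * (2 * parasite - 1)
}

#' Binarize a phenotype at the 0.5 midpoint
#'
#' Basal genes (exactly 0.5, or within `na_band` of it) are returned as `NA`.
#' @param s Expression vector.
#' @param na_band Half-width of the indeterminate band around 0.5.
#' @return Integer vector of 0/1 with `NA` for indeterminate genes.
#' @export
binarize_phenotype <- function(s, na_band = 0.05) {
  out <- ifelse(s > 0.5 + na_band, 1L, ifelse(s < 0.5 - na_band, 0L, NA_integer_))
  as.integer(out)
}
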