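# Mutational sensitivity and robustness measurements.
#
# A (virtual) point mutation replaces one interaction w_ij by a value l drawn
# from N(0, sigma^2). The sensitivity score SS_ij is the Gaussian-weighted
# probability that such a mutation inverts the phenotype, estimated on a
# regular grid of candidate values l in [-L, L]:
#   SS_ij = sum_l delta * f(l) * k(l),
# with f the Gaussian density and k(l) = 1 iff w_ij -> l inverts the
# phenotype. The genotype-level SS is the mean of SS_ij over all N^2 entries.

#' Mutation-value grid for sensitivity scoring
#'
#' @param L Range bound; candidate values span `[-L, L]`.
#' @param delta Grid step.
#' @param sigma Standard deviation of the Gaussian mutation kernel.
#' @return A list of class `"sensitivity_grid"` with the grid `values` and
#'   per-point Gaussian `weights` (`delta * dnorm(l, 0, sigma)`). The default
#'   grid (L = 3, delta = 0.02, sigma = 1) has 301 points and total weight
#'   ~0.9973, the Gaussian mass within three standard deviations.
#' @export
sensitivity_grid <- function(L = 3, delta = 0.02, sigma = 1) {
  stopifnot(L > 0, delta > 0, sigma > 0)
  values <- seq(-L, L, by = delta)
  structure(list(L = L, delta = delta, sigma = sigma, values = values,
                 weights = delta * stats::dnorm(values, 0, sigma)),
            class = "sensitivity_grid")
}

#' Classify the phenotypic effect of a single mutation
#'
#' Develops the mutant obtained by setting `W[i, j] <- l` from the same `s0`
#' as the reference and classifies the outcome relative to the reference
#' phenotype (basal set taken from the reference network):
#' `"nonviable"` (no steady state), `"inversion"` (L1 over non-basal genes
#' exceeds `p_flip * (N - Nb)`), `"unchanged"` (L1 over non-basal genes at
#' most `same_tol * (N - Nb)`), else `"partial"`.
#'
#' @param W Genotype matrix (must itself develop to a steady state).
#' @param i,j Interaction indices (row = target gene, column = regulator).
#' @param l Mutant value for `w_ij`.
#' @param s0 Initial expression state.
#' @param p_flip Inversion threshold per non-basal gene.
#' @param same_tol "Unchanged" threshold per non-basal gene.
#' @param params [dynamics_params()].
#' @return One of `"inversion"`, `"unchanged"`, `"partial"`, `"nonviable"`.
#' @export
classify_mutation <- function(W, i, j, l, s0, p_flip = 0.9, same_tol = 0.1,
                              params = dynamics_params()) {
  validate_network(W)
  ref <- develop(W, s0, params)
  if (!ref$converged)
    stop("reference network does not reach a steady state", call. = FALSE)
  Wm <- W
  Wm[i, j] <- l
  mut <- develop(Wm, s0, params)
  if (!mut$converged) return("nonviable")
  nb <- ref$basal
  n_active <- sum(!nb)
  d <- if (n_active) sum(abs(ref$phenotype[!nb] - mut$phenotype[!nb])) else 0
  if (n_active > 0 && d > p_flip * n_active) return("inversion")
  if (d <= same_tol * n_active) return("unchanged")
  "partial"
}

#' Sensitivity score of a single interaction
#'
#' @inheritParams classify_mutation
#' @param grid A [sensitivity_grid()].
#' @return Scalar `SS_ij` in `[0, total grid mass]`.
#' @export
interaction_sensitivity <- function(W, i, j, s0, grid = sensitivity_grid(),
                                    p_flip = 0.9, same_tol = 0.1,
                                    params = dynamics_params()) {
  validate_network(W)
  m <- cpp_interaction_masses(W, as.numeric(s0), as.integer(i), as.integer(j),
                              params$gain, params$max_steps, params$conv_tol,
                              params$conv_window, grid$values, grid$weights,
                              p_flip, same_tol)
  m$inversion
}

#' Full sensitivity profile of a genotype
#'
#' Sweeps every interaction over the mutation grid and accumulates the
#' Gaussian-weighted mass of each outcome class per interaction.
#'
#' @inheritParams interaction_sensitivity
#' @return A list of class `"sensitivity_profile"`: `ss` (N x N matrix of
#'   `SS_ij`), `sensitive` (integer vector of linear indices with
#'   `SS_ij > 0`), `ss_total` (mean over all N^2 entries), `row_sums`
#'   (`SS_i`), `i_max` (row with maximal `SS_i`; 0 when no interaction is
#'   sensitive), `masses` (the four class-mass matrices), `n_basal`, and the
#'   reference `phenotype`.
#' @export
network_sensitivity <- function(W, s0, grid = sensitivity_grid(),
                                p_flip = 0.9, same_tol = 0.1,
                                params = dynamics_params()) {
  validate_network(W)
  m <- cpp_sensitivity_masses(W, as.numeric(s0), params$gain, params$max_steps,
                              params$conv_tol, params$conv_window,
                              grid$values, grid$weights, p_flip, same_tol)
  ss <- m$inversion
  rs <- rowSums(ss)
  structure(list(ss = ss,
                 sensitive = which(ss > 0),
                 ss_total = mean(ss),
                 row_sums = rs,
                 i_max = if (any(rs > 0)) which.max(rs) else 0L,
                 masses = m[c("inversion", "unchanged", "partial", "nonviable")],
                 n_basal = m$n_basal,
                 phenotype = m$phenotype,
                 grid = grid, p_flip = p_flip, same_tol = same_tol),
            class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat("sensitivity profile:", nrow(x$ss), "genes,",
      length(x$sensitive), "sensitive interactions, SS =",
      signif(x$ss_total, 4), "\n")
  invisible(x)
}

#' Mutational robustness of a genotype
#'
#' Gaussian-weighted fraction of non-inversion mutations that leave the
#' phenotype unchanged: mass(unchanged) / (mass(unchanged) + mass(partial)).
#' Non-viable mutants destroy the phenotype and count as changed by default.
#'
#' @inheritParams network_sensitivity
#' @param profile Optionally, a precomputed [network_sensitivity()] profile
#'   (avoids re-sweeping the grid).
#' @param nonviable How non-converging mutants enter the denominator:
#'   `"partial"` (default, counted as changed) or `"exclude"`.
#' @param weighting `"gaussian"` uses the grid's Gaussian masses; `"uniform"`
#'   counts grid points equally.
#' @return Robustness in `[0, 1]`; 1 by convention when no non-inversion
#'   mutations exist.
#' @export
mutational_robustness <- function(W, s0, grid = sensitivity_grid(),
                                  p_flip = 0.9, same_tol = 0.1,
                                  params = dynamics_params(), profile = NULL,
                                  nonviable = c("partial", "exclude"),
                                  weighting = c("gaussian", "uniform")) {
  nonviable <- match.arg(nonviable)
  weighting <- match.arg(weighting)
  if (is.null(profile)) {
    if (weighting == "uniform") {
      grid <- structure(c(grid[c("L", "delta", "sigma", "values")],
                          list(weights = rep(1, length(grid$values)))),
                        class = "sensitivity_grid")
    }
    profile <- network_sensitivity(W, s0, grid, p_flip, same_tol, params)
  }
  u <- sum(profile$masses$unchanged)
  p <- sum(profile$masses$partial)
  v <- sum(profile$masses$nonviable)
  den <- u + p + if (nonviable == "partial") v else 0
  if (den == 0) return(1)
  u / den
}

#' Environmental robustness of a genotype
#'
#' Perturbs the initial expression state `n_pert` times (each gene flipped
#' `s -> 1 - s` independently with probability `rate`), develops each
#' perturbed state, and averages the mean absolute phenotype distance to the
#' unperturbed phenotype. Perturbations that invert the phenotype or fail to
#' converge are excluded from the average. Larger values mean *less*
#' environmental robustness.
#'
#' @inheritParams network_sensitivity
#' @param rate Per-gene flip probability of the initial state.
#' @param n_pert Number of perturbed developments.
#' @return A list with `mean_distance`, `n_used`, `n_inversion`,
#'   `n_nonconverged`.
#' @export
environmental_robustness <- function(W, s0, rate = 0.01, n_pert = 500L,
                                     p_flip = 0.9, params = dynamics_params()) {
  validate_network(W)
  stopifnot(rate >= 0, rate <= 1, n_pert >= 1)
  cpp_env_robustness(W, as.numeric(s0), rate, as.integer(n_pert), params$gain,
                     params$max_steps, params$conv_tol, params$conv_window,
                     p_flip)
}
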