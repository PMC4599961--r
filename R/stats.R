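# Population- and lineage-level statistics: lability of sensitive
# interactions, nulls, diversity, dominance, modularity, alternating-phenotype
# detection, and the host-x-parasite "winning" matrix.

#' Jaccard index between two sensitive-interaction sets
#'
#' Sets are given as integer vectors of linear indices into the N^2 grid of
#' interactions (e.g. the `sensitive` field of a [network_sensitivity()]
#' profile). Two empty sets count as identical (J = 1, by convention).
#'
#' @param a,b Integer index vectors (duplicates ignored).
#' @return Jaccard index `|intersection| / |union|` in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap in sensitivity between an individual and its ancestors
#'
#' For each lag bucket, finds the closest ancestor (within a search window)
#' whose binarized phenotype equals that of the focal individual, and
#' measures the Jaccard overlap between the two sensitive-interaction sets.
#' The null overlap relocates both sets uniformly at random within the N^2
#' universe (preserving set sizes) `n_null` times.
#'
#' @param trace An asexual `coevo_trace`.
#' @param species `"host"` or `"parasite"`.
#' @param generation Focal generation.
#' @param index Focal individual.
#' @param interval Lag spacing between buckets (generations).
#' @param window Bucket search window: lags `interval*b - (0:(window-1))` are
#'   tried in order and the first same-phenotype ancestor is used.
#' @param n_buckets Number of lag buckets (default: as many as fit).
#' @param n_null Null-model replicates per bucket.
#' @return Data frame with `lag`, `jaccard`, `null_jaccard`, and the ancestor
#'   generation used; buckets with no same-phenotype ancestor are dropped.
#' @export
ancestor_overlap_curve <- function(trace, species = c("host", "parasite"),
                                   generation, index, interval = 100L,
                                   window = 10L, n_buckets = NULL,
                                   n_null = 100L) {
  species <- match.arg(species)
  cfg <- trace$config
  if (is.null(n_buckets)) n_buckets <- generation %/% interval
  lineage <- trace_lineage(trace, species, generation, index,
                           steps_back = min(generation,
                                            interval * n_buckets))
  s0 <- trace[[species]]$s0
  prof_of <- function(rec)
    network_sensitivity(rec$W, s0, cfg$grid, cfg$p_flip, cfg$same_tol,
                        cfg$dynamics)
  phen_key <- function(rec) {
    d <- develop(rec$W, s0, cfg$dynamics)
    if (!d$converged) return(NULL)
    paste(binarize_phenotype(d$phenotype), collapse = "")
  }
  focal <- lineage[[1L]]
  focal_prof <- prof_of(focal)
  focal_key <- phen_key(focal)
  out <- list()
  for (b in seq_len(n_buckets)) {
    hit <- NULL
    for (off in 0:(window - 1L)) {
      lag <- interval * b - off
      if (lag < 1 || lag + 1 > length(lineage)) next
      anc <- lineage[[lag + 1L]]
      if (identical(phen_key(anc), focal_key)) { hit <- list(anc, lag); break }
    }
    if (is.null(hit)) next
    anc_prof <- prof_of(hit[[1L]])
    jac <- jaccard_index(focal_prof$sensitive, anc_prof$sensitive)
    nn <- cfg$N^2
    ka <- length(focal_prof$sensitive); kb <- length(anc_prof$sensitive)
    nulls <- vapply(seq_len(n_null), function(r)
      jaccard_index(sample.int(nn, ka), sample.int(nn, kb)), numeric(1))
    out[[length(out) + 1L]] <-
      data.frame(lag = hit[[2L]], jaccard = jac,
                 null_jaccard = mean(nulls),
                 ancestor_generation = generation - hit[[2L]])
  }
  if (!length(out)) return(data.frame(lag = integer(0), jaccard = numeric(0),
                                      null_jaccard = numeric(0),
                                      ancestor_generation = integer(0)))
  do.call(rbind, out)
}

#' String-cutting (Dirichlet) null for the spread of sensitivity
#'
#' Generates `x` nonnegative numbers summing to `H` by cutting the interval
#' `(0, H)` at `x - 1` uniform points (the pieces are Dirichlet(1,...,1)
#' scaled by `H`) and returns the mean standard deviation of the pieces over
#' `n_rep` replicates. Used as the null spread against the observed SD of the
#' positive sensitivity scores of a network.
#'
#' @param x Number of pieces (sensitive interactions).
#' @param H Total (sum of their sensitivity scores).
#' @param n_rep Replicates.
#' @param sample_sd Use the n-1 denominator instead of the population SD.
#' @return Mean SD across replicates (0 when `x = 1`).
#' @export
sd_null_string_cutting <- function(x, H, n_rep = 100L, sample_sd = FALSE) {
  stopifnot(x >= 1, H > 0, n_rep >= 1)
  if (x == 1) return(0)
  one <- function() {
    pieces <- diff(c(0, sort(stats::runif(x - 1, 0, H)), H))
    if (sample_sd) stats::sd(pieces)
    else sqrt(mean((pieces - mean(pieces))^2))
  }
  mean(vapply(seq_len(n_rep), function(i) one(), numeric(1)))
}

#' Sign-simplified network diversity of a population
#'
#' Maps every genotype to its sign matrix (-1/0/+1) and counts the distinct
#' matrices as a fraction of the population size.
#'
#' @param pop A `coevo_population`, or a packed genome matrix (N^2 x M).
#' @return Diversity in `[1/M, 1]`.
#' @export
sign_diversity <- function(pop) {
  genomes <- if (inherits(pop, "coevo_population")) pop$genomes else pop
  keys <- apply(sign(genomes), 2, paste, collapse = "")
  length(unique(keys)) / ncol(genomes)
}

#' Row (or column) dominance of sensitivity across a population
#'
#' For each timepoint, assigns every sampled individual the row index with
#' maximal summed sensitivity `SS_i` (`0` when the individual has no
#' sensitive interaction), and calls a row *dominant* when more than half of
#' the sampled individuals share it.
#'
#' @param samples A list of timepoint samples; each element is a list with
#'   `generation` and `ss` (a list of N x N SS matrices). The `ss_samples`
#'   field of a `coevo_trace` has this shape (optionally filter by species).
#' @param margin `"row"` (cis-regulatory regions) or `"column"` (gene
#'   outputs).
#' @return List with `per_time` (data frame: generation, dominant row or 0,
#'   its frequency) and `rank_freq` (how often each row was dominant, in rank
#'   order, the share of timepoints with no dominant row listed as row 0).
#' @export
row_dominance <- function(samples, margin = c("row", "column")) {
  margin <- match.arg(margin)
  per_time <- lapply(samples, function(s) {
    imax <- vapply(s$ss, function(m) {
      sums <- if (margin == "row") rowSums(m) else colSums(m)
      if (any(sums > 0)) which.max(sums) else 0L
    }, integer(1))
    tab <- table(imax)
    top <- names(tab)[which.max(tab)]
    n <- length(imax)
    dom <- tab[top] > n / 2 && top != "0"
    data.frame(generation = s$generation,
               dominant = if (dom) as.integer(top) else 0L,
               top_row = as.integer(top),
               top_frequency = as.numeric(tab[top]) / n)
  })
  per_time <- do.call(rbind, per_time)
  freq <- table(factor(per_time$dominant))
  rank_freq <- data.frame(row = as.integer(names(freq)),
                          frequency = as.numeric(freq) / nrow(per_time))
  rank_freq <- rank_freq[order(-rank_freq$frequency, rank_freq$row), ]
  rank_freq$rank <- seq_len(nrow(rank_freq))
  list(per_time = per_time, rank_freq = rank_freq)
}

# --- modularity ------------------------------------------------------------

#' Undirected interaction graph of a network
#'
#' Vertices are genes; an (undirected, unweighted) edge joins i and j
#' (i != j) whenever either directed interaction w_ij or w_ji is nonzero.
#' Self-loops are dropped.
#'
#' @param W Genotype matrix.
#' @return Symmetric logical adjacency matrix with zero diagonal.
#' @export
interaction_graph <- function(W) {
  validate_network(W)
  A <- (W != 0) | (t(W) != 0)
  diag(A) <- FALSE
  A
}

#' Newman modularity of a vertex partition
#'
#' `Q(C) = sum_i [ |E(C_i)|/l - (sum_{v in C_i} deg(v) / (2l))^2 ]` over the
#' clusters `C_i`, where `l` is the number of edges, `|E(C_i)|` the number of
#' within-cluster edges and `deg` the vertex degree. The one-block partition
#' scores exactly 0 for any graph.
#'
#' @param A Adjacency matrix (as from [interaction_graph()]) or a genotype
#'   matrix (coerced via [interaction_graph()] if not symmetric logical).
#' @param membership Integer cluster labels, one per vertex.
#' @return Modularity Q.
#' @export
modularity_q <- function(A, membership) {
  if (!is.logical(A)) A <- interaction_graph(A)
  stopifnot(isSymmetric(unname(A * 1)), length(membership) == nrow(A))
  l <- sum(A) / 2
  if (l < 1) stop("modularity is undefined for an empty edge set", call. = FALSE)
  deg <- rowSums(A)
  q <- 0
  for (cl in unique(membership)) {
    v <- membership == cl
    e_in <- sum(A[v, v, drop = FALSE]) / 2
    q <- q + e_in / l - (sum(deg[v]) / (2 * l))^2
  }
  q
}

#' Modularity-maximizing partition (greedy + refinement)
#'
#' Deterministic greedy agglomeration from singletons (always merging the
#' pair with the largest positive gain, ties broken by lowest cluster
#' indices), followed by single-vertex relocation passes until no move
#' improves Q. Never returns a partition worse than the one-block partition
#' (Q = 0).
#'
#' @param A Adjacency or genotype matrix (see [modularity_q()]).
#' @return List with `membership` (labels 1..k) and `q`.
#' @export
best_partition <- function(A) {
  if (!is.logical(A)) A <- interaction_graph(A)
  n <- nrow(A)
  l <- sum(A) / 2
  if (l < 1) stop("modularity is undefined for an empty edge set", call. = FALSE)
  memb <- seq_len(n)
  q <- modularity_q(A, memb)
  # greedy agglomeration
  repeat {
    labs <- sort(unique(memb))
    best <- list(gain = 1e-12, pair = NULL)
    for (ai in seq_along(labs)) for (bi in seq_along(labs)) {
      if (bi <= ai) next
      cand <- memb
      cand[cand == labs[bi]] <- labs[ai]
      gain <- modularity_q(A, cand) - q
      if (gain > best$gain) best <- list(gain = gain, pair = c(ai, bi))
    }
    if (is.null(best$pair)) break
    memb[memb == labs[best$pair[2]]] <- labs[best$pair[1]]
    q <- q + best$gain
  }
  # single-vertex relocation
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      targets <- setdiff(sort(unique(memb)), memb[v])
      for (tg in targets) {
        cand <- memb
        cand[v] <- tg
        qc <- modularity_q(A, cand)
        if (qc > q + 1e-12) {
          memb <- cand; q <- qc; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  if (q < 0) {  # never worse than the trivial one-block partition
    memb <- rep(1L, n)
    q <- 0
  }
  list(membership = as.integer(factor(memb)), q = q)
}

# --- alternating-phenotype detection ---------------------------------------

# Internal: binarize per-generation modal (population-mean) expression;
# genes near 0.5 (basal or mid-sweep) become NA.
binarize_modal <- function(mean_expr, na_band = 0.1) {
  bin <- matrix(NA_integer_, nrow(mean_expr), ncol(mean_expr))
  bin[mean_expr > 0.5 + na_band] <- 1L
  bin[mean_expr < 0.5 - na_band] <- 0L
  bin
}

# fraction of (jointly determinate) genes agreeing between two binary states;
# NA when fewer than half the genes are comparable
state_agreement <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < length(a) / 2) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Detect the alternating-phenotype strategy in a trace
#'
#' The alternating strategy shows up as *rapid, repeated phenotype
#' inversions*: the binarized modal (population-mean) phenotype jumps to its
#' near-complement within a few generations, stays on a stable plateau, and
#' jumps back. Gradual drift also turns phenotypes over, but never flips
#' most genes within a short window, and is not counted. A trace is
#' alternating when *both* species show at least `min_cycles` rapid
#' inversions, each departing from a plateau that still resembles the
#' previous inversion's endpoint (the two-state structure P, 1-P).
#'
#' @param trace A `coevo_trace`.
#' @param min_cycles Minimum number of rapid inversions per species.
#' @param flip_window Maximum number of generations a jump may take.
#' @param flip_tol Maximum fraction of (determinate) genes still agreeing
#'   after a jump for it to count as an inversion.
#' @param assign_tol Minimum agreement between one inversion's endpoint and
#'   the next inversion's start (plateau stability).
#' @return List with `alternating` (logical) and `onset` (generation at which
#'   the qualifying inversions start, maximized over species; `NA` if not
#'   alternating).
#' @export
detect_alternating <- function(trace, min_cycles = 3L, flip_window = 5L,
                               flip_tol = 0.1, assign_tol = 0.8) {
  G <- trace$generations
  if (G < 2) return(list(alternating = FALSE, onset = NA_integer_))
  events_for <- function(mean_expr) {
    bin <- binarize_modal(mean_expr)
    events <- list()
    t <- 1L
    last_end_state <- NULL
    while (t < G) {
      hit <- 0L
      for (k in seq_len(min(flip_window, G - t))) {
        ag <- state_agreement(bin[t, ], bin[t + k, ])
        if (!is.na(ag) && ag <= flip_tol) { hit <- k; break }
      }
      if (hit > 0L) {
        stable <- if (is.null(last_end_state)) TRUE else {
          ag0 <- state_agreement(last_end_state, bin[t, ])
          !is.na(ag0) && ag0 >= assign_tol
        }
        if (stable) {
          events[[length(events) + 1L]] <- c(start = t, end = t + hit)
          last_end_state <- bin[t + hit, ]
        }
        t <- t + hit
      } else {
        t <- t + 1L
      }
    }
    events
  }
  eh <- events_for(trace$host$mean_expr)
  ep <- events_for(trace$parasite$mean_expr)
  if (length(eh) >= min_cycles && length(ep) >= min_cycles)
    list(alternating = TRUE,
         onset = max(eh[[1L]]["start"], ep[[1L]]["start"]),
         n_inversions = c(host = length(eh), parasite = length(ep)))
  else
    list(alternating = FALSE, onset = NA_integer_,
         n_inversions = c(host = length(eh), parasite = length(ep)))
}

#' Host x parasite "winning" matrix
#'
#' For each generation, pairs hosts and parasites at random and multiplies
#' their rescaled (`[0,1] -> [-1,1]`) gene expressions: negative entries mean
#' divergent expression (host winning, blue in the usual rendering), positive
#' entries similar expression (parasite winning, yellow). Columns are
#' gene-major: the first `n_pairs` columns are gene 1 across all pairs, and
#' so on.
#'
#' @param trace A `coevo_trace` with stored phenotypes
#'   (`store_phenotypes = TRUE`).
#' @param n_pairs Number of host-parasite pairs per generation (default: as
#'   many as both populations allow).
#' @return `generations x (N * n_pairs)` numeric matrix in `[-1, 1]`.
#' @export
winning_matrix <- function(trace, n_pairs = NULL) {
  if (is.null(trace$host$phen))
    stop("trace was run without store_phenotypes = TRUE", call. = FALSE)
  N <- trace$config$N
  G <- trace$generations
  if (is.null(n_pairs))
    n_pairs <- min(trace$config$M_host, trace$config$M_parasite)
  out <- matrix(NA_real_, G, N * n_pairs)
  for (g in seq_len(G)) {
    hp <- trace$host$phen[[g]]
    pp <- trace$parasite$phen[[g]]
    hi <- sample.int(ncol(hp), n_pairs)
    pi <- sample.int(ncol(pp), n_pairs)
    prod <- (2 * hp[, hi, drop = FALSE] - 1) * (2 * pp[, pi, drop = FALSE] - 1)
    out[g, ] <- as.numeric(t(prod))  # gene-major blocks
  }
  out
}
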