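# Pure-R reference implementations, independent of the package's C++ path.
# Used as oracles in the unit and property tests.

r_sigmoid <- function(x, a) 1 / (1 + exp(-a * x))

# reference development: plain R iteration of S(t+1) = sigma(W (2S - 1))
r_develop <- function(W, s0, a = 20, max_steps = 100, tol = 1e-4, window = 10) {
  s <- as.numeric(s0)
  run <- 0
  for (t in seq_len(max_steps)) {
    snew <- r_sigmoid(as.numeric(W %*% (2 * s - 1)), a)
    run <- if (max(abs(snew - s)) < tol) run + 1 else 0
    s <- snew
    if (run >= window) return(list(phenotype = s, converged = TRUE, steps = t))
  }
  list(phenotype = s, converged = FALSE, steps = max_steps)
}

# brute-force classification of a single mutation, mirroring the definitions
# (not the package code): develop mutant, compare to reference over non-basal
# genes of the reference network
r_classify <- function(W, i, j, l, s0, p_flip = 0.9, same_tol = 0.1, a = 20) {
  ref <- r_develop(W, s0, a)
  stopifnot(ref$converged)
  basal <- rowSums(W != 0) == 0
  Wm <- W
  Wm[i, j] <- l
  mut <- r_develop(Wm, s0, a)
  if (!mut$converged) return("nonviable")
  n_active <- sum(!basal)
  d <- if (n_active) sum(abs(ref$phenotype[!basal] - mut$phenotype[!basal])) else 0
  if (n_active > 0 && d > p_flip * n_active) return("inversion")
  if (d <= same_tol * n_active) return("unchanged")
  "partial"
}

# brute-force grid sweep: per-class Gaussian masses for a whole network
r_masses <- function(W, s0, grid_values, grid_weights, p_flip = 0.9,
                     same_tol = 0.1, a = 20) {
  N <- nrow(W)
  out <- list(inversion = matrix(0, N, N), unchanged = matrix(0, N, N),
              partial = matrix(0, N, N), nonviable = matrix(0, N, N))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    for (g in seq_along(grid_values)) {
      cls <- r_classify(W, i, j, grid_values[g], s0, p_flip, same_tol, a)
      out[[cls]][i, j] <- out[[cls]][i, j] + grid_weights[g]
    }
  }
  out
}

# exhaustive modularity maximization over all set partitions (n <= 8)
r_best_partition_exhaustive <- function(A) {
  n <- nrow(A)
  parts <- list(list(1L))
  for (v in 2:n) {
    grown <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], v)
        grown[[length(grown) + 1L]] <- q
      }
      grown[[length(grown) + 1L]] <- c(p, list(v))
    }
    parts <- grown
  }
  best <- -Inf
  best_m <- NULL
  for (p in parts) {
    memb <- integer(n)
    for (b in seq_along(p)) memb[p[[b]]] <- b
    q <- modularity_q(A, memb)
    if (q > best) { best <- q; best_m <- memb }
  }
  list(q = best, membership = best_m)
}

# small default-parameter coevolution run shared by several tests
small_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- coevo_config(N = 6L, M = 40L, generations = 60L, seed = 42L,
                          ss_every = 0L, diversity_every = 10L)
      cache <<- run_coevolution(cfg)
    }
    cache
  }
})
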