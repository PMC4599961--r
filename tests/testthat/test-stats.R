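# Jaccard lability, nulls, diversity, dominance, modularity, detection.

test_that("jaccard index identities", {
  expect_equal(jaccard_index(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_equal(jaccard_index(1, c(1, 2, 3)), 1 / 3)
  expect_equal(jaccard_index(integer(0), integer(0)), 1)  # empty-set convention
  # symmetry and monotonicity under removing shared elements
  set.seed(8)
  for (k in 1:20) {
    a <- sample(100, 12); b <- sample(100, 20)
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    shared <- intersect(a, b)
    if (length(shared))
      expect_lte(jaccard_index(setdiff(a, shared[1]), b), jaccard_index(a, b))
  }
})

test_that("random-relocation null matches a brute-force placement oracle", {
  # null mean J for independently placed sets of sizes ka, kb in universe 100
  set.seed(14)
  ka <- 8; kb <- 12; U <- 100
  sim <- replicate(4000, jaccard_index(sample.int(U, ka), sample.int(U, kb)))
  # brute-force oracle over the hypergeometric intersection distribution
  k <- 0:ka
  pk <- dhyper(k, ka, U - ka, kb)
  oracle <- sum(pk * k / (ka + kb - k))
  expect_lt(abs(mean(sim) - oracle), 3 * sd(sim) / sqrt(4000))
})

test_that("string-cutting null: conservation, x = 1, and the x = 2 mean SD", {
  expect_equal(sd_null_string_cutting(1, 5), 0)
  set.seed(15)
  # pieces sum to H exactly
  for (k in 1:20) {
    x <- sample(2:8, 1); H <- runif(1, 0.5, 4)
    pieces <- diff(c(0, sort(runif(x - 1, 0, H)), H))
    expect_equal(sum(pieces), H, tolerance = 1e-12)
    expect_true(all(pieces >= 0))
  }
  # x = 2, H = 1: population SD of (U, 1-U) is |U - 1/2|, mean 1/4
  set.seed(16)
  m <- sd_null_string_cutting(2, 1, n_rep = 4000)
  expect_lt(abs(m - 0.25), 0.01)
  # sample-SD flag scales by sqrt(2) for x = 2
  set.seed(16)
  m2 <- sd_null_string_cutting(2, 1, n_rep = 4000, sample_sd = TRUE)
  expect_equal(m2 / m, sqrt(2), tolerance = 1e-9)
})

test_that("sign diversity counts distinct sign matrices as a fraction", {
  g <- cbind(c(1, -2, 0, 3), c(2, -1, 0, 5), c(-1, 2, 0, 3))
  # columns 1 and 2 share the sign pattern (+,-,0,+)
  expect_equal(sign_diversity(g), 2 / 3)
  expect_equal(sign_diversity(cbind(g[, 1], g[, 1] * 2)), 1 / 2)  # scalar invariance
  cfg <- coevo_config(M = 10L, generations = 0L)
  set.seed(18)
  pop <- found_population(cfg, "host")
  expect_equal(sign_diversity(pop), 1 / 10)  # clonal population
})

test_that("row dominance flags rows shared by more than half the sample", {
  mk <- function(imax_rows, N = 4) lapply(imax_rows, function(r) {
    m <- matrix(0, N, N)
    if (r > 0) m[r, 1] <- 0.5
    m
  })
  s1 <- list(generation = 50, ss = mk(c(3, 3, 3, 2, 0)))   # 3/5 share row 3
  s2 <- list(generation = 100, ss = mk(c(1, 2, 3, 4, 0)))  # no dominant row
  out <- row_dominance(list(s1, s2))
  expect_equal(out$per_time$dominant, c(3L, 0L))
  expect_equal(out$per_time$top_frequency[1], 3 / 5)
  expect_setequal(out$rank_freq$row, c(3L, 0L))
  # exactly half is not dominant
  s3 <- list(generation = 1, ss = mk(c(2, 2, 1, 3)))
  expect_equal(row_dominance(list(s3))$per_time$dominant, 0L)
  # column margin uses column sums
  m <- matrix(0, 4, 4); m[1, 4] <- 1
  s4 <- list(generation = 1, ss = list(m, m, m))
  expect_equal(row_dominance(list(s4), margin = "column")$per_time$dominant, 4L)
})

test_that("modularity formula on known partitions", {
  A <- interaction_graph(make_fixture("two_triangle_graph")$W)
  expect_equal(modularity_q(A, rep(1L, 6)), 0)            # one block: exactly 0
  expect_equal(modularity_q(A, c(1, 1, 1, 2, 2, 2)), 0.5) # the two triangles
  # singleton partition of a clique is negative
  K <- matrix(TRUE, 5, 5); diag(K) <- FALSE
  expect_lt(modularity_q(K, 1:5), 0)
  expect_error(modularity_q(matrix(FALSE, 3, 3), c(1, 2, 3)), "empty edge")
  # agreement with the reference graph-library implementation
  skip_if_not_installed("igraph")
  set.seed(19)
  for (k in 1:10) {
    W <- random_network(7, 0.4)
    A <- interaction_graph(W)
    if (sum(A) == 0) next
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    memb <- sample(1:3, 7, replace = TRUE)
    expect_equal(modularity_q(A, memb), igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("greedy partition matches exhaustive search on small graphs", {
  A <- interaction_graph(make_fixture("two_triangle_graph")$W)
  bp <- best_partition(A)
  expect_equal(bp$q, 0.5)
  expect_equal(length(unique(bp$membership)), 2)
  # complete graph: no community structure, best Q = 0
  K <- matrix(TRUE, 6, 6); diag(K) <- FALSE
  expect_equal(best_partition(K)$q, 0)
  set.seed(23)
  for (k in 1:5) {
    W <- random_network(6, 0.4)
    A <- interaction_graph(W)
    if (sum(A) == 0) next
    bp <- best_partition(A)
    ex <- r_best_partition_exhaustive(A)
    expect_equal(bp$q, ex$q, tolerance = 1e-9)
    expect_gte(bp$q, 0)  # never worse than the one-block partition
  }
})

test_that("alternating detector separates synthetic alternation from drift", {
  cfg <- coevo_config(N = 6L, M = 10L, generations = 0L)
  # synthetic trace: clean period-10 alternation in both species
  P <- c(1, 0, 1, 0, 1, 0)
  me <- t(sapply(1:200, function(g) if ((g %/% 10) %% 2 == 0) P else 1 - P))
  tr <- structure(list(config = cfg, generations = 200L,
                       host = list(mean_expr = me),
                       parasite = list(mean_expr = me)),
                  class = "coevo_trace")
  d <- detect_alternating(tr)
  expect_true(d$alternating)
  expect_gte(d$n_inversions[["host"]], 3)
  # constant phenotype: never alternating
  trc <- tr; trc$host$mean_expr <- matrix(rep(P, each = 200), 200)
  expect_false(detect_alternating(trc)$alternating)
  # gradual drift (one gene turning over every 15 generations) is not counted
  drift <- me
  for (g in 1:200) drift[g, ] <- as.numeric(1:6 <= (g %/% 15) %% 7)
  trd <- tr; trd$host$mean_expr <- drift; trd$parasite$mean_expr <- drift
  expect_false(detect_alternating(trd)$alternating)
})

test_that("winning matrix encodes per-gene battle outcomes", {
  cfg <- coevo_config(N = 3L, M = 4L, generations = 0L)
  phenH <- matrix(c(1, 0, 0.5), 3, 4)
  phenP <- matrix(c(1, 1, 0.5), 3, 4)
  tr <- structure(list(config = cfg, generations = 2L,
                       host = list(phen = list(phenH, phenH)),
                       parasite = list(phen = list(phenP, phenP))),
                  class = "coevo_trace")
  set.seed(30)
  wm <- winning_matrix(tr, n_pairs = 4)
  expect_equal(dim(wm), c(2L, 12L))
  expect_equal(unname(wm[1, 1:4]), rep(1, 4))    # gene 1 equal: parasite wins
  expect_equal(unname(wm[1, 5:8]), rep(-1, 4))   # gene 2 opposite: host wins
  expect_equal(unname(wm[1, 9:12]), rep(0, 4))   # basal gene: neutral
})

test_that("ancestor overlap decays from self-identity toward the null", {
  tr <- small_trace()
  curve <- ancestor_overlap_curve(tr, "host", generation = 60, index = 1,
                                  interval = 15, window = 5, n_null = 30)
  if (nrow(curve) > 0) {
    expect_true(all(curve$jaccard >= 0 & curve$jaccard <= 1))
    expect_true(all(curve$null_jaccard >= 0 & curve$null_jaccard <= 1))
    expect_true(all(curve$ancestor_generation < 60))
  }
  # lag zero is self-comparison: J = 1 by construction
  prof <- network_sensitivity(get_network(tr$final$host, 1), tr$host$s0,
                              tr$config$grid)
  expect_equal(jaccard_index(prof$sensitive, prof$sensitive), 1)
})
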