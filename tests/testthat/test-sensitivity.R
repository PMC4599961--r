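# Sensitivity scores, robustness, environmental robustness.

# 2-gene switch with an analytically known sensitivity: gene 1 locks itself ON,
# gene 2 follows w21 alone, so mutating w21 -> l gives s2 = sigma(a * l) and
# the inversion set on the grid is exactly {l < log(1/9)/a} for p_flip = 0.45.
switch_net <- function(t = 2) {
  W <- matrix(0, 2, 2)
  W[1, 1] <- 5
  W[2, 1] <- t
  W
}

test_that("sensitivity grid carries the truncated Gaussian mass", {
  g <- sensitivity_grid()
  expect_length(g$values, 301)
  expect_equal(sum(g$weights), 0.9973, tolerance = 5e-4)
  g2 <- sensitivity_grid(L = 2, delta = 0.1, sigma = 0.5)
  expect_length(g2$values, 2 * 2 / 0.1 + 1)
})

test_that("classify_mutation covers all four outcome classes", {
  W <- switch_net()
  s0 <- c(1, 1)
  expect_equal(classify_mutation(W, 2, 1, 2, s0), "unchanged")   # no-op value
  expect_equal(classify_mutation(W, 2, 1, -2, s0, p_flip = 0.45), "inversion")
  expect_equal(classify_mutation(W, 2, 1, 0.02, s0), "partial")  # s2 drifts mid-range
  # a strong negative self-loop on the driver creates a limit cycle
  expect_equal(classify_mutation(W, 1, 1, -5, s0), "nonviable")
})

test_that("classification agrees with the pure-R oracle on random networks", {
  set.seed(33)
  done <- 0
  while (done < 30) {
    W <- random_network(5, 0.6)
    s0 <- as.numeric(runif(5) < 0.5)
    if (!develop(W, s0)$converged) next
    i <- sample(5, 1); j <- sample(5, 1); l <- rnorm(1)
    expect_identical(classify_mutation(W, i, j, l, s0),
                     r_classify(W, i, j, l, s0))
    done <- done + 1
  }
})

test_that("interaction sensitivity matches the Gaussian-CDF oracle", {
  W <- switch_net()
  s0 <- c(1, 1)
  ss <- interaction_sensitivity(W, 2, 1, s0, p_flip = 0.45)
  cutoff <- log(1 / 9) / 20  # sigma(20 l) = 0.1
  expect_equal(ss, pnorm(cutoff), tolerance = 0.01)
  # grid refinement moves the estimate by less than one coarse cell's mass
  ss_coarse <- interaction_sensitivity(W, 2, 1, s0, p_flip = 0.45,
                                       grid = sensitivity_grid(delta = 0.04))
  expect_lt(abs(ss - ss_coarse), 0.02)
})

test_that("network sensitivity: zero matrix scores zero, founders near zero", {
  prof0 <- network_sensitivity(matrix(0, 5, 5), rep(1, 5))
  expect_equal(prof0$ss_total, 0)
  expect_length(prof0$sensitive, 0)
  expect_identical(prof0$i_max, 0L)
  # random founders carry negligible sensitivity
  set.seed(11)
  ss <- c()
  for (k in 1:20) {
    f <- list(W = random_network(10, 0.5), s0 = as.numeric(runif(10) < 0.5))
    if (!develop(f$W, f$s0)$converged) next
    ss <- c(ss, network_sensitivity(f$W, f$s0)$ss_total)
  }
  expect_lt(mean(ss), 0.03)  # negligible next to the evolved plateau ~0.09
})

test_that("SS is bounded by the truncated mass and equals the SS_ij mean", {
  f <- make_fixture("founder")
  prof <- network_sensitivity(f$W, f$s0)
  expect_true(all(prof$ss >= 0))
  expect_true(all(prof$ss <= sum(prof$grid$weights) + 1e-12))
  expect_equal(prof$ss_total, mean(prof$ss))
  expect_equal(prof$row_sums, rowSums(prof$ss))
})

test_that("the four class masses conserve the total grid mass", {
  f <- make_fixture("founder")
  prof <- network_sensitivity(f$W, f$s0)
  total <- Reduce(`+`, prof$masses)
  expect_equal(max(abs(total - sum(prof$grid$weights))), 0, tolerance = 1e-9)
})

test_that("robustness equals brute-force enumeration on 3-gene networks", {
  set.seed(77)
  grid <- sensitivity_grid(delta = 0.25)
  done <- 0
  while (done < 5) {
    W <- random_network(3, 0.7)
    s0 <- as.numeric(runif(3) < 0.5)
    if (!develop(W, s0)$converged) next
    rob <- mutational_robustness(W, s0, grid = grid)
    oracle <- r_masses(W, s0, grid$values, grid$weights)
    u <- sum(oracle$unchanged); p <- sum(oracle$partial); v <- sum(oracle$nonviable)
    expect_equal(rob, if (u + p + v == 0) 1 else u / (u + p + v),
                 tolerance = 1e-10)
    done <- done + 1
  }
})

test_that("robustness extremes and conventions", {
  # all-basal network: every viable mutant leaves the (empty) non-basal set
  # alone; some single-interaction mutants oscillate, so the default counts
  # them as changed while excluding them recovers 1 exactly
  expect_equal(mutational_robustness(matrix(0, 4, 4), rep(0, 4),
                                     nonviable = "exclude"), 1)
  rz <- mutational_robustness(matrix(0, 4, 4), rep(0, 4))
  expect_gte(rz, 0); expect_lte(rz, 1)
  # uniform weighting counts grid points equally
  W <- switch_net()
  r1 <- mutational_robustness(W, c(1, 1), weighting = "uniform")
  expect_gte(r1, 0); expect_lte(r1, 1)
})

test_that("environmental robustness behaves at its trivial extremes", {
  f <- make_fixture("founder")
  set.seed(1)
  expect_equal(environmental_robustness(f$W, f$s0, rate = 0, n_pert = 10)$mean_distance, 0)
  z <- environmental_robustness(matrix(0, 6, 6), rep(1, 6), rate = 0.2,
                                n_pert = 50)
  expect_equal(z$mean_distance, 0)  # phenotype is all-basal regardless of s0
  r <- environmental_robustness(f$W, f$s0, rate = 0.1, n_pert = 200)
  expect_gte(r$mean_distance, 0)
  expect_equal(r$n_used + r$n_inversion + r$n_nonconverged, 200)
})
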