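# Comparison models: environmental-perturbation fitness, split selection,
# discrete dynamics, logic goals, MVG regime.

test_that("environmental-perturbation fitness evaluates the printed formula", {
  # all perturbed phenotypes on target: gamma = 1, f = 1 - exp(-3)
  f <- make_fixture("toggle_switch")
  target <- c(1, 0)
  set.seed(40)
  v <- espinosa_fitness(f$W, f$s0, target, env_rate = 0, n_env = 20)
  expect_equal(v, 1 - exp(-3))
  # all at maximal distance: f = 0
  set.seed(40)
  v0 <- espinosa_fitness(f$W, f$s0, 1 - target, env_rate = 0, n_env = 20,
                         d_max = 2)
  expect_equal(v0, 0)
  # half-and-half: gamma = 0.5 (direct evaluation of the formula)
  gamma <- mean(c(rep(1, 200), rep(0, 200)))
  expect_equal(1 - exp(-3 * gamma), 1 - exp(-1.5))
  # monotone non-increasing in each D_i, bounded by 1 - exp(-3)
  set.seed(41)
  r <- espinosa_fitness(f$W, f$s0, target, env_rate = 0.3, n_env = 100)
  expect_gte(r, 0); expect_lte(r, 1 - exp(-3))
})

test_that("split fitness scores the two gene subsets separately", {
  phen <- c(1, 1, 0, 0)
  founder <- c(1, 1, 1, 1)
  opp <- c(0, 0, 0, 0)
  r <- split_fitness(phen, founder, opp, "parasite", alpha = 0.1,
                     stabilized_genes = 1:2)
  expect_equal(r$f_s, 1)              # matches founder on stabilized genes
  expect_equal(r$f_c, 1)              # matches antagonist on coevolving genes
  # printed stabilizing form exposes the boundary anomaly: f_s = 0 at d = 0
  rp <- split_fitness(phen, founder, opp, "parasite", alpha = 0.1,
                      stabilized_genes = 1:2, stabilizing_form = "printed")
  expect_equal(rp$f_s, 0)
  # discrete scale: all coevolving genes opposite (+1 vs -1), zeta = 4 -> d = 1
  rd <- split_fitness(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, -1, -1), "host",
                      alpha = 0.1, stabilized_genes = 1:2, zeta = 4)
  expect_equal(rd$f_c, exp(0))        # host form e^{-(1-d)/alpha} at d = 1
})

test_that("discrete dynamics: fixed points, the sign(0) convention, cycles", {
  # zero matrix: sign(0) = +1 fixed point after one step
  d0 <- discrete_develop(matrix(0, 3, 3), c(-1, -1, 1))
  expect_true(d0$converged)
  expect_equal(d0$phenotype, rep(1, 3))
  # identity-like W: any state is a fixed point
  dI <- discrete_develop(diag(4), c(1, -1, 1, -1))
  expect_true(dI$converged)
  expect_equal(dI$phenotype, c(1, -1, 1, -1))
  # 2-gene negative loop cycles (exhaustive state space)
  W <- matrix(c(0, -1, 1, 0), 2, 2)
  dc <- discrete_develop(W, c(1, 1))
  expect_false(dc$converged)
  # detection bounded by the finite state space
  set.seed(44)
  for (k in 1:20) {
    W <- random_network(5, 0.6)
    s0 <- sample(c(-1, 1), 5, replace = TRUE)
    d <- discrete_develop(W, s0)
    expect_lte(d$steps, 2^5 + 1)
  }
})

test_that("logic goals: truth tables and their overlap", {
  g1 <- logic_goal("G1"); g2 <- logic_goal("G2")
  p <- logic_patterns()
  expect_equal(nrow(p), 16L)
  expect_equal(sum(g1), 12L)  # OR of two XORs is true on 12/16 inputs
  expect_equal(sum(g2), 4L)   # AND of two XORs is true on 4/16
  expect_equal(sum(g1 == g2), 8L)  # the goals agree on exactly half
  # spot-check one row: X=1,Y=0,Z=1,W=1 -> XOR1=1, XOR2=0 -> G1=1, G2=0
  row <- which(p[, 1] == 1 & p[, 2] == 0 & p[, 3] == 1 & p[, 4] == 1)
  expect_equal(g1[row], 1L); expect_equal(g2[row], 0L)
})

test_that("logic evaluation enumerates 16 patterns; constants score as expected", {
  cfg <- mvg_config()
  # perfect circuit
  g <- make_fixture("mvg_perfect_g1")
  expect_equal(logic_goal_eval(g$W, "G1", cfg, s0 = g$s0), 1)
  # constant-1 output: self-locked output gene
  W1 <- matrix(0, 10, 10); W1[10, 10] <- 5
  s0 <- c(rep(0, 9), 1)
  expect_equal(logic_goal_eval(W1, "G1", cfg, s0 = s0), 12 / 16)
  expect_equal(logic_goal_eval(W1, "G2", cfg, s0 = s0), 4 / 16)
  # constant-0 output
  W0 <- matrix(0, 10, 10); W0[10, 10] <- 5
  s00 <- rep(0, 10)
  expect_equal(logic_goal_eval(W0, "G1", cfg, s0 = s00), 4 / 16)
  expect_equal(logic_goal_eval(W0, "G2", cfg, s0 = s00), 12 / 16)
})

test_that("MVG run: frozen sensitivity under mu = 0 and working machinery", {
  cfg <- mvg_config(M = 20L, generations = 40L, mu = 0, switch_every = 20L,
                    sense_every = 20L, sense_sample = 3L,
                    sense_grid = sensitivity_grid(delta = 0.5), seed = 77L)
  tr <- run_mvg(cfg, regime = "mvg")
  expect_true(all(tr$persistence %in% c(0, 1)))  # clonal: frozen sets
  expect_true(all(tr$mean_fitness >= 0 & tr$mean_fitness <= 1))
  expect_equal(dim(tr$frequency), c(10L, 10L))
})

test_that("alternating-target control regimes run and score standard sensitivity", {
  cfg <- mvg_config(M = 20L, generations = 30L, switch_every = 15L,
                    sense_every = 15L, sense_sample = 2L,
                    sense_grid = sensitivity_grid(delta = 0.5), seed = 78L)
  for (regime in c("half_invert", "full_invert")) {
    tr <- run_mvg(cfg, regime = regime)
    expect_s3_class(tr, "mvg_trace")
    expect_true(all(tr$persistence >= 0 & tr$persistence <= 1))
  }
})
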