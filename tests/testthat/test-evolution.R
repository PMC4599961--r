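# Founding, mutation operator, reproduction, fitness, generations, lineage.

test_that("founder construction respects the density parameter", {
  cfg0 <- coevo_config(c0 = 0, M = 5L, generations = 0L)
  set.seed(1)
  pop0 <- found_population(cfg0, "host")
  expect_equal(pop0$founder, matrix(0, 10, 10))
  expect_equal(pop0$phen[, 1], rep(0.5, 10))  # all basal
  cfg1 <- coevo_config(c0 = 1, M = 5L, generations = 0L)
  set.seed(2)
  pop1 <- found_population(cfg1, "host")
  expect_true(all(pop1$founder != 0))
  # nonzero count ~ Binomial(100, 0.5): mean over 200 founders within 3 SE
  set.seed(3)
  counts <- replicate(200, sum(random_network(10, 0.5) != 0))
  se <- sqrt(100 * 0.25 / 200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("founder population is clonal and viable", {
  cfg <- coevo_config(M = 30L, generations = 0L)
  set.seed(4)
  pop <- found_population(cfg, "parasite")
  expect_equal(pop$M, 30L)
  expect_true(all(pop$genomes == pop$genomes[, 1]))
  expect_true(develop(get_network(pop, 7), pop$s0)$converged)
})

test_that("mutation operator: event bookkeeping and zero-rate neutrality", {
  f <- make_fixture("founder")
  set.seed(9)
  r0 <- mutate_network(f$W, mu = 0)
  expect_identical(r0$W, f$W)
  expect_equal(nrow(r0$events), 0L)
  # events describe exactly the genotype difference
  set.seed(10)
  for (k in 1:20) {
    r <- mutate_network(f$W, mu = 3)
    changed <- which(r$W != f$W, arr.ind = TRUE)
    expect_setequal(paste(changed[, 1], changed[, 2]),
                    paste(r$events[, "i"], r$events[, "j"]))
    if (nrow(r$events))
      expect_equal(r$W[r$events[, c("i", "j"), drop = FALSE]],
                   unname(r$events[, "new"]))
  }
})

test_that("mutation drives density toward rho/(rho+phi)", {
  # empirical per-event density drift matches mu*(rho*(1-c) - phi*c)/N^2
  set.seed(12)
  N <- 10; c0 <- 0.3
  drift <- replicate(4000, {
    W <- random_network(N, c0)
    sum(mutate_network(W, mu = 1, rho = 0.025, phi = 0.025)$W != 0) - sum(W != 0)
  })
  expected <- 1 * (0.025 * (1 - c0) - 0.025 * c0)  # in counts per genotype
  expect_lt(abs(mean(drift) - expected), 3 * sd(drift) / sqrt(4000))
  # long-run walk settles at density 0.5 regardless of the start
  walk <- mutation_only_walk(M = 50L, N = N, c0 = 0.3, generations = 60000L,
                             record_every = 1000L)$trajectory
  late <- walk$density[walk$generation > 40000]
  expect_lt(abs(mean(late) - 0.5), 0.03)
})

test_that("offspring construction: clonal and row-wise recombination", {
  cfg <- coevo_config(M = 20L, generations = 0L)
  set.seed(20)
  pop <- found_population(cfg, "host")
  off <- make_offspring(pop, "asexual")
  expect_identical(off$W, get_network(pop, off$parents))
  # sexual: rows come wholly from one of two distinct parents
  A <- matrix(1, 4, 4); B <- matrix(-1, 4, 4)
  pop2 <- list(genomes = cbind(as.numeric(A), as.numeric(B)),
               phen = matrix(0.5, 4, 2), N = 4L, M = 2L, s0 = rep(1, 4),
               species = "host")
  class(pop2) <- "coevo_population"
  set.seed(21)
  rowpat <- replicate(400, {
    W <- make_offspring(pop2, "sexual")$W
    expect_true(all(W %in% c(-1, 1)))
    expect_true(all(apply(W, 1, function(r) length(unique(r)) == 1)))
    sum(W[, 1] == 1)
  })
  # rows from parent A ~ Binomial(4, 1/2)
  expect_equal(mean(rowpat), 2, tolerance = 3 * sqrt(4 * 0.25 / 400))
  expect_error(make_offspring(list(M = 1L), "sexual"), "M >= 2")
})

test_that("fitness functions are mirror images meeting at D = 0.5", {
  # D = 0: parasite at the optimum, host maximally exposed
  expect_equal(coevo_fitness(rep(1, 4), rep(1, 4), "parasite", 0.1), 1)
  expect_equal(coevo_fitness(rep(1, 4), rep(1, 4), "host", 0.1), exp(-1 / 0.1))
  # rms D = 0.5 is the symmetry point, for any alpha
  x <- rep(0, 4); y <- rep(0.5, 4)
  for (al in c(0.05, 0.1, 0.3, 1, 10)) {
    expect_identical(coevo_fitness(x, y, "host", al),
                     coevo_fitness(x, y, "parasite", al))
  }
  expect_equal(coevo_fitness(x, y, "host", 0.1), exp(-5), tolerance = 1e-12)
})

test_that("a generation preserves population size, viability and lineage links", {
  cfg <- coevo_config(N = 6L, M = 30L, generations = 0L, seed = 31L)
  set.seed(31)
  host <- found_population(cfg, "host")
  parasite <- found_population(cfg, "parasite")
  step <- next_generation(host, parasite, cfg)
  for (sp in c("host", "parasite")) {
    pop <- step[[sp]]
    expect_equal(ncol(pop$genomes), 30L)
    expect_true(all(attr(pop, "parents")[, 1] %in% 1:30))
    for (k in c(1, 15, 30))
      expect_true(develop(get_network(pop, k), pop$s0)$converged)
  }
})

test_that("with mu = 0 the founder genotype is conserved forever", {
  cfg <- coevo_config(N = 6L, M = 20L, mu = 0, alpha = 1, generations = 15L,
                      seed = 32L, ss_every = 0L, diversity_every = 0L)
  tr <- run_coevolution(cfg)
  expect_true(all(tr$final$host$genomes == as.numeric(tr$host$founder)))
  expect_true(all(vapply(tr$host$events, nrow, integer(1)) == 0L))
})

test_that("identical seed and config reproduce the trace bit-exactly", {
  cfg <- coevo_config(N = 6L, M = 25L, generations = 25L, seed = 99L,
                      diversity_every = 5L, ss_every = 25L, ss_sample = 3L)
  t1 <- run_coevolution(cfg)
  t2 <- run_coevolution(cfg)
  expect_identical(t1$final$host$genomes, t2$final$host$genomes)
  expect_identical(t1$final$parasite$phen, t2$final$parasite$phen)
  expect_identical(t1$measurements, t2$measurements)
  expect_identical(t1$diversity, t2$diversity)
})

test_that("generations = 0 returns the clonal founder populations", {
  cfg <- coevo_config(N = 6L, M = 10L, generations = 0L, seed = 5L)
  tr <- run_coevolution(cfg)
  expect_equal(tr$generations, 0L)
  expect_true(all(tr$final$host$genomes == tr$final$host$genomes[, 1]))
})

test_that("asymmetric population sizes are supported", {
  cfg <- coevo_config(N = 6L, M_host = 15L, M_parasite = 40L,
                      generations = 8L, seed = 51L, ss_every = 0L,
                      diversity_every = 0L)
  tr <- run_coevolution(cfg)
  expect_equal(ncol(tr$final$host$genomes), 15L)
  expect_equal(ncol(tr$final$parasite$genomes), 40L)
})

test_that("stabilizing pre-phase keeps the population near its founder phenotype", {
  cfg <- coevo_config(N = 6L, M = 30L, generations = 1L,
                      stabilizing_generations = 30L, seed = 61L,
                      ss_every = 0L, diversity_every = 0L)
  tr <- run_coevolution(cfg)
  target <- tr$host$founder_phenotype
  D <- sqrt(colMeans((tr$final$host$phen - target)^2))
  expect_lt(mean(D), 0.25)
})

test_that("lineage tracing replays mutation events to exact genotypes", {
  tr <- small_trace()
  lin <- trace_lineage(tr, "host", generation = 60, index = 3)
  expect_length(lin, 61)
  expect_equal(lin[[1]]$generation, 60L)
  expect_equal(lin[[61]]$generation, 0L)
  expect_identical(lin[[61]]$W, tr$host$founder)
  # the reconstructed focal genotype equals the stored final population column
  expect_equal(as.numeric(lin[[1]]$W), tr$final$host$genomes[, 3])
  # consecutive genotypes differ exactly by the recorded events
  for (k in 2:20) {
    diffs <- sum(lin[[k - 1]]$W != lin[[k]]$W)
    expect_lte(diffs, max(nrow(lin[[k - 1]]$events), 0))
  }
  # steps_back = 0 returns the individual itself
  self <- trace_lineage(tr, "host", 60, 3, steps_back = 0)
  expect_length(self, 1)
  # multiple-mutation counts along the lineage are recoverable
  nmut <- vapply(lin[-61], function(x) nrow(x$events), integer(1))
  expect_true(all(nmut >= 0))
})
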