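# Two-population coevolution engine.
#
# Each generation, each species independently: (1) scores every current
# individual against a freshly drawn random opponent from the other species'
# pre-update generation; (2) fills M offspring slots by drawing parents with
# probability proportional to fitness (Wright-Fisher sampling), cloning
# (asexual) or recombining rows (sexual), mutating and developing; offspring
# that fail to reach a steady state have zero fitness and are discarded
# (the slot is redrawn). Host fitness rewards phenotype divergence, parasite
# fitness rewards mimicry:
#   f_host = exp(-(1 - D)/alpha),  f_parasite = exp(-D/alpha),
# with D the RMS phenotype distance. Both species update synchronously from
# the same pre-update opponent pool.

#' Configuration for a coevolution run
#'
#' Defaults are the model's standard conditions: N = 10 genes, M = 200
#' individuals per species, per-gene mutation rate mu = 0.1 (one expected
#' mutation event per genotype per generation),
#' selection strength alpha = 0.1, founder density c0 = 0.5, addition and
#' deletion probabilities rho = phi = 0.025 (the values for which the expected
#' density change mu*(rho*(1-c) - phi*c)/N^2 vanishes at c = 0.5), asexual
#' reproduction.
#'
#' @param N Number of genes.
#' @param M Population size per species (shorthand for equal sizes).
#' @param M_host,M_parasite Per-species population sizes (default `M`).
#' @param mu Mutation rate per gene (cis-regulatory region) per generation;
#'   the number of mutation events per offspring genotype is
#'   Poisson(`mu * N`).
#' @param alpha Selection strength (smaller = stronger selection).
#' @param c0 Founder network density.
#' @param rho Probability that a mutation event hitting a zero entry adds a
#'   new N(0,1) interaction.
#' @param phi Probability that a mutation event hitting a nonzero entry
#'   deletes it (otherwise the weight is redrawn from N(0,1)).
#' @param reproduction `"asexual"` (clonal) or `"sexual"` (two distinct
#'   parents, each W row inherited from either parent with probability 1/2).
#' @param generations Number of coevolutionary generations.
#' @param stabilizing_generations Optional pre-phase length: before
#'   coevolution starts, each species evolves toward its own founder
#'   phenotype under stabilizing selection (`f = exp(-D/alpha)`).
#' @param s0_shared Use one shared random binary initial expression state for
#'   both species (default: independent states).
#' @param seed Seed for the run's single RNG stream (`NULL` = leave the
#'   current RNG state untouched).
#' @param dynamics [dynamics_params()].
#' @param grid [sensitivity_grid()] used for scheduled sensitivity samples.
#' @param p_flip,same_tol Inversion / unchanged thresholds.
#' @param fitness_distance Phenotype-distance convention inside the fitness
#'   functions: `"msd"` (mean squared difference, the printed form
#'   `sum((x_i-y_i)^2)/N`) or `"rms"` (its square root).
#' @param selection `"proportional"` (Wright-Fisher: parents drawn with
#'   probability proportional to fitness; offspring only filtered for
#'   developmental viability) or `"threshold"` (viability selection: a
#'   candidate offspring survives iff its fitness against a fresh random
#'   opponent exceeds a U(0,1) draw; parents drawn uniformly). Both produce
#'   the same qualitative phenomenology; the proportional scheme is the
#'   default because it reproduces the reference steady-state sensitivity
#'   and diversity plateaus.
#' @param ss_every Generations between sensitivity/robustness samples
#'   (0 disables them).
#' @param ss_sample Individuals sampled per sensitivity measurement.
#' @param ss_species Species to sample (`"host"`, `"parasite"` or both).
#' @param diversity_every Generations between sign-diversity measurements
#'   (0 disables).
#' @param store_phenotypes Keep the full N x M phenotype matrix of every
#'   generation (needed by [winning_matrix()]).
#' @param genotype_snapshot_every Store full population genotypes every k
#'   generations (0 = none). Lineages can always be reconstructed exactly
#'   from the founder plus the per-generation mutation event log.
#' @param max_attempt_factor Offspring-attempt budget per generation, as a
#'   multiple of M; exceeding it aborts the run with a diagnostic (under
#'   threshold selection, mean survival of the losing species can drop to
#'   ~exp(-1/alpha), so the budget must accommodate it).
#' @param founder_tries Redraws allowed when searching for a viable founder.
#' @return A list of class `"coevo_config"`.
#' @export
coevo_config <- function(N = 10L, M = 200L, M_host = M, M_parasite = M,
                         mu = 0.1, alpha = 0.1, c0 = 0.5,
                         rho = 0.025, phi = 0.025,
                         reproduction = c("asexual", "sexual"),
                         generations = 2000L, stabilizing_generations = 0L,
                         s0_shared = FALSE, seed = NULL,
                         dynamics = dynamics_params(),
                         grid = sensitivity_grid(),
                         p_flip = 0.9, same_tol = 0.1,
                         fitness_distance = c("msd", "rms"),
                         selection = c("proportional", "threshold"),
                         ss_every = 50L, ss_sample = 20L,
                         ss_species = c("host", "parasite"),
                         diversity_every = 10L,
                         store_phenotypes = TRUE,
                         genotype_snapshot_every = 0L,
                         max_attempt_factor = 10000L,
                         founder_tries = 1000L) {
  reproduction <- match.arg(reproduction)
  fitness_distance <- match.arg(fitness_distance)
  selection <- match.arg(selection)
  ss_species <- match.arg(ss_species, several.ok = TRUE)
  stopifnot(N >= 1, M_host >= 1, M_parasite >= 1, mu >= 0, alpha > 0,
            c0 >= 0, c0 <= 1, rho >= 0, rho <= 1, phi >= 0, phi <= 1,
            generations >= 0, stabilizing_generations >= 0,
            max_attempt_factor >= 1)
  if (reproduction == "sexual" && min(M_host, M_parasite) < 2)
    stop("sexual reproduction requires at least two individuals", call. = FALSE)
  structure(list(N = as.integer(N), M_host = as.integer(M_host),
                 M_parasite = as.integer(M_parasite), mu = mu, alpha = alpha,
                 c0 = c0, rho = rho, phi = phi, reproduction = reproduction,
                 generations = as.integer(generations),
                 stabilizing_generations = as.integer(stabilizing_generations),
                 s0_shared = isTRUE(s0_shared), seed = seed,
                 dynamics = dynamics, grid = grid,
                 p_flip = p_flip, same_tol = same_tol,
                 fitness_distance = fitness_distance,
                 selection = selection,
                 ss_every = as.integer(ss_every),
                 ss_sample = as.integer(ss_sample), ss_species = ss_species,
                 diversity_every = as.integer(diversity_every),
                 store_phenotypes = isTRUE(store_phenotypes),
                 genotype_snapshot_every = as.integer(genotype_snapshot_every),
                 max_attempt_factor = as.integer(max_attempt_factor),
                 founder_tries = as.integer(founder_tries)),
            class = "coevo_config")
}

#' Random founder-style network
#'
#' Each entry is nonzero with probability `density`, with weights drawn from
#' N(0,1). Uses the current RNG stream.
#'
#' @param N Number of genes.
#' @param density Probability that an entry is nonzero.
#' @return N x N numeric matrix.
#' @export
random_network <- function(N, density = 0.5) {
  mask <- stats::runif(N * N) < density
  W <- matrix(0, N, N)
  W[mask] <- stats::rnorm(sum(mask))
  W
}

#' Found a clonal population
#'
#' Draws a random binary initial expression state and a random founder
#' network, redrawing the network until it develops to a steady state; the
#' founder is then copied M times.
#'
#' @param config A [coevo_config()].
#' @param species `"host"` or `"parasite"`.
#' @param s0 Optional initial expression state (default: fresh random binary).
#' @return A list of class `"coevo_population"` with the packed `genomes`
#'   (N^2 x M, one column per individual), `phen` (N x M), `species`, `s0`,
#'   and sizes `N`, `M`.
#' @export
found_population <- function(config, species = c("host", "parasite"),
                             s0 = NULL) {
  species <- match.arg(species)
  N <- config$N
  M <- if (species == "host") config$M_host else config$M_parasite
  if (is.null(s0)) s0 <- as.numeric(stats::runif(N) < 0.5)
  dyn <- config$dynamics
  for (k in seq_len(config$founder_tries)) {
    W <- random_network(N, config$c0)
    dev <- develop(W, s0, dyn)
    if (dev$converged) {
      genomes <- matrix(rep(as.numeric(W), M), ncol = M)
      phen <- matrix(rep(dev$state, M), ncol = M)
      return(structure(list(genomes = genomes, phen = phen, species = species,
                            s0 = s0, N = N, M = M, founder = W),
                       class = "coevo_population"))
    }
  }
  stop("no viable founder found after ", config$founder_tries, " draws",
       call. = FALSE)
}

#' @export
print.coevo_population <- function(x, ...) {
  cat("coevo_population:", x$species, "-", x$M, "individuals,", x$N, "genes\n")
  invisible(x)
}

#' Extract one individual's genotype from a population
#' @param pop A `coevo_population`.
#' @param k Individual index.
#' @return N x N genotype matrix.
#' @export
get_network <- function(pop, k) {
  matrix(pop$genomes[, k], pop$N, pop$N)
}

#' Extract one individual's phenotype from a population
#' @inheritParams get_network
#' @return Length-N expression vector.
#' @export
get_phenotype <- function(pop, k) pop$phen[, k]

#' Mutate a genotype
#'
#' The number of mutation events is Poisson(`mu`); each event picks a uniform
#' random matrix element. A zero element gains a fresh N(0,1) weight with
#' probability `rho` (otherwise nothing happens); a nonzero element is deleted
#' with probability `phi` and otherwise replaced by a fresh N(0,1) draw.
#'
#' @param W Genotype matrix.
#' @param mu Mean events per call.
#' @param rho,phi Addition / deletion probabilities.
#' @return List with the mutated `W` and an `events` matrix
#'   (columns `i`, `j`, `old`, `new`; realized changes only).
#' @export
mutate_network <- function(W, mu = 0.1, rho = 0.025, phi = 0.025) {
  validate_network(W)
  stopifnot(mu >= 0, rho >= 0, rho <= 1, phi >= 0, phi <= 1)
  cpp_mutate(W, mu, rho, phi)
}

#' Produce one candidate offspring genotype (before mutation)
#'
#' @param pop A `coevo_population`.
#' @param mode `"asexual"` (clone a uniform-random parent) or `"sexual"` (two
#'   distinct uniform-random parents; each W row is inherited from one of them
#'   with probability 1/2 — row-wise inheritance of cis-regulatory regions
#'   with free recombination among loci).
#' @return List with `W` and `parents` (one or two indices).
#' @export
make_offspring <- function(pop, mode = c("asexual", "sexual")) {
  mode <- match.arg(mode)
  if (mode == "asexual") {
    p <- sample.int(pop$M, 1L)
    return(list(W = get_network(pop, p), parents = p))
  }
  if (pop$M < 2) stop("sexual reproduction requires M >= 2", call. = FALSE)
  ps <- sample.int(pop$M, 2L)
  A <- get_network(pop, ps[1])
  B <- get_network(pop, ps[2])
  pick <- stats::runif(pop$N) < 0.5
  W <- A
  W[!pick, ] <- B[!pick, ]
  list(W = W, parents = ps)
}

#' Antagonistic / stabilizing fitness
#'
#' @param phen Candidate phenotype.
#' @param opponent Opponent phenotype (or target, for stabilizing selection).
#' @param role `"host"` (`exp(-(1-D)/alpha)`), `"parasite"` (`exp(-D/alpha)`)
#'   or `"stabilizing"` (`exp(-D/alpha)` toward a fixed target).
#' @param alpha Selection strength.
#' @return Fitness in `[0, 1]`. `D` is the RMS phenotype distance; host and
#'   parasite fitness are mirror images, equal at `D = 0.5`.
#' @export
coevo_fitness <- function(phen, opponent,
                          role = c("host", "parasite", "stabilizing"),
                          alpha = 0.1) {
  role <- match.arg(role)
  stopifnot(alpha > 0)
  D <- phenotype_distance(phen, opponent, "rms")
  if (role == "host") exp(-(1 - D) / alpha) else exp(-D / alpha)
}

# Single-species generation step (internal): returns the cpp result or errors
# when the viability budget is exhausted.
step_species <- function(pop, opp_phen, role, config) {
  dyn <- config$dynamics
  r <- cpp_evolve_generation(pop$genomes, opp_phen, pop$phen, pop$s0,
                             if (role == "host") 0L else 1L, pop$M,
                             dyn$gain, dyn$max_steps, dyn$conv_tol,
                             dyn$conv_window, config$mu * config$N,
                             config$rho,
                             config$phi, config$reproduction == "sexual",
                             config$alpha,
                             as.integer(config$max_attempt_factor) * pop$M,
                             config$fitness_distance == "rms",
                             config$selection == "threshold")
  if (r$accepted < pop$M)
    stop("offspring viability stall in ", pop$species, " population: only ",
         r$accepted, "/", pop$M, " viable offspring within ",
         r$attempts, " attempts", call. = FALSE)
  r
}

#' Advance both populations by one generation
#'
#' Both species update synchronously: every individual of either species is
#' scored against a freshly drawn random opponent from the other species'
#' *pre-update* generation, and parents are then sampled in proportion to
#' fitness. Offspring that do not reach a steady state are discarded.
#'
#' @param host,parasite `coevo_population` objects.
#' @param config A [coevo_config()].
#' @return List with updated `host` and `parasite` populations; each carries
#'   the generation's `parents`, `events` and `attempts` as attributes.
#' @export
next_generation <- function(host, parasite, config) {
  rh <- step_species(host, parasite$phen, "host", config)
  rp <- step_species(parasite, host$phen, "parasite", config)
  host$genomes <- rh$genomes; host$phen <- rh$phen
  parasite$genomes <- rp$genomes; parasite$phen <- rp$phen
  attr(host, "parents") <- rh$parents
  attr(host, "events") <- rh$events
  attr(host, "attempts") <- rh$attempts
  attr(host, "fitness") <- rh$fitness
  attr(parasite, "parents") <- rp$parents
  attr(parasite, "events") <- rp$events
  attr(parasite, "attempts") <- rp$attempts
  attr(parasite, "fitness") <- rp$fitness
  list(host = host, parasite = parasite)
}

new_species_record <- function(G, N, M, store_phen) {
  list(mean_expr = matrix(NA_real_, G, N),
       parents = matrix(NA_integer_, G, M),
       parents2 = NULL,  # filled for sexual runs
       events = vector("list", G),
       attempts = integer(G),
       density = numeric(G),
       mean_fitness = numeric(G),
       phen = if (store_phen) vector("list", G) else NULL,
       snapshots = list())
}

record_generation <- function(rec, g, r, store_phen, snapshot_every) {
  rec$mean_expr[g, ] <- rowMeans(r$phen)
  rec$parents[g, ] <- r$parents[, 1]
  if (!all(is.na(r$parents[, 2]))) {
    if (is.null(rec$parents2))
      rec$parents2 <- matrix(NA_integer_, nrow(rec$parents), ncol(rec$parents))
    rec$parents2[g, ] <- r$parents[, 2]
  }
  rec$events[[g]] <- r$events
  rec$attempts[g] <- r$attempts
  rec$density[g] <- mean(r$genomes != 0)
  rec$mean_fitness[g] <- mean(r$fitness)
  if (store_phen) rec$phen[[g]] <- r$phen
  if (snapshot_every > 0 && g %% snapshot_every == 0)
    rec$snapshots[[as.character(g)]] <- r$genomes
  rec
}

#' Run a full coevolution simulation
#'
#' Founds both populations (optionally runs a stabilizing pre-phase toward
#' each species' own founder phenotype), then iterates [next_generation()]
#' for `config$generations` generations, recording per-generation lineage and
#' phenotype summaries and scheduled sensitivity/robustness/diversity
#' measurements.
#'
#' @param config A [coevo_config()].
#' @param progress Print a progress line every 100 generations.
#' @return A list of class `"coevo_trace"`; see Details.
#' @details The trace contains `config`; per-species records (`host`,
#'   `parasite`) with the founder, `s0`, per-generation mean expression,
#'   parent indices, mutation event logs, attempt counts, densities and
#'   (optionally) full phenotype matrices; `measurements` (a data frame of
#'   scheduled sensitivity/robustness samples, with the sampled profiles in
#'   `ss_samples`); `diversity` (data frame); and the `final` populations.
#' @export
run_coevolution <- function(config = coevo_config(), progress = FALSE) {
  stopifnot(inherits(config, "coevo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  host <- found_population(config, "host")
  parasite <- found_population(config, "parasite",
                               s0 = if (config$s0_shared) host$s0 else NULL)
  founder_phen <- list(host = host$phen[, 1], parasite = parasite$phen[, 1])

  # stabilizing pre-phase: each species evolves toward its founder phenotype
  for (g in seq_len(config$stabilizing_generations)) {
    for (sp in c("host", "parasite")) {
      pop <- get(sp)
      r <- cpp_evolve_generation(pop$genomes,
                                 matrix(founder_phen[[sp]], ncol = 1),
                                 pop$phen, pop$s0, 1L, pop$M,
                                 config$dynamics$gain,
                                 config$dynamics$max_steps,
                                 config$dynamics$conv_tol,
                                 config$dynamics$conv_window,
                                 config$mu * config$N, config$rho, config$phi,
                                 config$reproduction == "sexual",
                                 config$alpha,
                                 config$max_attempt_factor * pop$M,
                                 config$fitness_distance == "rms",
                                 config$selection == "threshold")
      if (r$accepted < pop$M)
        stop("offspring viability stall during stabilizing pre-phase",
             call. = FALSE)
      pop$genomes <- r$genomes; pop$phen <- r$phen
      assign(sp, pop)
    }
  }

  G <- config$generations
  rec <- list(host = new_species_record(G, config$N, config$M_host,
                                        config$store_phenotypes),
              parasite = new_species_record(G, config$N, config$M_parasite,
                                            config$store_phenotypes))
  meas <- list(); ss_samples <- list(); divers <- list()

  measure_ss <- function(pop, g) {
    idx <- sample.int(pop$M, min(config$ss_sample, pop$M))
    profs <- lapply(idx, function(k)
      network_sensitivity(get_network(pop, k), pop$s0, config$grid,
                          config$p_flip, config$same_tol, config$dynamics))
    rob <- vapply(profs, function(p)
      mutational_robustness(NULL, NULL, profile = p), numeric(1))
    list(summary = data.frame(generation = g, species = pop$species,
                              mean_ss = mean(vapply(profs, `[[`, numeric(1),
                                                    "ss_total")),
                              mean_robustness = mean(rob),
                              mean_fraction_sensitive =
                                mean(vapply(profs, function(p)
                                  length(p$sensitive), numeric(1))) / config$N^2),
         profiles = list(generation = g, species = pop$species, indices = idx,
                         ss = lapply(profs, `[[`, "ss")))
  }

  take_measurements <- function(g, pops) {
    if (config$ss_every > 0 && g %% config$ss_every == 0) {
      for (sp in config$ss_species) {
        m <- measure_ss(pops[[sp]], g)
        meas[[length(meas) + 1L]] <<- m$summary
        ss_samples[[length(ss_samples) + 1L]] <<- m$profiles
      }
    }
    if (config$diversity_every > 0 && g %% config$diversity_every == 0) {
      for (sp in c("host", "parasite")) {
        divers[[length(divers) + 1L]] <<-
          data.frame(generation = g, species = sp,
                     diversity = sign_diversity(pops[[sp]]))
      }
    }
  }

  for (g in seq_len(G)) {
    step <- next_generation(host, parasite, config)
    host <- step$host; parasite <- step$parasite
    rec$host <- record_generation(rec$host, g,
                                  list(phen = host$phen,
                                       parents = attr(host, "parents"),
                                       events = attr(host, "events"),
                                       attempts = attr(host, "attempts"),
                                       fitness = attr(host, "fitness"),
                                       genomes = host$genomes),
                                  config$store_phenotypes,
                                  config$genotype_snapshot_every)
    rec$parasite <- record_generation(rec$parasite, g,
                                      list(phen = parasite$phen,
                                           parents = attr(parasite, "parents"),
                                           events = attr(parasite, "events"),
                                           attempts = attr(parasite, "attempts"),
                                           fitness = attr(parasite, "fitness"),
                                           genomes = parasite$genomes),
                                      config$store_phenotypes,
                                      config$genotype_snapshot_every)
    take_measurements(g, list(host = host, parasite = parasite))
    if (progress && g %% 100 == 0)
      message("generation ", g, "/", G,
              " host attempts ", rec$host$attempts[g],
              " parasite attempts ", rec$parasite$attempts[g])
  }

  structure(list(config = config,
                 host = c(list(founder = host$founder, s0 = host$s0,
                               founder_phenotype = founder_phen$host),
                          rec$host),
                 parasite = c(list(founder = parasite$founder,
                                   s0 = parasite$s0,
                                   founder_phenotype = founder_phen$parasite),
                              rec$parasite),
                 measurements = if (length(meas)) do.call(rbind, meas) else NULL,
                 ss_samples = ss_samples,
                 diversity = if (length(divers)) do.call(rbind, divers) else NULL,
                 final = list(host = host, parasite = parasite),
                 generations = G),
            class = "coevo_trace")
}

#' @export
print.coevo_trace <- function(x, ...) {
  cat("coevo_trace:", x$generations, "generations, N =", x$config$N,
      ", M =", x$config$M_host, "/", x$config$M_parasite,
      ",", x$config$reproduction, "reproduction\n")
  if (!is.null(x$measurements)) {
    last <- x$measurements[x$measurements$generation ==
                             max(x$measurements$generation), , drop = FALSE]
    cat("last sensitivity sample (generation",
        max(x$measurements$generation), "):\n")
    print(last, row.names = FALSE)
  }
  invisible(x)
}

#' Trace the ancestral lineage of an individual
#'
#' Follows single-parent links back through an asexual trace, reconstructing
#' each ancestor's genotype exactly by replaying the recorded mutation events
#' from the founder.
#'
#' @param trace A `coevo_trace` from an asexual run.
#' @param species `"host"` or `"parasite"`.
#' @param generation Generation of the focal individual (1-based; 0 is the
#'   founder population).
#' @param index Individual index within the generation.
#' @param steps_back Number of ancestors to return (0 = the individual only).
#' @return List of `steps_back + 1` records, newest first; each has
#'   `generation`, `index`, `W`, and `events` (the mutations that produced it
#'   from its parent).
#' @export
trace_lineage <- function(trace, species = c("host", "parasite"),
                          generation, index, steps_back = generation) {
  species <- match.arg(species)
  if (trace$config$reproduction != "asexual")
    stop("lineage tracing is only supported for asexual traces", call. = FALSE)
  stopifnot(generation >= 0, generation <= trace$generations,
            steps_back <= generation)
  rec <- trace[[species]]
  # walk back to the founder, collecting (generation, index)
  chain <- integer(generation + 1L)  # index at each generation g = 0..generation
  chain[generation + 1L] <- index
  g <- generation
  k <- index
  while (g > 0) {
    k <- rec$parents[g, k]
    chain[g] <- k
    g <- g - 1L
  }
  # replay events forward from the founder
  N <- trace$config$N
  W <- rec$founder
  genotypes <- vector("list", generation + 1L)
  events_at <- vector("list", generation + 1L)
  genotypes[[1L]] <- W
  events_at[[1L]] <- matrix(numeric(0), 0, 5)
  for (g in seq_len(generation)) {
    ev <- rec$events[[g]]
    mine <- ev[ev[, "child"] == chain[g + 1L], , drop = FALSE]
    if (nrow(mine)) {
      for (r in seq_len(nrow(mine))) W[mine[r, "i"], mine[r, "j"]] <- mine[r, "new"]
    }
    genotypes[[g + 1L]] <- W
    events_at[[g + 1L]] <- mine
  }
  keep <- seq(generation + 1L, by = -1L, length.out = steps_back + 1L)
  lapply(keep, function(slot)
    list(generation = slot - 1L, index = chain[slot], W = genotypes[[slot]],
         events = events_at[[slot]]))
}

#' Mutation-only density walk
#'
#' Evolves a population of networks under the mutation operator alone (no
#' reproduction, no selection): each individual receives Poisson(`mu * N`)
#' mutation events per generation. The expected density change per
#' generation is `mu*N*(rho*(1-c) - phi*c)/N^2`, so the long-run mean
#' density is `rho/(rho + phi)` from any starting density.
#'
#' @param M Number of networks.
#' @param N Genes per network.
#' @param c0 Initial density.
#' @param mu Per-gene mutation rate.
#' @param rho,phi Addition / deletion probabilities.
#' @param generations Number of generations.
#' @param record_every Recording cadence.
#' @return A list with `trajectory` (data frame: generation, mean density)
#'   and the final packed `genomes`.
#' @export
mutation_only_walk <- function(M = 200L, N = 10L, c0 = 0.5, mu = 0.1,
                               rho = 0.025, phi = 0.025, generations = 5000L,
                               record_every = 50L) {
  stopifnot(M >= 1, generations >= 1, record_every >= 1)
  genomes <- vapply(seq_len(M), function(k) as.numeric(random_network(N, c0)),
                    numeric(N * N))
  r <- cpp_mutation_only(genomes, as.integer(N), mu * N, rho, phi,
                         as.integer(generations), as.integer(record_every))
  list(trajectory = data.frame(generation = r$generation,
                               density = r$density),
       genomes = r$genomes)
}
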