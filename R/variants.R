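# Comparison model variants: split stabilizing/coevolutionary selection with
# environmental perturbations, discrete-expression dynamics, and the
# modularly-varying-goals (MVG) logic-circuit regime.

#' Environmental-perturbation fitness (split-target comparison model)
#'
#' Perturbs the initial expression state `n_env` times (each gene flipped
#' with probability `env_rate`), develops each copy, and scores the Hamming
#' distance `D_i` between the binarized perturbed phenotype and the binary
#' `target`:
#' `gamma = sum_i (1 - D_i/D_max)^5 / n_env`, `f = 1 - exp(-3*gamma)`.
#' Non-converged perturbed developments contribute `D_i = D_max`.
#'
#' @param W Genotype matrix (must develop to a steady state from `s0`).
#' @param s0 Initial expression state.
#' @param target Binary target phenotype (length N).
#' @param env_rate Per-gene flip probability (default `0.15/N`).
#' @param n_env Number of perturbed developments.
#' @param d_max Hamming-distance normalizer (default N, the full-vector
#'   bound).
#' @param params [dynamics_params()].
#' @return Fitness in `[0, 1 - exp(-3)]`.
#' @export
espinosa_fitness <- function(W, s0, target, env_rate = 0.15 / length(s0),
                             n_env = 400L, d_max = length(s0),
                             params = dynamics_params()) {
  validate_network(W)
  stopifnot(length(target) == length(s0), all(target %in% c(0, 1)))
  N <- length(s0)
  d <- numeric(n_env)
  for (i in seq_len(n_env)) {
    flip <- stats::runif(N) < env_rate
    sp <- ifelse(flip, 1 - s0, s0)
    dev <- develop(W, sp, params)
    d[i] <- if (!dev$converged) d_max
            else sum((dev$phenotype > 0.5) != (target > 0.5))
  }
  gamma <- mean((1 - d / d_max)^5)
  1 - exp(-3 * gamma)
}

#' Split stabilizing / coevolutionary fitness
#'
#' Half of the genes are under stabilizing selection toward the founder
#' target, the rest under coevolutionary selection against an antagonist:
#' `d = sum (target_i - phen_i)^2 / (n * zeta)` over the respective subsets
#' (`zeta` = 1 for continuous, 4 for discrete -1/+1 expression). The
#' coevolutionary part uses the host form `exp(-(1-d)/alpha)` or the parasite
#' form `exp(-d/alpha)`. Survival (applied upstream) requires both components
#' to exceed independent U(0,1) draws.
#'
#' The stabilizing component is printed in the source model as
#' `1 - exp(-d/alpha)`, which *rewards* distance from the stabilizing target;
#' `stabilizing_form = "decay"` (default) uses the self-consistent
#' `exp(-d/alpha)`, `"printed"` reproduces the printed form.
#'
#' @param phen Candidate phenotype vector.
#' @param founder_target Target for the stabilized genes (full-length).
#' @param antagonist_phen Opponent phenotype (full-length).
#' @param role `"host"` or `"parasite"` for the coevolutionary part.
#' @param alpha Selection strength.
#' @param stabilized_genes Indices of genes under stabilizing selection; the
#'   complement is under coevolutionary selection.
#' @param zeta Scale: 1 (continuous) or 4 (discrete -1/+1).
#' @param stabilizing_form `"decay"` or `"printed"` (see Details).
#' @return List with `f_s` and `f_c`.
#' @export
split_fitness <- function(phen, founder_target, antagonist_phen,
                          role = c("host", "parasite"), alpha = 0.1,
                          stabilized_genes = seq_len(length(phen) %/% 2),
                          zeta = 1,
                          stabilizing_form = c("decay", "printed")) {
  role <- match.arg(role)
  stabilizing_form <- match.arg(stabilizing_form)
  stopifnot(zeta %in% c(1, 4), alpha > 0)
  N <- length(phen)
  s_idx <- stabilized_genes
  c_idx <- setdiff(seq_len(N), s_idx)
  stopifnot(length(s_idx) >= 1, length(c_idx) >= 1)
  d_s <- sum((founder_target[s_idx] - phen[s_idx])^2) / (length(s_idx) * zeta)
  d_c <- sum((antagonist_phen[c_idx] - phen[c_idx])^2) / (length(c_idx) * zeta)
  f_s <- if (stabilizing_form == "decay") exp(-d_s / alpha)
         else 1 - exp(-d_s / alpha)
  f_c <- if (role == "host") exp(-(1 - d_c) / alpha) else exp(-d_c / alpha)
  list(f_s = f_s, f_c = f_c)
}

#' Discrete-expression development
#'
#' Threshold dynamics on states in `{-1, +1}^N`:
#' `s_i(t+1) = sign(sum_j w_ij s_j(t))` with the fixed convention
#' `sign(0) = +1`. The state space is finite, so the trajectory is guaranteed
#' to hit either a fixed point (converged) or a limit cycle (non-converged)
#' within `2^N + 1` steps.
#'
#' @param W Genotype matrix.
#' @param s0 Initial state, entries in `{-1, +1}`.
#' @return A list of class `"grn_dev"` (phenotype in `{-1, +1}^N`).
#' @export
discrete_develop <- function(W, s0) {
  validate_network(W)
  stopifnot(length(s0) == nrow(W), all(s0 %in% c(-1, 1)))
  s <- as.numeric(s0)
  seen <- new.env(hash = TRUE)
  assign(paste(s, collapse = ","), TRUE, envir = seen)
  max_steps <- 2^length(s0) + 1
  for (t in seq_len(max_steps)) {
    x <- as.numeric(W %*% s)
    snew <- ifelse(x >= 0, 1, -1)
    if (identical(snew, s))
      return(structure(list(phenotype = s, state = s, converged = TRUE,
                            steps = t, basal = basal_genes(W)),
                       class = "grn_dev"))
    key <- paste(snew, collapse = ",")
    if (exists(key, envir = seen, inherits = FALSE))
      return(structure(list(phenotype = NULL, state = snew, converged = FALSE,
                            steps = t, basal = basal_genes(W)),
                       class = "grn_dev"))
    assign(key, TRUE, envir = seen)
    s <- snew
  }
  stop("internal error: discrete dynamics neither fixed nor periodic")
}

# --- MVG logic-goal variant ------------------------------------------------

#' The 16 binary input patterns over (X, Y, Z, W)
#' @return 16 x 4 integer matrix (rows in binary counting order).
#' @export
logic_patterns <- function() {
  g <- as.matrix(expand.grid(W = 0:1, Z = 0:1, Y = 0:1, X = 0:1))[, 4:1]
  storage.mode(g) <- "integer"
  g
}

#' Truth table of a modularly-varying goal
#'
#' `G1 = (X XOR Y) OR (Z XOR W)`; `G2 = (X XOR Y) AND (Z XOR W)`. The two
#' goals share the XOR sub-goals and differ only in how they are combined.
#'
#' @param goal `"G1"` or `"G2"`.
#' @return Integer vector of length 16, aligned with [logic_patterns()].
#' @export
logic_goal <- function(goal = c("G1", "G2")) {
  goal <- match.arg(goal)
  p <- logic_patterns()
  x1 <- xor(p[, 1] == 1, p[, 2] == 1)
  x2 <- xor(p[, 3] == 1, p[, 4] == 1)
  as.integer(if (goal == "G1") x1 | x2 else x1 & x2)
}

#' Configuration for the logic-goal (MVG) variant
#'
#' Networks have 4 designated input genes (clamped to the input pattern
#' during development) and 6 interacting regulatory genes, one of which is
#' the output.
#'
#' @param input_genes Indices of the 4 clamped input genes.
#' @param output_gene Index of the output gene (read out at steady state,
#'   binarized at 0.5).
#' @param N Total gene count.
#' @param s0 Initial expression of the non-input genes (default: random
#'   binary, drawn once per run).
#' @param switch_every Generations per goal before switching (G1, G2, G1,
#'   ...).
#' @param sensitivity_threshold Fraction of the 16 mappings a mutated network
#'   must match of the *alternate* goal to count as sensitive (`> 12/16`).
#' @param M Population size.
#' @param generations Total generations.
#' @param mu,rho,phi Mutation parameters (`mu` is the per-gene rate; events
#'   per offspring ~ Poisson(`mu * N`)).
#' @param c0 Founder density.
#' @param alpha Selection strength (used by the non-MVG alternating-target
#'   control regimes).
#' @param grid [sensitivity_grid()] for the mutation sweep (the MVG
#'   sensitivity sweep can use a coarser grid via `sense_grid`).
#' @param sense_grid Grid used for the per-interaction sensitivity sweep.
#' @param sense_every Generations between sensitivity sweeps (0 disables).
#' @param sense_sample Individuals sampled per sweep.
#' @param dynamics [dynamics_params()].
#' @param max_attempt_factor Attempt budget multiple of M.
#' @param seed Seed (`NULL` = current RNG state).
#' @return A list of class `"mvg_config"`.
#' @export
mvg_config <- function(input_genes = 1:4, output_gene = 10L, N = 10L,
                       s0 = NULL, switch_every = 50L,
                       sensitivity_threshold = 0.75, M = 200L,
                       generations = 500L, mu = 0.1, rho = 0.025, phi = 0.025,
                       c0 = 0.5, alpha = 0.1,
                       grid = sensitivity_grid(),
                       sense_grid = sensitivity_grid(delta = 0.1),
                       sense_every = 50L, sense_sample = 5L,
                       dynamics = dynamics_params(),
                       max_attempt_factor = 100L, seed = NULL) {
  stopifnot(length(input_genes) == 4, output_gene <= N,
            !(output_gene %in% input_genes), switch_every >= 1)
  structure(list(input_genes = as.integer(input_genes),
                 output_gene = as.integer(output_gene), N = as.integer(N),
                 s0 = s0, switch_every = as.integer(switch_every),
                 sensitivity_threshold = sensitivity_threshold,
                 M = as.integer(M), generations = as.integer(generations),
                 mu = mu, rho = rho, phi = phi, c0 = c0, alpha = alpha,
                 grid = grid, sense_grid = sense_grid,
                 sense_every = as.integer(sense_every),
                 sense_sample = as.integer(sense_sample),
                 dynamics = dynamics,
                 max_attempt_factor = as.integer(max_attempt_factor),
                 seed = seed),
            class = "mvg_config")
}

#' Fraction of correct input-output mappings for a logic goal
#'
#' Clamps the input genes to each of the 16 binary patterns, develops the
#' network, binarizes the output gene at 0.5 and compares with the goal's
#' truth table. Non-converged developments count as incorrect.
#'
#' @param W Genotype matrix.
#' @param goal `"G1"`, `"G2"`, or an explicit length-16 0/1 vector.
#' @param config An [mvg_config()] (its `s0` must be set, or pass `s0`).
#' @param s0 Initial expression state (overrides `config$s0`).
#' @return Fraction in `{0, 1/16, ..., 1}`.
#' @export
logic_goal_eval <- function(W, goal = "G1", config = mvg_config(), s0 = NULL) {
  validate_network(W)
  tt <- if (is.character(goal)) logic_goal(goal) else as.integer(goal)
  stopifnot(length(tt) == 16)
  if (is.null(s0)) s0 <- config$s0
  if (is.null(s0)) s0 <- rep(0.5, config$N)
  dyn <- config$dynamics
  out <- cpp_logic_outputs(W, as.numeric(s0), config$input_genes,
                           config$output_gene, logic_patterns(), dyn$gain,
                           dyn$max_steps, dyn$conv_tol, dyn$conv_window)
  mean(!is.na(out) & out == tt)
}

#' Run the single-population alternating-goal regimes
#'
#' `regime = "mvg"`: fitness is the fraction of correct mappings of the
#' current logic goal, goals alternating (G1, G2, G1, ...) every
#' `switch_every` generations; an interaction is *sensitive* when some grid
#' mutation makes the network match the alternate goal in more than
#' `16 * sensitivity_threshold` of the 16 mappings.
#'
#' `regime = "half_invert"` / `"full_invert"`: the population evolves under
#' stabilizing-type selection `exp(-D/alpha)` toward a target that
#' alternates every `switch_every` generations between the founder phenotype
#' and a version with half (respectively all) of the genes inverted;
#' sensitivity is the standard phenotype-inversion criterion (`SS_ij > 0`).
#'
#' @param config An [mvg_config()].
#' @param regime One of `"mvg"`, `"half_invert"`, `"full_invert"`.
#' @param progress Print progress lines.
#' @return A list of class `"mvg_trace"` with per-generation `mean_fitness`,
#'   the sensitivity `frequency` matrix (fraction of sweeps in which each
#'   interaction was sensitive in at least one sampled individual),
#'   `persistence` (the frequency histogram input: per-interaction
#'   frequencies as a vector), per-sweep records, and the `final` genomes.
#' @export
run_mvg <- function(config = mvg_config(),
                    regime = c("mvg", "half_invert", "full_invert"),
                    progress = FALSE) {
  regime <- match.arg(regime)
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$N
  dyn <- config$dynamics
  if (is.null(config$s0)) config$s0 <- as.numeric(stats::runif(N) < 0.5)
  s0 <- config$s0
  patterns <- logic_patterns()
  goals <- list(logic_goal("G1"), logic_goal("G2"))

  # founder: viable, and for the control regimes defines the targets
  founder <- NULL
  for (k in seq_len(1000L)) {
    W <- random_network(N, config$c0)
    dev <- develop(W, s0, dyn)
    if (dev$converged) { founder <- list(W = W, phen = dev$phenotype); break }
  }
  if (is.null(founder)) stop("no viable founder found", call. = FALSE)
  genomes <- matrix(rep(as.numeric(founder$W), config$M), ncol = config$M)
  phen <- matrix(rep(founder$phen, config$M), ncol = config$M)

  if (regime != "mvg") {
    t1 <- founder$phen
    t2 <- if (regime == "full_invert") 1 - t1
          else c(t1[seq_len(N %/% 2)], 1 - t1[(N %/% 2 + 1):N])
    targets <- list(t1, t2)
  }

  G <- config$generations
  mean_fitness <- numeric(G)
  sweeps <- list()
  freq_acc <- matrix(0, N, N)
  n_sweeps <- 0L
  for (g in seq_len(G)) {
    phase <- ((g - 1) %/% config$switch_every) %% 2 + 1
    if (regime == "mvg") {
      r <- cpp_evolve_logic_generation(genomes, s0, config$input_genes,
                                       config$output_gene, patterns,
                                       goals[[phase]], dyn$gain, dyn$max_steps,
                                       dyn$conv_tol, dyn$conv_window,
                                       config$mu * N, config$rho, config$phi,
                                       config$max_attempt_factor * config$M)
      if (r$accepted < config$M)
        stop("acceptance stall in MVG run", call. = FALSE)
      genomes <- r$genomes
      mean_fitness[g] <- mean(r$fitness)
    } else {
      r <- cpp_evolve_generation(genomes, matrix(targets[[phase]], ncol = 1),
                                 phen, s0, 1L, config$M, dyn$gain,
                                 dyn$max_steps, dyn$conv_tol, dyn$conv_window,
                                 config$mu * N, config$rho, config$phi, FALSE,
                                 config$alpha,
                                 config$max_attempt_factor * config$M, FALSE,
                                 FALSE)
      if (r$accepted < config$M)
        stop("acceptance stall in alternating-target run", call. = FALSE)
      genomes <- r$genomes
      phen <- r$phen
      mean_fitness[g] <- mean(r$fitness)
    }
    if (config$sense_every > 0 && g %% config$sense_every == 0) {
      idx <- sample.int(config$M, min(config$sense_sample, config$M))
      sens <- matrix(FALSE, N, N)
      for (k in idx) {
        Wk <- matrix(genomes[, k], N, N)
        sk <- if (regime == "mvg") {
          alt <- goals[[3 - phase]]
          cpp_mvg_sensitivity(Wk, s0, config$input_genes, config$output_gene,
                              patterns, alt, config$sense_grid$values,
                              as.integer(16 * config$sensitivity_threshold) + 1L,
                              dyn$gain, dyn$max_steps, dyn$conv_tol,
                              dyn$conv_window)
        } else {
          dref <- develop(Wk, s0, dyn)
          if (!dref$converged) matrix(FALSE, N, N)
          else network_sensitivity(Wk, s0, config$sense_grid,
                                   params = dyn)$ss > 0
        }
        sens <- sens | sk
      }
      freq_acc <- freq_acc + sens
      n_sweeps <- n_sweeps + 1L
      sweeps[[length(sweeps) + 1L]] <- list(generation = g, phase = phase,
                                            sensitive = sens)
      if (progress) message("sweep at generation ", g)
    }
  }
  freq <- if (n_sweeps) freq_acc / n_sweeps else freq_acc
  structure(list(config = config, regime = regime,
                 mean_fitness = mean_fitness, frequency = freq,
                 persistence = as.numeric(freq), sweeps = sweeps,
                 founder = founder, final = genomes),
            class = "mvg_trace")
}

#' @export
print.mvg_trace <- function(x, ...) {
  cat("mvg_trace:", x$regime, "regime,", length(x$mean_fitness),
      "generations;", sum(x$persistence == 1), "interaction(s) persistently",
      "sensitive\n")
  invisible(x)
}
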