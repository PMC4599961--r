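# Serialization: network matrices (CSV / JSON), run configuration (YAML),
# trace archives (directory of plain-text files), and deterministic fixtures
# shared by the examples and the test-suite.

#' Read a regulatory network matrix
#'
#' CSV files hold N rows x N columns of signed floats (no header); JSON files
#' hold a record `{"N": n, "W": [row-major values], "labels": [...]}`.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return N x N numeric matrix (with `dimnames` from JSON labels, if any).
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    W <- matrix(as.numeric(rec$W), rec$N, rec$N, byrow = TRUE)
    if (!is.null(rec$labels)) dimnames(W) <- list(rec$labels, rec$labels)
  } else {
    W <- as.matrix(data.table::fread(path, header = FALSE))
    dimnames(W) <- NULL
  }
  validate_network(W)
  W
}

#' Write a regulatory network matrix
#'
#' @param W Square numeric matrix.
#' @param path Destination; format chosen by extension (`.csv` or `.json`).
#' @export
write_network <- function(W, path) {
  validate_network(W)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- list(N = nrow(W), W = as.numeric(t(W)))
    if (!is.null(rownames(W))) rec$labels <- rownames(W)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17))
  } else {
    fwrite_mat(W, path)
  }
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the standard defaults of
#' [coevo_config()]. An empty file yields the full default configuration.
#'
#' @param path YAML file.
#' @return A [coevo_config()] object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(coevo_config))
  allowed <- setdiff(allowed, c("dynamics", "grid"))
  nested <- c("dynamics", "grid")
  unknown <- setdiff(names(raw), c(allowed, nested))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- raw[intersect(names(raw), allowed)]
  if (!is.null(raw$dynamics)) args$dynamics <- do.call(dynamics_params, raw$dynamics)
  if (!is.null(raw$grid)) args$grid <- do.call(sensitivity_grid, raw$grid)
  do.call(coevo_config, args)
}

#' Save a run configuration to YAML
#' @param config A [coevo_config()].
#' @param path Destination file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "coevo_config"))
  out <- unclass(config)
  out$dynamics <- unclass(out$dynamics)
  out$grid <- unclass(out$grid)[c("L", "delta", "sigma")]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic fixtures for examples and tests
#'
#' * `founder`: a random viable N = 10 founder network (list with `W`, `s0`).
#' * `toggle_switch`: 2-gene mutual repression with self-activation; bistable
#'   (binary steady state depends on `s0`).
#' * `oscillator`: a 2-gene negative feedback loop (activation/repression);
#'   its state cycles and never reaches a steady state.
#' * `two_triangle_graph`: 6-gene network whose interaction graph is two
#'   disjoint triangles (modularity of the triangle partition = 0.5).
#' * `mvg_perfect_g1`: 10-gene logic network (inputs 1-4, bias gene 5,
#'   output 10) computing `(X XOR Y) OR (Z XOR W)` exactly.
#'
#' @param kind Fixture name.
#' @param seed Seed used for the random fixtures (fixed default makes every
#'   call reproducible).
#' @return A list with at least `W`; `s0` where meaningful.
#' @export
make_fixture <- function(kind = c("founder", "toggle_switch", "oscillator",
                                  "two_triangle_graph", "mvg_perfect_g1"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    founder = {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      repeat {
        W <- random_network(10L, 0.5)
        s0 <- as.numeric(stats::runif(10) < 0.5)
        if (develop(W, s0)$converged) return(list(W = W, s0 = s0))
      }
    },
    toggle_switch = {
      W <- matrix(c(3, -3, -3, 3), 2, 2, byrow = TRUE)
      list(W = W, s0 = c(1, 0))
    },
    oscillator = {
      W <- matrix(0, 2, 2)
      W[1, 2] <- -10
      W[2, 1] <- 10
      list(W = W, s0 = c(1, 0))
    },
    two_triangle_graph = {
      W <- matrix(0, 6, 6)
      for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
        W[e[1], e[2]] <- 1
      list(W = W)
    },
    mvg_perfect_g1 = {
      W <- matrix(0, 10, 10)
      # gene 5 is the bias source: self-locked ON, contributes +1 (centered)
      W[5, 5] <- 5
      W[6, 1] <- -1; W[6, 2] <- -1; W[6, 5] <- 1    # NAND(X, Y)
      W[7, 1] <- 1;  W[7, 2] <- 1;  W[7, 5] <- 1    # OR(X, Y)
      W[8, 3] <- -1; W[8, 4] <- -1; W[8, 5] <- 1    # NAND(Z, W)
      W[9, 3] <- 1;  W[9, 4] <- 1;  W[9, 5] <- 1    # OR(Z, W)
      # out = XOR(X,Y) OR XOR(Z,W): on reachable gate states, true iff
      # y_n1 + y_o1 + y_n2 + y_o2 >= 2 (centered +/-1 values)
      W[10, 6:9] <- 1; W[10, 5] <- -1
      list(W = W, s0 = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
    })
}

# --- trace archives --------------------------------------------------------

# %.17g guarantees bit-exact double round trips through the text archive
fwrite_mat <- function(m, path) {
  m <- as.matrix(m)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = ",")), path)
}

fread_mat <- function(path, mode = "double") {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- mode
  m
}

#' Save a coevolution trace to a directory archive
#'
#' Writes plain-text files only: `config.yaml`, per-species founder/`s0`
#' CSVs, per-generation summaries (mean expression, parent indices, attempt
#' counts, densities), the mutation event log, scheduled measurements,
#' diversity series, sampled SS matrices, final-population genomes and
#' (when stored) per-generation phenotype matrices. The archive round-trips
#' through [load_trace()] with full double precision.
#'
#' @param trace A `coevo_trace`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_trace <- function(trace, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  save_config(trace$config, file.path(path, "config.yaml"))
  writeLines(as.character(trace$generations), file.path(path, "generations.txt"))
  for (sp in c("host", "parasite")) {
    rec <- trace[[sp]]
    d <- file.path(path, sp)
    dir.create(d, showWarnings = FALSE)
    fwrite_mat(rec$founder, file.path(d, "founder.csv"))
    fwrite_mat(matrix(rec$s0, nrow = 1), file.path(d, "s0.csv"))
    fwrite_mat(matrix(rec$founder_phenotype, nrow = 1),
               file.path(d, "founder_phenotype.csv"))
    fwrite_mat(rec$mean_expr, file.path(d, "mean_expression.csv"))
    fwrite_mat(rec$parents, file.path(d, "parents.csv"))
    if (!is.null(rec$parents2))
      fwrite_mat(rec$parents2, file.path(d, "parents2.csv"))
    fwrite_mat(cbind(attempts = rec$attempts, density = rec$density,
                     mean_fitness = rec$mean_fitness),
               file.path(d, "per_generation.csv"))
    ev <- do.call(rbind, lapply(seq_along(rec$events), function(g) {
      e <- rec$events[[g]]
      if (is.null(e) || nrow(e) == 0) return(NULL)
      cbind(generation = g, e)
    }))
    if (is.null(ev)) ev <- matrix(numeric(0), 0, 6)
    if (nrow(ev)) fwrite_mat(ev, file.path(d, "events.csv"))
    else writeLines(character(0), file.path(d, "events.csv"))
    if (!is.null(rec$phen)) {
      pd <- file.path(d, "phenotypes")
      dir.create(pd, showWarnings = FALSE)
      for (g in seq_along(rec$phen))
        fwrite_mat(rec$phen[[g]], file.path(pd, sprintf("gen%06d.csv", g)))
    }
    fwrite_mat(trace$final[[sp]]$genomes, file.path(d, "final_genomes.csv"))
    fwrite_mat(trace$final[[sp]]$phen, file.path(d, "final_phenotypes.csv"))
  }
  if (!is.null(trace$measurements))
    data.table::fwrite(trace$measurements, file.path(path, "measurements.csv"))
  if (!is.null(trace$diversity))
    data.table::fwrite(trace$diversity, file.path(path, "diversity.csv"))
  if (length(trace$ss_samples)) {
    sd_ <- file.path(path, "profiles")
    dir.create(sd_, showWarnings = FALSE)
    for (k in seq_along(trace$ss_samples)) {
      s <- trace$ss_samples[[k]]
      for (m in seq_along(s$ss))
        fwrite_mat(s$ss[[m]],
                   file.path(sd_, sprintf("g%06d_%s_%03d.csv", s$generation,
                                          s$species, m)))
    }
    meta <- do.call(rbind, lapply(trace$ss_samples, function(s)
      data.frame(generation = s$generation, species = s$species,
                 indices = paste(s$indices, collapse = " "))))
    data.table::fwrite(meta, file.path(sd_, "index.csv"))
  }
  invisible(path)
}

#' Load a coevolution trace archive
#'
#' Reconstructs a `coevo_trace` from a [save_trace()] directory. Archives
#' written without phenotypes (or with a missing optional component) load
#' with that component `NULL`; downstream analyses that need it fail with a
#' clear message.
#'
#' @param path Archive directory.
#' @return A `coevo_trace`.
#' @export
load_trace <- function(path) {
  config <- load_config(file.path(path, "config.yaml"))
  G <- as.integer(readLines(file.path(path, "generations.txt")))
  out <- list(config = config, generations = G)
  final <- list()
  for (sp in c("host", "parasite")) {
    d <- file.path(path, sp)
    M <- if (sp == "host") config$M_host else config$M_parasite
    ev_raw <- tryCatch(as.matrix(data.table::fread(file.path(d, "events.csv"),
                                                   header = FALSE)),
                       error = function(e) matrix(numeric(0), 0, 6))
    events <- vector("list", G)
    for (g in seq_len(G)) events[[g]] <- matrix(numeric(0), 0, 5,
      dimnames = list(NULL, c("child", "i", "j", "old", "new")))
    if (nrow(ev_raw)) {
      colnames(ev_raw) <- c("generation", "child", "i", "j", "old", "new")
      for (g in unique(ev_raw[, "generation"]))
        events[[g]] <- ev_raw[ev_raw[, "generation"] == g, -1, drop = FALSE]
    }
    pg <- fread_mat(file.path(d, "per_generation.csv"))
    phen_dir <- file.path(d, "phenotypes")
    phen <- NULL
    if (dir.exists(phen_dir)) {
      phen <- lapply(seq_len(G), function(g)
        fread_mat(file.path(phen_dir, sprintf("gen%06d.csv", g))))
    }
    p2path <- file.path(d, "parents2.csv")
    rec <- list(founder = fread_mat(file.path(d, "founder.csv")),
                s0 = as.numeric(fread_mat(file.path(d, "s0.csv"))),
                founder_phenotype =
                  as.numeric(fread_mat(file.path(d, "founder_phenotype.csv"))),
                mean_expr = fread_mat(file.path(d, "mean_expression.csv")),
                parents = fread_mat(file.path(d, "parents.csv"), "integer"),
                parents2 = if (file.exists(p2path)) fread_mat(p2path, "integer"),
                events = events,
                attempts = as.integer(pg[, 1]),
                density = as.numeric(pg[, 2]),
                mean_fitness = as.numeric(pg[, 3]),
                phen = phen,
                snapshots = list())
    out[[sp]] <- rec
    genomes <- fread_mat(file.path(d, "final_genomes.csv"))
    final[[sp]] <- structure(list(genomes = genomes,
                                  phen = fread_mat(file.path(d, "final_phenotypes.csv")),
                                  species = sp, s0 = rec$s0, N = config$N,
                                  M = M, founder = rec$founder),
                             class = "coevo_population")
  }
  out$final <- final
  mpath <- file.path(path, "measurements.csv")
  out$measurements <- if (file.exists(mpath))
    as.data.frame(data.table::fread(mpath))
  dpath <- file.path(path, "diversity.csv")
  out$diversity <- if (file.exists(dpath))
    as.data.frame(data.table::fread(dpath))
  out$ss_samples <- list()
  idx_path <- file.path(path, "profiles", "index.csv")
  if (file.exists(idx_path)) {
    meta <- as.data.frame(data.table::fread(idx_path))
    for (r in seq_len(nrow(meta))) {
      idx <- as.integer(strsplit(meta$indices[r], " ")[[1]])
      ss <- lapply(seq_along(idx), function(m)
        fread_mat(file.path(path, "profiles",
                            sprintf("g%06d_%s_%03d.csv", meta$generation[r],
                                    meta$species[r], m))))
      out$ss_samples[[r]] <- list(generation = meta$generation[r],
                                  species = meta$species[r], indices = idx,
                                  ss = ss)
    }
  }
  structure(out, class = "coevo_trace")
}
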