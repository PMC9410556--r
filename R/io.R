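#' Deterministic per-run seed derivation
#'
#' SplitMix-style integer hashing of (base seed, batch, run), so that every
#' run of a batch design gets an independent, reproducible seed without a
#' shared stream.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param base_seed integer base seed.
#' @param batch,run 1-based indices.
#' @return An integer seed.
#' @export
deriveSeed <- function(base_seed, batch, run) {
  # 64-bit-safe mixing in double arithmetic (all intermediates < 2^53)
  x <- (as.numeric(base_seed) %% 2147483647) * 69069 +
    as.numeric(batch) * 1234567 + as.numeric(run) * 97
  x <- (x * 48271) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

#' Run a seeded batch design of simulations
#'
#' Runs `n_batches * runs_per_batch` simulations with per-run seeds derived
#' from `base_seed` via [deriveSeed()], and aggregates pattern statistics
#' per batch at the requested times.  Optionally writes one trajectory CSV
#' per run, one summary CSV, and a JSON manifest (full configuration,
#' parameters, mutant, seeds and file inventory) from which the outputs can
#' be regenerated exactly.
#'
#' @param config a [SimulationConfig] object.
#' @param params a [ModelParameters] object.
#' @param mutant a [MutantSpec] overlay.
#' @param noise a [NoiseSettings] template (its seed is replaced per run).
#' @param n_batches,runs_per_batch batch design (default 15 x 10).
#' @param base_seed integer base seed.
#' @param times_h ages at which to compute batch statistics (defaults to
#'   the final time).
#' @param out_dir if non-NULL, directory to write CSVs and the manifest.
#' @return A list with `trajectories`, `batch` (index per trajectory), and
#'   `stats` (a list of [BatchResult], one per requested time).
#' @export
runBatch <- function(config, params, mutant = mutantSpec("WT"),
                     noise = noiseSettings(), n_batches = 15L,
                     runs_per_batch = 10L, base_seed = 1L,
                     times_h = config@t_end, out_dir = NULL) {
  stopifnot(n_batches >= 1L, runs_per_batch >= 1L)
  trajs <- vector("list", n_batches * runs_per_batch)
  batch <- integer(length(trajs))
  seeds <- integer(length(trajs))
  i <- 0L
  for (b in seq_len(n_batches)) {
    for (r in seq_len(runs_per_batch)) {
      i <- i + 1L
      seeds[i] <- deriveSeed(base_seed, b, r)
      batch[i] <- b
      trajs[[i]] <- runSimulation(config, params, mutant,
        noiseSettings(noise@omega_phi, noise@omega_lambda, seeds[i]))
    }
  }
  stats <- lapply(times_h, function(t)
    batchStatistics(trajs, t, batch = batch))
  names(stats) <- paste0("t", times_h)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (j in seq_along(trajs)) {
      fn <- file.path(out_dir,
                      sprintf("trajectory_b%02d_r%02d.csv", batch[j],
                              ((j - 1L) %% runs_per_batch) + 1L))
      utils::write.csv(trajectoryAsDataFrame(trajs[[j]]), fn,
                       row.names = FALSE)
      files <- c(files, fn)
    }
    sm <- do.call(rbind, lapply(seq_along(stats), function(k) {
      s <- stats[[k]]
      data.frame(condition = mutant@label, time_h = s@time_h,
                 batch = s@per_batch$batch,
                 m = s@per_batch$m, p = s@per_batch$p,
                 terminal = s@per_batch$terminal,
                 mean_R_veg = s@per_batch$mean_R_veg)
    }))
    sum_fn <- file.path(out_dir, "summary.csv")
    utils::write.csv(sm, sum_fn, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("HetPattern")),
      base_seed = base_seed, n_batches = n_batches,
      runs_per_batch = runs_per_batch, seeds = seeds,
      mutant = .mutantToList(mutant), noise = .noiseToList(noise),
      simulation = .configToList(config), parameters = .paramsToList(params),
      files = c(files, sum_fn))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trajectories = trajs, batch = batch, stats = stats)
}

.paramsToList <- function(p) {
  nms <- slotNames("ModelParameters")
  stats::setNames(lapply(nms, function(nm) slot(p, nm)), nms)
}

.noiseToList <- function(ns) list(omega_phi = ns@omega_phi,
                                  omega_lambda = ns@omega_lambda,
                                  seed = ns@seed)

.configToList <- function(cf) list(
  dt = cf@dt, t_end = cf@t_end, record_every = cf@record_every,
  n_initial_cells = cf@n_initial_cells,
  initial_size_policy = cf@initial_size_policy,
  initial_concentration_policy = cf@initial_concentration_policy)

.mutantToList <- function(m) list(
  rho_S_factor = m@rho_S_factor, rho_N_factor = m@rho_N_factor,
  rho_A_factor = m@rho_A_factor, beta_F_factor = m@beta_F_factor,
  d_border_factor = m@d_border_factor, label = m@label)

#' Save the full run configuration to a YAML file
#'
#' Writes four sections -- `parameters`, `noise`, `simulation`, `mutant` --
#' whose keys are the model symbol names.  [loadConfig()] restores
#' identical objects.
#'
#' @param path output file path.
#' @param params a [ModelParameters] object.
#' @param noise a [NoiseSettings] object.
#' @param config a [SimulationConfig] object.
#' @param mutant a [MutantSpec] object.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(path, params, noise = noiseSettings(),
                       config = simulationConfig(),
                       mutant = mutantSpec("WT")) {
  yaml::write_yaml(list(parameters = .paramsToList(params),
                        noise = .noiseToList(noise),
                        simulation = .configToList(config),
                        mutant = .mutantToList(mutant)), path)
  invisible(path)
}

.checkKeys <- function(got, expected, section) {
  unknown <- setdiff(got, expected)
  missing <- setdiff(expected, got)
  msgs <- character(0)
  if (length(unknown))
    msgs <- c(msgs, paste0("unknown key(s) in '", section, "': ",
                           paste(unknown, collapse = ", ")))
  if (length(missing))
    msgs <- c(msgs, paste0("missing key(s) in '", section, "': ",
                           paste(missing, collapse = ", ")))
  msgs
}

#' Load a run configuration from a YAML file
#'
#' Validates that every section contains exactly the expected keys
#' (unknown or missing keys raise an error listing the offenders) and that
#' the values satisfy the class invariants.
#'
#' @param path YAML file written by [saveConfig()].
#' @return A list with elements `params`, `noise`, `config`, `mutant`.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  msgs <- .checkKeys(names(raw),
                     c("parameters", "noise", "simulation", "mutant"),
                     "top level")
  if (!length(msgs)) {
    msgs <- c(
      .checkKeys(names(raw$parameters), slotNames("ModelParameters"),
                 "parameters"),
      .checkKeys(names(raw$noise), c("omega_phi", "omega_lambda", "seed"),
                 "noise"),
      .checkKeys(names(raw$simulation),
                 c("dt", "t_end", "record_every", "n_initial_cells",
                   "initial_size_policy", "initial_concentration_policy"),
                 "simulation"),
      .checkKeys(names(raw$mutant),
                 c("rho_S_factor", "rho_N_factor", "rho_A_factor",
                   "beta_F_factor", "d_border_factor", "label"),
                 "mutant"))
  }
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  pl <- raw$parameters
  params <- do.call(modelParameters,
                    c(pl[setdiff(names(pl), character(0))],
                      list(check_M_R = FALSE)))
  noise <- noiseSettings(raw$noise$omega_phi, raw$noise$omega_lambda,
                         raw$noise$seed)
  config <- do.call(simulationConfig, raw$simulation)
  m <- raw$mutant
  mutant <- new("MutantSpec", rho_S_factor = m$rho_S_factor,
                rho_N_factor = m$rho_N_factor,
                rho_A_factor = m$rho_A_factor,
                beta_F_factor = m$beta_F_factor,
                d_border_factor = m$d_border_factor, label = m$label)
  list(params = params, noise = noise, config = config, mutant = mutant)
}
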