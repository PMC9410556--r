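.refKey <- function(condition, time_h) paste0(condition, "@", time_h)

#' Construct a ReferenceDataset
#'
#' @param entries list of entries, each a list with fields `condition`,
#'   `time_h`, `group` ("O" or "N"), `sample` (numeric vector), `m`, `p`.
#' @return A [ReferenceDataset] object.
#' @export
referenceDataset <- function(entries) {
  names(entries) <- vapply(entries, function(e)
    .refKey(e$condition, e$time_h), character(1))
  new("ReferenceDataset", entries = entries)
}

#' Construct EnergyWeights
#'
#' @param w1,w2,w3,w4 non-negative weights; defaults (1000, 10, 500, 1).
#' @return An [EnergyWeights] object.
#' @export
energyWeights <- function(w1 = 1000, w2 = 10, w3 = 500, w4 = 1) {
  new("EnergyWeights", w1 = w1, w2 = w2, w3 = w3, w4 = w4)
}

## KS distance robust to degenerate simulated samples during calibration:
## an empty simulated sample against a nonempty reference counts as the
## maximal distance 1; two empty samples count as 0.
.ksSafe <- function(ref, sim) {
  if (!length(ref) && !length(sim)) return(0)
  if (!length(ref) || !length(sim)) return(1)
  ksDistance(ref, sim)
}

#' Calibration energy comparing simulated and reference statistics
#'
#' For every reference entry the simulated statistics for the same
#' condition and time are compared.  "O"-group entries contribute
#' `w1 * KS^2 + w2 * ((m_ref - m_sim)^2 + (p_ref - p_sim)^2)`; "N"-group
#' entries contribute `w3 * KS^2 + w4 * p_sim` (any heterocysts at all are
#' penalized in the patA backgrounds).  If the simulated wild type formed
#' no heterocysts, a rescue term `(mean_R_WT - T_R)^2` pushes the mean
#' vegetative HetR of the wild type toward the commitment threshold so
#' that heterocyst-forming parameter regions stay reachable.
#'
#' A simulated entry with no intervals scores the maximal KS distance 1 and
#' an `m_sim` of 0.
#'
#' @param sim named list keyed like the reference entries
#'   (`"condition@time"`), each element a list with `sample`, `m`, `p`.
#' @param ref a [ReferenceDataset] object.
#' @param weights an [EnergyWeights] object.
#' @param mean_R_WT time-averaged mean vegetative HetR of the simulated
#'   wild type (used only by the rescue term).
#' @param T_R the commitment threshold.
#' @param wt_has_heterocysts did the simulated wild type form any
#'   heterocysts?
#' @return The energy, a single number >= 0.
#' @export
patternEnergy <- function(sim, ref, weights = energyWeights(),
                          mean_R_WT, T_R, wt_has_heterocysts = TRUE) {
  stopifnot(is(ref, "ReferenceDataset"), is(weights, "EnergyWeights"))
  E <- 0
  for (key in names(ref@entries)) {
    e <- ref@entries[[key]]
    s <- sim[[key]]
    if (is.null(s))
      stop("patternEnergy: no simulated statistics for reference entry '",
           key, "'")
    ks <- .ksSafe(e$sample, s$sample)
    if (e$group == "O") {
      m_sim <- if (is.finite(s$m)) s$m else 0
      E <- E + weights@w1 * ks^2 +
        weights@w2 * ((e$m - m_sim)^2 + (e$p - s$p)^2)
    } else {
      E <- E + weights@w3 * ks^2 + weights@w4 * s$p
    }
  }
  if (!wt_has_heterocysts) E <- E + (mean_R_WT - T_R)^2
  E
}

#' Custom simulated annealing in log-parameter space
#'
#' Metropolis acceptance `exp(-dE/T)` under a geometric cooling schedule.
#' Each proposal multiplies one randomly chosen free parameter by
#' `exp(N(0, sigma^2))`, which keeps parameters positive.  The best-ever
#' parameter set is returned.  Proposals whose objective is non-finite are
#' rejected and counted.  Reproducible from `seed`.
#'
#' @param objective function mapping a parameter object to a finite energy;
#'   takes either a [ModelParameters] or a named numeric vector, matching
#'   `initial`.
#' @param initial starting point: a [ModelParameters] object or a named
#'   numeric vector.
#' @param free_params character vector of parameter names to vary.  The
#'   six manually set parameters (`K_d`, `lam`, `M_Lambda`, `T_R`, `M_R`,
#'   `T_min`) are excluded by default when `initial` is a
#'   [ModelParameters].
#' @param schedule list with elements `sigma` (proposal width in log space,
#'   default 0.1), `cooling` (geometric factor, default 0.98), `cool_every`
#'   (proposals per temperature stage, default 50), `n_proposals` (default
#'   5000), `T0` (initial temperature, default 1).
#' @param seed integer RNG seed.
#' @return list with `best` (parameter object), `best_energy`, `trace`
#'   (energy of the current state after every proposal), `accepted`,
#'   `rejected_nonfinite`.
#' @export
simulatedAnnealing <- function(objective, initial, free_params = NULL,
                               schedule = list(), seed = 1L) {
  sch <- utils::modifyList(list(sigma = 0.1, cooling = 0.98,
                                cool_every = 50L, n_proposals = 5000L,
                                T0 = 1), schedule)
  set.seed(seed)
  isS4par <- is(initial, "ModelParameters")
  if (is.null(free_params)) {
    free_params <- if (isS4par) {
      setdiff(slotNames(initial),
              c("K_d", "lam", "M_Lambda", "T_R", "M_R", "T_min",
                "hill_exponent"))
    } else names(initial)
  }
  getp <- if (isS4par) function(x, nm) slot(x, nm) else
    function(x, nm) x[[nm]]
  setp <- if (isS4par) function(x, nm, v) { slot(x, nm) <- v; x } else
    function(x, nm, v) { x[[nm]] <- v; x }

  # Objectives that run simulations reseed the global RNG internally
  # (runSimulation is reproducible by design); snapshot and restore the
  # annealer's own stream around every evaluation so proposals stay i.i.d.
  evalE <- function(p) {
    rs <- get(".Random.seed", envir = globalenv())
    v <- tryCatch(objective(p), error = function(e) NaN)
    assign(".Random.seed", rs, envir = globalenv())
    v
  }

  cur <- initial
  curE <- evalE(cur)
  if (!is.finite(curE)) stop("objective is non-finite at the initial point")
  best <- cur; bestE <- curE
  temp <- sch$T0
  trace <- numeric(sch$n_proposals)
  acc <- 0L; badobj <- 0L
  n <- as.integer(sch$n_proposals)
  for (i in seq_len(n)) {
    nm <- free_params[[sample.int(length(free_params), 1L)]]
    prop <- setp(cur, nm, getp(cur, nm) * exp(stats::rnorm(1, 0, sch$sigma)))
    propE <- evalE(prop)
    if (is.finite(propE)) {
      dE <- propE - curE
      accept <- dE <= 0 ||
        (temp > 0 && stats::runif(1) < exp(-dE / temp))
      if (accept) {
        cur <- prop; curE <- propE; acc <- acc + 1L
        if (curE < bestE) { best <- cur; bestE <- curE }
      }
    } else badobj <- badobj + 1L
    trace[i] <- curE
    if (i %% sch$cool_every == 0L) temp <- temp * sch$cooling
  }
  list(best = best, best_energy = bestE, trace = trace,
       accepted = acc, rejected_nonfinite = badobj)
}

#' Relative sensitivity of an observable to one parameter
#'
#' Evaluates the observable at the baseline parameters and at the
#' parameters with `X` scaled by `1 + frac`, averaging over the given
#' seeds, and returns `S = (dY/Y) / (dX/X)`.
#'
#' @param params a [ModelParameters] object.
#' @param X name of the parameter to perturb.
#' @param frac relative perturbation (nonzero; 0.1 means +10\%).
#' @param evaluator function `(params, seed) -> numeric` computing the
#'   observable (for simulation observables, see
#'   [meanIntervalEvaluator()]).
#' @param seeds integer vector of seeds to average over.
#' @param observable_name label stored in the result.
#' @return A [SensitivityResult]; `S` is `NA` when the baseline observable
#'   is zero.
#' @export
parameterSensitivity <- function(params, X, frac, evaluator,
                                 seeds = 1L, observable_name = "Y") {
  stopifnot(is(params, "ModelParameters"), frac != 0,
            X %in% slotNames(params))
  x0 <- slot(params, X)
  pert <- params
  slot(pert, X) <- x0 * (1 + frac)
  y0 <- mean(vapply(seeds, function(s) evaluator(params, s), numeric(1)))
  y1 <- mean(vapply(seeds, function(s) evaluator(pert, s), numeric(1)))
  S <- if (y0 == 0) NA_real_ else ((y1 - y0) / y0) / frac
  new("SensitivityResult", parameter = X, baseline_X = x0,
      perturbed_X = x0 * (1 + frac), frac = frac,
      observable = observable_name, baseline_Y = y0, perturbed_Y = y1,
      S = S)
}

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("Sensitivity of %s to %s (%+.0f%%): S = %.3g\n",
              object@observable, object@parameter, 100 * object@frac,
              object@S))
  invisible(object)
})

#' Evaluator of the mean vegetative interval for sensitivity analysis
#'
#' Returns a closure `(params, seed) -> mean interval` that runs one
#' simulation under the given configuration and measures the mean
#' vegetative interval at `time_h`.
#'
#' @param config a [SimulationConfig].
#' @param mutant a [MutantSpec] (default wild type).
#' @param noise a [NoiseSettings] template (its seed is replaced per call).
#' @param time_h filament age at which to measure (h), default 72.
#' @return A function `(params, seed) -> numeric`.
#' @export
meanIntervalEvaluator <- function(config, mutant = mutantSpec("WT"),
                                  noise = noiseSettings(), time_h = 72) {
  force(config); force(mutant); force(noise); force(time_h)
  function(params, seed) {
    ns <- noiseSettings(noise@omega_phi, noise@omega_lambda, seed)
    tr <- runSimulation(config, params, mutant, ns)
    iv <- vegetativeIntervals(snapshotAt(tr, time_h))
    if (length(iv)) mean(iv) else 0
  }
}

#' Build a synthetic reference dataset from simulations
#'
#' Runs the simulator for the requested conditions and times and packages
#' the pooled pattern statistics in the reference-dataset schema, so the
#' calibration machinery can be exercised without external data.
#'
#' @param params a [ModelParameters] object.
#' @param config a [SimulationConfig] object.
#' @param conditions named list mapping condition label to a [MutantSpec].
#' @param times_h numeric vector of filament ages (h).
#' @param groups named character vector mapping condition label to "O" or
#'   "N" (default: conditions whose label contains "patA" go to "N").
#' @param n_runs simulations pooled per condition.
#' @param noise a [NoiseSettings] template.
#' @param base_seed base seed; per-run seeds are derived deterministically.
#' @return A [ReferenceDataset].
#' @export
referenceFromSimulations <- function(params, config, conditions, times_h,
                                     groups = NULL, n_runs = 10,
                                     noise = noiseSettings(),
                                     base_seed = 1L) {
  if (is.null(groups)) {
    groups <- ifelse(grepl("patA", names(conditions)), "N", "O")
    names(groups) <- names(conditions)
  }
  entries <- list()
  for (cond in names(conditions)) {
    trajs <- lapply(seq_len(n_runs), function(r)
      runSimulation(config, params, conditions[[cond]],
                    noiseSettings(noise@omega_phi, noise@omega_lambda,
                                  deriveSeed(base_seed, match(cond, names(conditions)), r))))
    for (t in times_h) {
      fs <- lapply(trajs, snapshotAt, time_h = t)
      iv <- unlist(lapply(fs, vegetativeIntervals))
      nhet <- sum(vapply(fs, function(f) sum(f@het), numeric(1)))
      ncell <- sum(vapply(fs, nCells, numeric(1)))
      entries[[length(entries) + 1L]] <- list(
        condition = cond, time_h = t, group = unname(groups[cond]),
        sample = as.numeric(iv),
        m = if (length(iv)) mean(iv) else NA_real_,
        p = 100 * nhet / ncell)
    }
  }
  referenceDataset(entries)
}

#' Simulated statistics in the shape patternEnergy() expects
#'
#' Convenience companion to [referenceFromSimulations()]: runs the same
#' conditions and times and returns the named list consumed by the `sim`
#' argument of [patternEnergy()].
#'
#' @inheritParams referenceFromSimulations
#' @return Named list keyed `"condition@time"`.
#' @export
simulatedStatistics <- function(params, config, conditions, times_h,
                                n_runs = 10, noise = noiseSettings(),
                                base_seed = 1L) {
  ref <- referenceFromSimulations(params, config, conditions, times_h,
                                  n_runs = n_runs, noise = noise,
                                  base_seed = base_seed)
  lapply(ref@entries, function(e) list(sample = e$sample, m = e$m, p = e$p))
}

#' Write a reference dataset to CSV
#'
#' Long format with columns `condition`, `time_h`, `group`, `kind`,
#' `interval_length`, `count`, `value`: one `interval` row per histogram
#' bin and one `m` and one `p` row per (condition, time).
#'
#' @param ref a [ReferenceDataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceCSV <- function(ref, path) {
  stopifnot(is(ref, "ReferenceDataset"))
  rows <- lapply(ref@entries, function(e) {
    h <- table(e$sample)
    hist_df <- if (length(h)) data.frame(
      condition = e$condition, time_h = e$time_h, group = e$group,
      kind = "interval", interval_length = as.numeric(names(h)),
      count = as.numeric(h), value = NA_real_) else NULL
    rbind(hist_df,
          data.frame(condition = e$condition, time_h = e$time_h,
                     group = e$group, kind = c("m", "p"),
                     interval_length = NA_real_, count = NA_real_,
                     value = c(e$m, e$p)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a reference dataset from CSV
#'
#' Inverse of [writeReferenceCSV()]; interval histograms are expanded back
#' into samples.
#'
#' @param path CSV file path.
#' @return A [ReferenceDataset].
#' @export
readReferenceCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_h", "group", "kind", "interval_length",
            "count", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("reference CSV is missing columns: ",
         paste(missing, collapse = ", "))
  keys <- unique(df[, c("condition", "time_h", "group")])
  entries <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$condition == keys$condition[i] &
              df$time_h == keys$time_h[i], ]
    hist <- sub[sub$kind == "interval", ]
    list(condition = keys$condition[i], time_h = keys$time_h[i],
         group = keys$group[i],
         sample = rep(hist$interval_length, hist$count),
         m = sub$value[sub$kind == "m"][1],
         p = sub$value[sub$kind == "p"][1])
  })
  referenceDataset(entries)
}
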