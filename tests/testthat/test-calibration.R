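refEntry <- function(condition, time_h, group, sample, m = mean(sample),
                     p = 10) {
  list(condition = condition, time_h = time_h, group = group,
       sample = sample, m = m, p = p)
}

simEntry <- function(sample, m = mean(sample), p = 10) {
  list(sample = sample, m = m, p = p)
}

test_that("patternEnergy is exactly zero on a perfect match", {
  ref <- referenceDataset(list(
    refEntry("WT", 48, "O", c(8, 10, 12), p = 10),
    refEntry("dpatA", 48, "N", numeric(0), m = 0, p = 0)))
  sim <- list("WT@48" = simEntry(c(8, 10, 12), p = 10),
              "dpatA@48" = simEntry(numeric(0), m = 0, p = 0))
  expect_equal(patternEnergy(sim, ref, mean_R_WT = 0.5, T_R = 1), 0)
})

test_that("a single mismatched moment contributes w2 * delta^2", {
  ref <- referenceDataset(list(refEntry("WT", 48, "O", c(8, 10, 12),
                                        m = 10, p = 10)))
  # identical sample (KS = 0), identical p, m off by delta
  delta <- 0.7
  sim <- list("WT@48" = simEntry(c(8, 10, 12), m = 10 + delta, p = 10))
  w <- energyWeights()
  expect_equal(patternEnergy(sim, ref, weights = w, mean_R_WT = 1, T_R = 1),
               w@w2 * delta^2)
})

test_that("N-group entries penalize KS and heterocyst percentage", {
  ref <- referenceDataset(list(refEntry("dpatA", 48, "N", numeric(0),
                                        m = 0, p = 0)))
  w <- energyWeights()
  # empty reference vs nonempty simulated sample: maximal KS distance 1
  sim <- list("dpatA@48" = simEntry(c(5, 6), p = 3))
  expect_equal(patternEnergy(sim, ref, weights = w, mean_R_WT = 1, T_R = 1),
               w@w3 * 1 + w@w4 * 3)
})

test_that("the no-heterocyst rescue term pulls mean HetR to the threshold", {
  ref <- referenceDataset(list(refEntry("WT", 48, "O", c(8, 10), p = 10)))
  sim <- list("WT@48" = simEntry(c(8, 10), p = 10))
  e0 <- patternEnergy(sim, ref, mean_R_WT = 0.4, T_R = 1,
                      wt_has_heterocysts = TRUE)
  e1 <- patternEnergy(sim, ref, mean_R_WT = 0.4, T_R = 1,
                      wt_has_heterocysts = FALSE)
  expect_equal(e1 - e0, (0.4 - 1)^2)
})

test_that("patternEnergy requires simulated statistics for every entry", {
  ref <- referenceDataset(list(refEntry("WT", 48, "O", c(8, 10))))
  expect_error(patternEnergy(list(), ref, mean_R_WT = 1, T_R = 1),
               "WT@48")
})

test_that("patternEnergy is invariant to entry order", {
  e1 <- refEntry("WT", 24, "O", c(9, 11), p = 8)
  e2 <- refEntry("WT", 48, "O", c(8, 12), p = 12)
  sim <- list("WT@24" = simEntry(c(10, 10), p = 9),
              "WT@48" = simEntry(c(9, 9), p = 11))
  a <- patternEnergy(sim, referenceDataset(list(e1, e2)),
                     mean_R_WT = 1, T_R = 1)
  b <- patternEnergy(sim, referenceDataset(list(e2, e1)),
                     mean_R_WT = 1, T_R = 1)
  expect_equal(a, b)
})

test_that("simulatedAnnealing recovers the minimum of a smooth objective", {
  obj <- function(x) (log(x[["a"]]) - log(2))^2 + (log(x[["b"]]) + 1)^2
  out <- simulatedAnnealing(obj, c(a = 20, b = 3),
                            schedule = list(n_proposals = 3000L,
                                            sigma = 0.15),
                            seed = 4L)
  expect_lt(out$best_energy, 1e-3)
  expect_equal(out$best[["a"]], 2, tolerance = 0.05)
  expect_equal(out$best[["b"]], exp(-1), tolerance = 0.05)
  expect_length(out$trace, 3000L)
})

test_that("simulatedAnnealing with zero proposals returns the initial point", {
  obj <- function(x) x[["a"]]^2
  out <- simulatedAnnealing(obj, c(a = 3),
                            schedule = list(n_proposals = 0L), seed = 1L)
  expect_equal(out$best, c(a = 3))
  expect_equal(out$best_energy, 9)
  expect_equal(out$accepted, 0L)
})

test_that("at zero temperature the trace is non-increasing (greedy descent)", {
  obj <- function(x) (x[["a"]] - 1)^2
  out <- simulatedAnnealing(obj, c(a = 5),
                            schedule = list(n_proposals = 400L, T0 = 0),
                            seed = 2L)
  expect_true(all(diff(out$trace) <= 0))
})

test_that("simulatedAnnealing is reproducible and respects free_params", {
  obj <- function(x) (x[["a"]] - 2)^2 + (x[["b"]] - 2)^2
  a1 <- simulatedAnnealing(obj, c(a = 1, b = 1), free_params = "a",
                           schedule = list(n_proposals = 200L), seed = 7L)
  a2 <- simulatedAnnealing(obj, c(a = 1, b = 1), free_params = "a",
                           schedule = list(n_proposals = 200L), seed = 7L)
  expect_identical(a1$best, a2$best)
  expect_equal(a1$best[["b"]], 1)  # frozen parameter never moves

  # ModelParameters interface excludes the manually set block by default
  p <- testParams()
  counter <- new.env(); counter$names <- character(0)
  objP <- function(pp) {
    counter$names <- union(counter$names,
                           slotNames(pp)[vapply(slotNames(pp), function(nm)
                             !identical(slot(pp, nm), slot(p, nm)),
                             logical(1))])
    (pp@rho_S - p@rho_S)^2
  }
  out <- simulatedAnnealing(objP, p,
                            schedule = list(n_proposals = 150L), seed = 3L)
  expect_true(is(out$best, "ModelParameters"))
  expect_false(any(c("K_d", "lam", "M_Lambda", "T_R", "M_R", "T_min") %in%
                   counter$names))
})

test_that("non-finite proposals are rejected and counted", {
  obj <- function(x) if (x[["a"]] > 3) NaN else (x[["a"]] - 3)^2
  out <- simulatedAnnealing(obj, c(a = 2.9),
                            schedule = list(n_proposals = 300L, sigma = 0.2),
                            seed = 5L)
  expect_gt(out$rejected_nonfinite, 0)
  expect_true(is.finite(out$best_energy))
  expect_lte(out$best[["a"]], 3)
})

test_that("parameterSensitivity implements the relative-ratio definition", {
  p <- testParams()
  # Y = c * X  ->  S = 1 exactly
  evalLinear <- function(params, seed) 3 * params@rho_S
  s1 <- parameterSensitivity(p, "rho_S", 0.1, evalLinear)
  expect_equal(s1@S, 1)
  # Y = X^2 at +10%  ->  S = (1.1^2 - 1) / 0.1 = 2.1
  evalSq <- function(params, seed) params@rho_S^2
  s2 <- parameterSensitivity(p, "rho_S", 0.1, evalSq)
  expect_equal(s2@S, 2.1)
  # constant observable -> S = 0
  s3 <- parameterSensitivity(p, "rho_S", 0.1, function(params, seed) 42)
  expect_equal(s3@S, 0)
  # zero baseline -> NA
  s4 <- parameterSensitivity(p, "rho_S", 0.1, function(params, seed) 0)
  expect_true(is.na(s4@S))
  expect_error(parameterSensitivity(p, "rho_S", 0, evalLinear))
  expect_error(parameterSensitivity(p, "not_a_param", 0.1, evalLinear))
})

test_that("reference CSV round trip preserves the dataset", {
  ref <- referenceDataset(list(
    refEntry("WT", 48, "O", c(8, 8, 10, 12), m = 9.5, p = 10.5),
    refEntry("dpatS", 48, "O", c(4, 5, 5), m = 14 / 3, p = 17),
    refEntry("dpatA", 48, "N", numeric(0), m = 0, p = 0)))
  path <- tempfile(fileext = ".csv")
  writeReferenceCSV(ref, path)
  back <- readReferenceCSV(path)
  expect_setequal(names(back@entries), names(ref@entries))
  for (k in names(ref@entries)) {
    expect_equal(sort(back@entries[[k]]$sample),
                 sort(ref@entries[[k]]$sample))
    expect_equal(back@entries[[k]]$m, ref@entries[[k]]$m)
    expect_equal(back@entries[[k]]$p, ref@entries[[k]]$p)
    expect_equal(back@entries[[k]]$group, ref@entries[[k]]$group)
  }
  file.remove(path)
  expect_error(readReferenceCSV({
    bad <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
    bad
  }), "missing columns")
})
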