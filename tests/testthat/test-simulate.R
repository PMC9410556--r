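test_that("a noiseless Langevin step is an exact Euler step", {
  p <- testParams()
  set.seed(11)
  conc <- randomConc(6L)
  f <- makeFilament(rep(FALSE, 6), conc = conc, params = p)
  ns0 <- noiseSettings(0, 0, 1L)
  g <- langevinStep(f, p, ns0, dt = 0.02)
  expect_equal(concentrations(g),
               conc + driftMatrix(computeDrift(f, p)) * 0.02,
               tolerance = 1e-13)
  expect_equal(filamentTime(g), 0.02)
})

test_that("negative excursions are clipped to zero", {
  # pure decay from a tiny concentration with a large step undershoots zero
  p <- testParams()
  conc <- matrix(0, 1, 6, dimnames = list(NULL, c("R","A","S","N","I","G")))
  conc[1, "A"] <- 1e-4
  f <- makeFilament(FALSE, conc = conc, params = p)
  g <- langevinStep(f, p, noiseSettings(0, 0, 1L), dt = 10)
  expect_true(all(concentrations(g) >= 0))
})

test_that("Langevin increment variance matches omega * (P + |D|) * dt", {
  p <- testParams()
  n <- 20000L
  conc <- matrix(rep(c(2, 1, 1.5, 0.8, 0.5, 0.3), each = n), n, 6,
                 dimnames = list(NULL, c("R","A","S","N","I","G")))
  f <- makeFilament(rep(FALSE, n), conc = conc, params = p)
  dt <- 0.01
  omega <- 0.2
  pd <- computeDrift(f, p)
  drift <- pd@production + pd@degradation
  set.seed(99)
  g <- langevinStep(f, p, noiseSettings(omega, 0, 1L), dt)
  incr <- concentrations(g) - conc
  # interior cells are identical by construction; use them as replicates
  interior <- 2:(n - 1)
  for (sp in c("R", "A", "S", "N")) {
    noisepart <- incr[interior, sp] - drift[interior, sp] * dt
    expected_var <- omega *
      unname(pd@production[2, sp] - pd@degradation[2, sp]) * dt
    # MC error on a variance over ~2e4 draws is about 1% (se ~ sqrt(2/n))
    expect_equal(stats::var(noisepart), expected_var, tolerance = 0.05)
    expect_lt(abs(mean(noisepart)), 4 * sqrt(expected_var / length(interior)))
  }
})

test_that("commitment integral timing reproduces the threshold conventions", {
  p <- testParams()   # T_R = 1, M_R = 12, T_min = 5
  expect_equal(commitmentTime(p@T_R, p), 12)
  expect_equal(commitmentTime(3 * p@T_R, p), 5)  # limited by T_min
  expect_equal(commitmentTime(2 * p@T_R, p), 6)  # integral-limited: 12/2
  expect_identical(commitmentTime(0.5 * p@T_R, p, t_max = 20), Inf)
})

test_that("dropping below threshold resets integral and clock", {
  p <- testParams()
  f <- makeFilament(FALSE, params = p)
  f@conc[1, "R"] <- 2                 # above threshold
  for (i in 1:100) f <- updateCommitment(f, p, dt = 0.01)
  expect_gt(f@commitIntegral[1], 0)
  expect_gt(f@commitClock[1], 0)
  f@conc[1, "R"] <- 0.5               # dip below threshold once
  f <- updateCommitment(f, p, dt = 0.01)
  expect_equal(f@commitIntegral[1], 0)
  expect_equal(f@commitClock[1], 0)
  expect_false(isHeterocyst(f)[1])
})

test_that("heterocysts are ignored by the commitment update", {
  p <- testParams()
  f <- makeFilament(TRUE, params = p)
  f@conc[1, "R"] <- 10
  g <- updateCommitment(f, p, dt = 0.01)
  expect_equal(g@commitIntegral[1], 0)
  expect_true(isHeterocyst(g)[1])
})

test_that("division halves the mother and conserves total length", {
  p <- testParams()
  set.seed(5)
  conc <- randomConc(3L)
  f <- makeFilament(c(FALSE, FALSE, FALSE), conc = conc,
                    size = c(2, 3.999, 2), params = p)
  ns0 <- noiseSettings(0, 0, 1L)
  len0 <- sum(cellSizes(f))
  g <- growAndDivide(f, p, ns0, dt = 1)  # cell 2 passes M_Lambda = 4
  expect_equal(nCells(g), 4L)
  expect_equal(sum(cellSizes(g)), len0 + 3 * p@lam * 1)
  # daughters sit in place with identical concentrations and no progress
  expect_equal(concentrations(g)[2, ], concentrations(g)[3, ])
  expect_equal(unname(concentrations(g)[2, ]), unname(conc[2, ]))
  expect_equal(cellSizes(g)[2], cellSizes(g)[3])
  expect_equal(g@commitIntegral[2:3], c(0, 0))
})

test_that("heterocysts stop at their maximum size and never divide", {
  p <- testParams()
  f <- makeFilament(TRUE, size = 3.99, params = p)
  ns0 <- noiseSettings(0, 0, 1L)
  for (i in 1:50) f <- growAndDivide(f, p, ns0, dt = 1)
  expect_equal(nCells(f), 1L)
  expect_equal(cellSizes(f), f@mLambda)
})

test_that("noiseless growth divides on schedule", {
  # from half size, dividing takes (M_Lambda/2) / lam hours
  p <- testParams()  # lam = 0.08, M_Lambda = 4 -> 25 h
  f <- makeFilament(FALSE, size = 2, params = p)
  ns0 <- noiseSettings(0, 0, 1L)
  dt <- 0.01
  t <- 0
  while (nCells(f) == 1L && t < 30) {
    f <- growAndDivide(f, p, ns0, dt)
    t <- t + dt
  }
  expect_equal(nCells(f), 2L)
  expect_equal(t, 25, tolerance = 1e-3)
})

test_that("an isolated vegetative cell's HetN decays as the closed form", {
  p <- testParams()
  conc <- matrix(0, 1, 6, dimnames = list(NULL, c("R","A","S","N","I","G")))
  conc[1, "N"] <- 2
  dt <- 0.005
  ns0 <- noiseSettings(0, 0, 1L)
  f <- makeFilament(FALSE, conc = conc, params = p)
  for (i in seq_len(200)) f <- langevinStep(f, p, ns0, dt)
  t <- 200 * dt
  exact <- isolatedSpeciesDecay(2, 2 * p@c_N + p@alpha_N, t)
  err1 <- abs(concentrations(f)[1, "N"] - exact)
  expect_lt(err1, 0.01)
  # halving dt roughly halves the first-order Euler error
  f2 <- makeFilament(FALSE, conc = conc, params = p)
  for (i in seq_len(400)) f2 <- langevinStep(f2, p, ns0, dt / 2)
  err2 <- abs(concentrations(f2)[1, "N"] - exact)
  expect_lt(err2, 0.6 * err1)
})

test_that("runSimulation is reproducible from the seed", {
  p <- testParams()
  cfg <- simulationConfig(t_end = 3, n_initial_cells = 8L)
  a <- runSimulation(cfg, p, mutantSpec("WT"), noiseSettings(0.1, 0.05, 42L))
  b <- runSimulation(cfg, p, mutantSpec("WT"), noiseSettings(0.1, 0.05, 42L))
  expect_identical(trajectoryAsDataFrame(a), trajectoryAsDataFrame(b))
  d <- runSimulation(cfg, p, mutantSpec("WT"), noiseSettings(0.1, 0.05, 43L))
  expect_false(identical(concentrations(finalFilament(a)),
                         concentrations(finalFilament(d))))
})

test_that("trajectories record on the requested cadence with t = 0 first", {
  p <- testParams()
  cfg <- simulationConfig(t_end = 4, record_every = 2, n_initial_cells = 5L)
  tr <- runSimulation(cfg, p, noise = noiseSettings(0.1, 0.05, 7L))
  expect_equal(snapshotTimes(tr), c(0, 2, 4))
  expect_equal(nCells(snapshotAt(tr, 2)), nCells(snapshots(tr)[[2]]))
  expect_error(snapshotAt(tr, 3.2, tol = 0.5), "no snapshot")
})
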