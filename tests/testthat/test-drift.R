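test_that("regulatoryActivity matches hand-computed values", {
  p <- testParams(F_R = 1, tau_A = 0.5, K_d = 0.6, K_G = 0.7)
  # no activator: numerator is zero
  expect_equal(regulatoryActivity(0, 1, 1, 1, p), 0)
  # uninhibited half-occupancy: F_R R^2 (1 + A/tau) = 1 gives 1/2
  expect_equal(regulatoryActivity(1, 0, 0, 0, p), 0.5)
  # every term active: act = 1*4*(1+2) = 12, I^2/K_d^2 = 4, G/K_G = 2
  p2 <- testParams(F_R = 1, tau_A = 1, K_d = 1, K_G = 1)
  expect_equal(regulatoryActivity(2, 2, 2, 2, p2), 12 / (1 + 12 + 4 + 2))
  expect_error(regulatoryActivity(-1, 0, 0, 0, p), ">= 0")
})

test_that("regulatoryActivity is monotone and bounded for both exponents", {
  for (h in c(2, 4)) {
    p <- testParams(hill_exponent = h)
    r <- seq(0, 5, by = 0.25)
    gr <- regulatoryActivity(r, 1, 1, 1, p)
    expect_true(all(diff(gr) > 0))           # increasing in R
    expect_true(all(gr >= 0 & gr < 1))       # bounded in [0, 1)
    a <- seq(0, 5, by = 0.25)
    expect_true(all(diff(regulatoryActivity(1, a, 1, 1, p)) > 0))
    expect_true(all(diff(regulatoryActivity(1, 1, a, 1, p)) < 0))
    expect_true(all(diff(regulatoryActivity(1, 1, 1, a, p)) < 0))
  }
})

test_that("drift of a fresh vegetative cell is pure basal HetR production", {
  p <- testParams()
  f <- makeFilament(FALSE)
  d <- driftMatrix(computeDrift(f, p))
  expect_equal(unname(d[1, ]), c(p@beta_R, 0, 0, 0, 0, 0))
})

test_that("an isolated heterocyst produces HetN and fixed nitrogen only", {
  p <- testParams()
  f <- makeFilament(TRUE)
  d <- driftMatrix(computeDrift(f, p))
  expect_equal(unname(d[1, ]),
               c(p@beta_R, 0, 0, p@rho_N, 0, p@rho_G))
})

test_that("hexapeptide conversion moves mass from a cell to its neighbours", {
  p <- testParams()
  s0 <- 1.7
  conc <- matrix(0, 3, 6, dimnames = list(NULL, c("R","A","S","N","I","G")))
  conc[2, "S"] <- s0
  f <- makeFilament(c(FALSE, FALSE, FALSE), conc = conc)
  d <- driftMatrix(computeDrift(f, p))
  # each neighbour receives c_S * s0 as inhibitor
  expect_equal(unname(d[1, "I"]), p@c_S * s0)
  expect_equal(unname(d[3, "I"]), p@c_S * s0)
  # the source cell receives nothing and loses S through both membranes
  expect_equal(unname(d[2, "I"]), 0)
  expect_equal(unname(d[2, "S"]), -(2 * p@c_S + p@alpha_S) * s0)
})

test_that("drift matches the independent equation transcription exactly", {
  p <- testParams()
  set.seed(101)
  for (n in c(1L, 2L, 3L, 5L, 30L)) {
    conc <- randomConc(n)
    het <- stats::runif(n) < 0.3
    f <- makeFilament(het, conc = conc, params = p)
    pd <- computeDrift(f, p)
    expect_equal(driftMatrix(pd), oracleDrift(conc, het, p),
                 tolerance = 1e-13)
    # the split is termwise signed
    expect_true(all(pd@production >= 0))
    expect_true(all(pd@degradation <= 0))
  }
})

test_that("drift oracle equivalence also holds for the tetramer variant", {
  p <- testParams(hill_exponent = 4)
  set.seed(202)
  conc <- randomConc(8L)
  het <- c(TRUE, rep(FALSE, 6), TRUE)
  f <- makeFilament(het, conc = conc, params = p)
  expect_equal(driftMatrix(computeDrift(f, p)), oracleDrift(conc, het, p),
               tolerance = 1e-13)
})

test_that("inhibitor diffusion conserves mass; only conversion and borders move it", {
  # with decay off and no terminal leakage, total inhibitor changes only by
  # the conversion influx that interior neighbours provide
  p <- testParams(alpha_I = 1e-12, d_border = 1e-12)
  set.seed(303)
  n <- 12L
  conc <- randomConc(n)
  f <- makeFilament(rep(FALSE, n), conc = conc, params = p)
  d <- driftMatrix(computeDrift(f, p))
  S <- conc[, "S"]; Nn <- conc[, "N"]
  expected <- p@c_S * (2 * sum(S) - S[1] - S[n]) +
    p@c_N * (2 * sum(Nn) - Nn[1] - Nn[n])
  expect_equal(sum(d[, "I"]), expected, tolerance = 1e-9)
})

test_that("terminal cells leak at rate d_border * d through open faces", {
  p <- testParams()
  # single cell: both faces leak
  conc1 <- matrix(c(0, 0, 0, 0, 2, 3), 1, 6,
                  dimnames = list(NULL, c("R","A","S","N","I","G")))
  f1 <- makeFilament(FALSE, conc = conc1)
  d1 <- driftMatrix(computeDrift(f1, p))
  expect_equal(unname(d1[1, "I"]), -(2 * p@d_border * p@d_I + p@alpha_I) * 2)
  expect_equal(unname(d1[1, "G"]), -(2 * p@d_border * p@d_G + p@alpha_G) * 3)
})

test_that("isolatedSpeciesDecay is exponential decay", {
  expect_equal(isolatedSpeciesDecay(2, 0.5, 0), 2)
  expect_equal(isolatedSpeciesDecay(2, 0.5, 3), 2 * exp(-1.5))
  expect_error(isolatedSpeciesDecay(1, -1, 1))
})
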