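## Internal plain-list state <-> Filament conversion.  The integrator works
## on the plain representation to keep the inner loop free of S4 dispatch.
.filament2state <- function(f) {
  list(conc = f@conc, size = f@size, het = f@het, tR = f@tR, mR = f@mR,
       mLambda = f@mLambda, ci = f@commitIntegral, cc = f@commitClock,
       time = f@time)
}

.state2filament <- function(st) {
  new("Filament", conc = st$conc, size = st$size, het = st$het,
      tR = st$tR, mR = st$mR, mLambda = st$mLambda,
      commitIntegral = st$ci, commitClock = st$cc, time = st$time)
}

## Euler-Maruyama update of all concentrations.  Drift + multiplicative
## noise with local amplitude omega_phi * (P + |D|); negative excursions
## are clipped to zero.
.kernelConc <- function(st, p, omega_phi, dt) {
  pd <- .driftPD(st$conc, st$het, p)
  x <- st$conc + (pd$P + pd$D) * dt
  if (omega_phi > 0) {
    amp <- pd$P - pd$D                    # P + |D|, D is termwise <= 0
    x <- x + sqrt(omega_phi * amp * dt) *
      matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  }
  x[x < 0] <- 0
  if (!is.finite(sum(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite concentration at t = %.3f h: cell %d, species %s",
      st$time, bad[1], SPECIES[bad[2]]))
  }
  st$conc <- x
  st
}

## Commitment bookkeeping for vegetative cells: while HetR stays at or
## above the cell's threshold the integral of HetR and the clock advance;
## any drop below the threshold resets both.  A cell differentiates when
## the integral reaches its target AND the clock has reached T_min.
.kernelCommit <- function(st, p, dt) {
  veg <- !st$het
  if (!any(veg)) return(st)
  R <- st$conc[, 1L]
  above <- veg & (R >= st$tR)
  st$ci[above] <- st$ci[above] + R[above] * dt
  st$cc[above] <- st$cc[above] + dt
  reset <- veg & !above
  st$ci[reset] <- 0
  st$cc[reset] <- 0
  # tiny tolerance so held-at-threshold cases are not deferred one step by
  # floating-point accumulation
  newHet <- above & (st$ci >= st$mR * (1 - 1e-12)) &
    (st$cc >= p@T_min * (1 - 1e-12))
  if (any(newHet)) {
    st$het[newHet] <- TRUE
    st$ci[newHet] <- 0
    st$cc[newHet] <- 0
  }
  st
}

## Stochastic growth and division.  Vegetative cells reaching their
## maximum size split in place into two half-size cells with identical
## concentrations, fresh thresholds, and reset commitment; heterocysts
## stop growing at their maximum size and never divide.
.kernelGrow <- function(st, p, noise, dt) {
  n <- length(st$size)
  incr <- p@lam * dt
  if (noise@omega_lambda > 0)
    incr <- incr + p@lam * sqrt(noise@omega_lambda * dt) * stats::rnorm(n)
  size <- pmax(st$size + incr, 1e-9)
  size[st$het] <- pmin(size[st$het], st$mLambda[st$het])
  st$size <- size
  div <- !st$het & (size >= st$mLambda)
  if (any(div)) {
    idx <- rep(seq_len(n), ifelse(div, 2L, 1L))
    child <- div[idx]                      # TRUE for both daughters
    st$conc <- st$conc[idx, , drop = FALSE]
    st$het <- st$het[idx]
    st$size <- st$size[idx]
    st$size[child] <- st$size[child] / 2
    st$tR <- st$tR[idx]
    st$mR <- st$mR[idx]
    st$mLambda <- st$mLambda[idx]
    st$ci <- st$ci[idx]
    st$cc <- st$cc[idx]
    k <- sum(child)
    st$tR[child] <- .drawThreshold(k, p@T_R, noise@omega_phi)
    st$mR[child] <- .drawThreshold(k, p@M_R, noise@omega_phi)
    st$mLambda[child] <- .drawThreshold(k, p@M_Lambda, noise@omega_lambda)
    st$ci[child] <- 0
    st$cc[child] <- 0
  }
  st
}

#' One Euler-Maruyama step of the concentration dynamics
#'
#' Advances every concentration of every cell by
#' `drift * dt + sqrt(omega_phi * (P + |D|) * dt) * xi` with independent
#' standard-normal `xi` per cell and species (Ito interpretation), then
#' clips negative excursions to zero.  With `omega_phi = 0` this is an
#' exact deterministic Euler step.  Uses the current RNG state.  The
#' filament clock advances by `dt`.
#'
#' @param filament a [Filament] object.
#' @param params a [ModelParameters] object.
#' @param noise a [NoiseSettings] object (only `omega_phi` is used).
#' @param dt time step (h), > 0.
#' @return The advanced [Filament].
#' @export
langevinStep <- function(filament, params, noise = noiseSettings(), dt) {
  stopifnot(is(filament, "Filament"), is(params, "ModelParameters"),
            is(noise, "NoiseSettings"), dt > 0)
  st <- .kernelConc(.filament2state(filament), params, noise@omega_phi, dt)
  st$time <- st$time + dt
  .state2filament(st)
}

#' Advance the differentiation-commitment bookkeeping
#'
#' For every vegetative cell whose HetR concentration is at or above its
#' cell-specific threshold, the running integral of HetR and the
#' above-threshold clock advance by one step; cells that drop below their
#' threshold have both reset to zero.  A cell becomes a heterocyst once its
#' integral reaches its cell-specific target and the clock has reached
#' `T_min`; from the next drift evaluation it produces HetN and fixed
#' nitrogen instead of PatS.  Heterocysts are left untouched.
#'
#' @param filament a [Filament] object.
#' @param params a [ModelParameters] object.
#' @param dt time step (h), > 0.
#' @return The updated [Filament] (clock unchanged).
#' @export
updateCommitment <- function(filament, params, dt) {
  stopifnot(is(filament, "Filament"), is(params, "ModelParameters"), dt > 0)
  .state2filament(.kernelCommit(.filament2state(filament), params, dt))
}

#' Stochastic growth and cell division
#'
#' Every cell's size advances by `lam * dt` plus growth noise
#' `lam * sqrt(omega_lambda * dt) * xi`.  A vegetative cell reaching its
#' cell-specific maximum size splits in place into two cells of half its
#' size with identical concentrations; both daughters draw fresh
#' commitment thresholds and maximum sizes and start with commitment
#' progress zero.  Heterocysts grow to their maximum size, then stop, and
#' never divide.  Total filament length is exactly conserved across a
#' division.  Uses the current RNG state.
#'
#' @param filament a [Filament] object.
#' @param params a [ModelParameters] object.
#' @param noise a [NoiseSettings] object.
#' @param dt time step (h), > 0.
#' @return The updated [Filament] (clock unchanged).
#' @export
growAndDivide <- function(filament, params, noise = noiseSettings(), dt) {
  stopifnot(is(filament, "Filament"), is(params, "ModelParameters"),
            is(noise, "NoiseSettings"), dt > 0)
  .state2filament(.kernelGrow(.filament2state(filament), params, noise, dt))
}

#' Run one full filament simulation
#'
#' Starting from `n_initial_cells` vegetative cells at nitrogen step-down
#' (all concentrations zero), repeatedly applies one concentration step,
#' the commitment update, and growth/division, recording a snapshot every
#' `record_every` hours (including t = 0).  The mutant overlay is applied
#' to the parameters before integration.  Fully reproducible from
#' `noise@seed`.
#'
#' @param config a [SimulationConfig] object.
#' @param params a [ModelParameters] object (wild-type scale).
#' @param mutant a [MutantSpec] overlay (default wild type).
#' @param noise a [NoiseSettings] object; its seed seeds the run.
#' @return A [Trajectory] object.
#' @examples
#' cfg <- simulationConfig(t_end = 2, n_initial_cells = 5L)
#' tr <- runSimulation(cfg, wildTypeParameters(),
#'                     noise = noiseSettings(seed = 42))
#' finalFilament(tr)
#' @export
runSimulation <- function(config, params, mutant = mutantSpec("WT"),
                          noise = noiseSettings()) {
  stopifnot(is(config, "SimulationConfig"), is(params, "ModelParameters"),
            is(mutant, "MutantSpec"), is(noise, "NoiseSettings"))
  set.seed(noise@seed)
  p <- applyMutant(params, mutant)
  f0 <- newFilament(config@n_initial_cells, p, noise,
                    size_policy = config@initial_size_policy)
  st <- .filament2state(f0)
  dt <- config@dt
  n_steps <- round(config@t_end / dt)
  rec_k <- max(1L, round(config@record_every / dt))
  snaps <- vector("list", floor(n_steps / rec_k) + 1L)
  snaps[[1L]] <- f0
  j <- 1L
  om <- noise@omega_phi
  for (k in seq_len(n_steps)) {
    st <- .kernelConc(st, p, om, dt)
    st <- .kernelCommit(st, p, dt)
    st <- .kernelGrow(st, p, noise, dt)
    st$time <- st$time + dt
    if (k %% rec_k == 0L) {
      j <- j + 1L
      snaps[[j]] <- .state2filament(st)
    }
  }
  new("Trajectory", snapshots = snaps[seq_len(j)], params = p,
      mutant = mutant, noise = noise, config = config)
}

#' Time to commitment at a held HetR level
#'
#' Runs the commitment rule alone, noiselessly, on a single vegetative
#' cell whose HetR concentration is pinned at `R_level`, and returns the
#' elapsed time at which the cell differentiates.  With the default
#' convention `M_R = 12 * T_R`, a cell held exactly at the threshold
#' commits after 12 h; a cell held far above it is limited by `T_min`.
#'
#' @param R_level the pinned HetR concentration.
#' @param params a [ModelParameters] object.
#' @param dt commitment bookkeeping step (h).
#' @param t_max give up after this time (h).
#' @return Time of differentiation (h), or `Inf` if the threshold is never
#'   met within `t_max`.
#' @export
commitmentTime <- function(R_level, params, dt = 0.01, t_max = 100) {
  stopifnot(is(params, "ModelParameters"), R_level >= 0, dt > 0)
  conc <- matrix(c(R_level, 0, 0, 0, 0, 0), 1, 6,
                 dimnames = list(NULL, SPECIES))
  st <- list(conc = conc, size = params@M_Lambda / 2, het = FALSE,
             tR = params@T_R, mR = params@M_R, mLambda = params@M_Lambda,
             ci = 0, cc = 0, time = 0)
  k <- 0L
  while (k * dt < t_max) {
    st <- .kernelCommit(st, params, dt)
    k <- k + 1L
    if (st$het) return(k * dt)
  }
  Inf
}
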