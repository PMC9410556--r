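#' Create a filament of vegetative cells at nitrogen step-down
#'
#' All concentrations start at zero (the state right after combined
#' nitrogen is removed).  Initial sizes are either uniform on
#' `[M_Lambda/2, M_Lambda]` (default, desynchronizes the first division
#' round) or all `M_Lambda/2`.  Per-cell commitment thresholds and maximum
#' sizes are drawn from Gaussians with means `(T_R, M_R, M_Lambda)` and
#' variances `(T_R^2, M_R^2) * omega_phi` and `M_Lambda^2 * omega_lambda`;
#' draws are floored at 5\% of their mean to keep them positive.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param n number of cells.
#' @param params a [ModelParameters] object.
#' @param noise a [NoiseSettings] object.
#' @param size_policy `"uniform"` or `"half_max"`.
#' @return A [Filament] at time 0.
#' @export
newFilament <- function(n, params, noise = noiseSettings(),
                        size_policy = "uniform") {
  n <- as.integer(n)
  stopifnot(n >= 1L, is(params, "ModelParameters"),
            is(noise, "NoiseSettings"))
  conc <- matrix(0, n, 6L, dimnames = list(NULL, SPECIES))
  size <- switch(size_policy,
    uniform  = stats::runif(n, params@M_Lambda / 2, params@M_Lambda),
    half_max = rep(params@M_Lambda / 2, n),
    stop("unknown size_policy '", size_policy, "'"))
  new("Filament", conc = conc, size = size, het = rep(FALSE, n),
      tR = .drawThreshold(n, params@T_R, noise@omega_phi),
      mR = .drawThreshold(n, params@M_R, noise@omega_phi),
      mLambda = .drawThreshold(n, params@M_Lambda, noise@omega_lambda),
      commitIntegral = rep(0, n), commitClock = rep(0, n), time = 0)
}

## Gaussian draw with mean m and variance m^2 * omega, floored at 5% of m.
.drawThreshold <- function(n, m, omega) {
  pmax(stats::rnorm(n, m, m * sqrt(omega)), 0.05 * m)
}

#' Number of cells in a filament
#' @param filament a [Filament] object.
#' @return Integer cell count.
#' @export
nCells <- function(filament) nrow(filament@conc)

#' Heterocyst indicator per cell
#' @param filament a [Filament] object.
#' @return Logical vector, TRUE for heterocysts.
#' @export
isHeterocyst <- function(filament) filament@het

#' Concentration matrix of a filament
#' @param filament a [Filament] object.
#' @return Numeric matrix, rows = cells, columns `R, A, S, N, I, G`.
#' @export
concentrations <- function(filament) filament@conc

#' Cell sizes of a filament
#' @param filament a [Filament] object.
#' @return Numeric vector of sizes (um).
#' @export
cellSizes <- function(filament) filament@size

#' Simulation clock of a filament
#' @param filament a [Filament] object.
#' @return Time in hours.
#' @export
filamentTime <- function(filament) filament@time

#' One-row-per-cell data.frame view of a filament
#'
#' @param filament a [Filament] object.
#' @return data.frame with columns `time_h`, `cell_index`, `R`, `A`, `S`,
#'   `N`, `I`, `G`, `size_um`, `is_heterocyst`.
#' @export
filamentAsDataFrame <- function(filament) {
  n <- nCells(filament)
  data.frame(time_h = rep(filament@time, n), cell_index = seq_len(n),
             filament@conc, size_um = filament@size,
             is_heterocyst = filament@het)
}

setMethod("show", "Filament", function(object) {
  n <- nCells(object)
  cat(sprintf("Filament: %d cells (%d heterocysts) at t = %.2f h\n",
              n, sum(object@het), object@time))
  cat(" pattern:", paste(ifelse(object@het, "H", "v"), collapse = ""), "\n")
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  tt <- vapply(object@snapshots, filamentTime, numeric(1))
  last <- object@snapshots[[length(object@snapshots)]]
  cat(sprintf("Trajectory [%s]: %d snapshots over %.0f-%.0f h, seed %d\n",
              object@mutant@label, length(tt), min(tt), max(tt),
              object@noise@seed))
  cat(sprintf(" final: %d cells, %d heterocysts (%.1f%%)\n",
              nCells(last), sum(last@het), 100 * mean(last@het)))
  invisible(object)
})

#' Snapshots of a trajectory
#' @param traj a [Trajectory] object.
#' @return List of [Filament] objects.
#' @export
snapshots <- function(traj) traj@snapshots

#' Recorded snapshot times of a trajectory
#' @param traj a [Trajectory] object.
#' @return Numeric vector of times (h).
#' @export
snapshotTimes <- function(traj) {
  vapply(traj@snapshots, filamentTime, numeric(1))
}

#' Snapshot nearest to a requested time
#'
#' @param traj a [Trajectory] object.
#' @param time_h requested filament age (h).
#' @param tol maximum allowed distance to a recorded time (default half the
#'   recording cadence).
#' @return A [Filament] object.
#' @export
snapshotAt <- function(traj, time_h, tol = traj@config@record_every / 2) {
  tt <- snapshotTimes(traj)
  i <- which.min(abs(tt - time_h))
  if (abs(tt[i] - time_h) > tol + 1e-9)
    stop(sprintf("no snapshot within %.3g h of t = %g h", tol, time_h))
  traj@snapshots[[i]]
}

#' Final filament of a trajectory
#' @param traj a [Trajectory] object.
#' @return The last recorded [Filament].
#' @export
finalFilament <- function(traj) traj@snapshots[[length(traj@snapshots)]]

#' Long-format data.frame of a whole trajectory
#'
#' @param traj a [Trajectory] object.
#' @return data.frame concatenating [filamentAsDataFrame()] over snapshots.
#' @export
trajectoryAsDataFrame <- function(traj) {
  do.call(rbind, lapply(traj@snapshots, filamentAsDataFrame))
}
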