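#' Construct continuum activator-inhibitor parameters
#'
#' Defaults sit in a regime with a stable homogeneous steady state under
#' zero-flux boundary conditions, so any spatial structure that appears
#' under absorbing boundaries is attributable to the boundaries alone.
#' The default regulatory function is the filament model's promoter
#' activity with no PatA and no fixed nitrogen:
#' `f(r, s) = r^2 / (1 + r^2 + s^2)`.
#'
#' @param beta_r,rho_r,rho_s,alpha_r,alpha_s,d,L,nx see
#'   [ContinuumParams-class].
#' @param f regulatory function `f(r, s)`; vectorized, increasing in `r`,
#'   decreasing in `s`.
#' @param bc `"zeroflux"` or `"absorbing"`.
#' @return A [ContinuumParams] object.
#' @export
continuumParams <- function(beta_r = 0.1, rho_r = 2, rho_s = 2,
                            alpha_r = 1, alpha_s = 1, d = 2, L = 20,
                            f = function(r, s) r^2 / (1 + r^2 + s^2),
                            bc = "absorbing", nx = 201L) {
  new("ContinuumParams", beta_r = beta_r, rho_r = rho_r, rho_s = rho_s,
      alpha_r = alpha_r, alpha_s = alpha_s, d = d, L = L, f = f,
      bc = bc, nx = as.integer(nx))
}

#' Steady-state profiles of the continuum activator-inhibitor model
#'
#' Integrates a non-diffusing activator `r` and a diffusing inhibitor `s`
#' by the method of lines (second-order central differences; mirrored
#' ghost nodes for zero-flux, pinned zero boundary values for absorbing)
#' with `deSolve::ode` until the largest time derivative falls below
#' `tol`.  Under absorbing boundaries the inhibitor drains at the domain
#' ends, producing an inhibitor minimum and an activator maximum at each
#' boundary -- the continuum analogue of terminal-cell leakage.
#'
#' @param cp a [ContinuumParams] object.
#' @param tol convergence tolerance on `max |d/dt|` (default 1e-8).
#' @param t_max give up after this much integration time (default 5000).
#' @return A list with `x`, `r`, `s` (grid and profiles), `converged`
#'   (logical) and `t_used`.
#' @examples
#' out <- steadyStateProfiles(continuumParams(bc = "zeroflux", nx = 51L))
#' range(out$s)  # spatially uniform
#' @export
steadyStateProfiles <- function(cp, tol = 1e-8, t_max = 5000) {
  stopifnot(is(cp, "ContinuumParams"))
  nx <- cp@nx
  h <- cp@L / (nx - 1)
  absorbing <- cp@bc == "absorbing"
  deriv <- function(t, y, parms) {
    r <- y[1:nx]
    s <- y[(nx + 1):(2 * nx)]
    fv <- cp@f(r, s)
    dr <- cp@beta_r + fv * cp@rho_r - cp@alpha_r * r
    sl <- c(if (absorbing) 0 else s[2], s[-nx])
    sr <- c(s[-1], if (absorbing) 0 else s[nx - 1])
    lap <- (sl - 2 * s + sr) / h^2
    ds <- fv * cp@rho_s - cp@alpha_s * s + cp@d * lap
    if (absorbing) {
      ds[1] <- 0
      ds[nx] <- 0
    }
    list(c(dr, ds))
  }
  y <- rep(0, 2 * nx)
  t_used <- 0
  chunk <- 50
  converged <- FALSE
  while (t_used < t_max) {
    sol <- deSolve::ode(y, c(0, chunk), deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    y <- unname(sol[nrow(sol), -1])
    t_used <- t_used + chunk
    rate <- max(abs(unlist(deriv(0, y, NULL))))
    if (rate < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("no steady state reached by t = %g (max rate %.3g)",
                    t_max, rate))
  list(x = seq(0, cp@L, length.out = nx), r = y[1:nx],
       s = y[(nx + 1):(2 * nx)], converged = converged, t_used = t_used)
}

#' Closed-form inhibitor profile for a constant source and absorbing ends
#'
#' With a constant regulatory activity `f0` the inhibitor equation is
#' linear and its steady state with zero boundary values is
#' `(f0 rho_s / alpha_s) * (1 - cosh(k (x - L/2)) / cosh(k L / 2))` with
#' `k = sqrt(alpha_s / d)`.  Used as the independent oracle for the grid
#' solver.
#'
#' @param x positions.
#' @param f0 constant activity.
#' @param rho_s,alpha_s,d,L inhibitor parameters.
#' @return The profile at `x`.
#' @export
absorbingCoshProfile <- function(x, f0, rho_s, alpha_s, d, L) {
  k <- sqrt(alpha_s / d)
  (f0 * rho_s / alpha_s) * (1 - cosh(k * (x - L / 2)) / cosh(k * L / 2))
}
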