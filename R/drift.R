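#' Regulated-promoter activity of activated HetR
#'
#' The shared promoter-occupancy function used for every HetR-regulated
#' gene.  HetR oligomers (dimers by default, tetramers with
#' `hill_exponent = 4`) activated by HetF, with PatA enhancing the
#' activation, compete with hexapeptide and fixed-nitrogen inhibition:
#' \deqn{g = \frac{F_R R^h (1 + A/\tau_A)}
#'   {1 + F_R R^h (1 + A/\tau_A) + I^2/K_d^2 + G/K_G}.}
#' The value lies in `[0, 1)`, strictly increasing in `R` and `A`, strictly
#' decreasing in `I` and `G`.
#'
#' @param R,A,I,G concentrations (vectors recycle together), all >= 0.
#' @param params a [ModelParameters] object.
#' @return Promoter activity in `[0, 1)`.
#' @examples
#' p <- wildTypeParameters()
#' regulatoryActivity(0, 1, 1, 1, p)  # 0: no activator
#' @export
regulatoryActivity <- function(R, A, I, G, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(R < 0) || any(A < 0) || any(I < 0) || any(G < 0))
    stop("regulatoryActivity: all concentrations must be >= 0")
  act <- params@F_R * R^params@hill_exponent * (1 + A / params@tau_A)
  act / (1 + act + I^2 / params@K_d^2 + G / params@K_G)
}

## Internal drift kernel operating on raw state vectors.  Returns the
## production (P) and degradation (D) matrices whose sum is the exact
## deterministic right-hand side.  Interior cells exchange hexapeptide and
## fixed nitrogen with both neighbours; the two terminal cells exchange
## with their single neighbour and additionally leak both species to the
## medium at rate d_border * d (both faces leak for a one-cell filament).
.driftPD <- function(conc, het, p) {
  n <- nrow(conc)
  R <- conc[, 1L]; A <- conc[, 2L]; S <- conc[, 3L]
  Nn <- conc[, 4L]; I <- conc[, 5L]; G <- conc[, 6L]
  g <- p@F_R * R^p@hill_exponent * (1 + A / p@tau_A)
  g <- g / (1 + g + I^2 / p@K_d^2 + G / p@K_G)
  hc <- as.numeric(het)

  if (n == 1L) {
    nbr <- function(x) 0
    faces_in <- 0
    faces_out <- 2
  } else {
    nbr <- function(x) c(0, x[-n]) + c(x[-1L], 0)
    faces_in <- c(1, rep(2, n - 2L), 1)
    faces_out <- c(1, rep(0, n - 2L), 1)
  }

  P <- cbind(
    R = p@beta_R + g * p@rho_R,
    A = g * p@rho_A,
    S = (1 - hc) * g * p@rho_S,
    N = hc * p@rho_N,
    I = p@c_S * nbr(S) + p@c_N * nbr(Nn) + p@d_I * nbr(I),
    G = hc * p@rho_G + p@d_G * nbr(G))

  lossI <- p@d_I * (faces_in + p@d_border * faces_out)
  lossG <- p@d_G * (faces_in + p@d_border * faces_out)
  D <- cbind(
    R = -p@alpha_R * R * (1 + 2 * p@mu * R),
    A = -p@alpha_A * A,
    S = -(2 * p@c_S + p@alpha_S) * S,
    N = -(2 * p@c_N + p@alpha_N) * Nn,
    I = -(lossI + p@alpha_I) * I,
    G = -(lossG + p@alpha_G) * G)
  dimnames(P) <- list(NULL, SPECIES)
  dimnames(D) <- list(NULL, SPECIES)
  list(P = P, D = D)
}

#' Deterministic drift of a filament, split into production and degradation
#'
#' Evaluates the right-hand side of the per-cell dynamics for every cell
#' and species, returning the termwise-positive production sums and
#' termwise-negative degradation sums separately (their sum is the drift;
#' `production + |degradation|` sets the Langevin noise amplitude).
#' Vegetative cells produce PatS+PatX; heterocysts instead produce HetN and
#' fixed nitrogen.  The two terminal cells leak hexapeptide and fixed
#' nitrogen to the medium at the reduced rate `d_border * d_I` (resp.
#' `d_G`); a single-cell filament leaks through both faces.
#'
#' @param filament a [Filament] object.
#' @param params a [ModelParameters] object.
#' @return A [DriftDecomposition] object.
#' @seealso [driftMatrix()], [langevinStep()]
#' @export
computeDrift <- function(filament, params) {
  stopifnot(is(filament, "Filament"), is(params, "ModelParameters"))
  pd <- .driftPD(filament@conc, filament@het, params)
  new("DriftDecomposition", production = pd$P, degradation = pd$D)
}

#' Total drift of a decomposition
#'
#' @param x a [DriftDecomposition] object.
#' @return The matrix `production + degradation`.
#' @export
driftMatrix <- function(x) {
  stopifnot(is(x, "DriftDecomposition"))
  x@production + x@degradation
}

#' Closed-form linear decay
#'
#' Exponential decay `x0 * exp(-loss_rate * t)`, the exact solution of any
#' species whose only dynamics is linear loss.  Used as an independent
#' oracle for the integrator (for instance HetN in an isolated vegetative
#' cell decays at rate `2 c_N + alpha_N`).
#'
#' @param x0 initial concentration.
#' @param loss_rate total linear loss rate (1/h), >= 0.
#' @param t elapsed time (h), >= 0.
#' @return Concentration at time `t`.
#' @export
isolatedSpeciesDecay <- function(x0, loss_rate, t) {
  stopifnot(loss_rate >= 0, t >= 0)
  x0 * exp(-loss_rate * t)
}
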