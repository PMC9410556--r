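#' Construct a DimerKinetics object
#'
#' @param k_b,k_u,alpha_d,K_R,K_F see [DimerKinetics-class].
#' @return A [DimerKinetics] object.
#' @export
dimerKinetics <- function(k_b = 1, k_u = 1, alpha_d = 1, K_R = 1, K_F = 1) {
  new("DimerKinetics", k_b = k_b, k_u = k_u, alpha_d = alpha_d,
      K_R = K_R, K_F = K_F)
}

#' Equilibrium HetF concentration
#'
#' HetF is produced at a constant basal rate and degraded linearly, so its
#' concentration relaxes to `beta_F / alpha_F` and is treated as constant in
#' every cell.
#'
#' @param beta_F basal HetF production (conc/h), >= 0.
#' @param alpha_F HetF degradation rate (1/h), > 0.
#' @return The equilibrium concentration `beta_F / alpha_F`.
#' @examples
#' hetfEquilibrium(2, 4)  # 0.5
#' @export
hetfEquilibrium <- function(beta_F, alpha_F) {
  if (!is.finite(beta_F) || beta_F < 0)
    stop("'beta_F' must be finite and >= 0")
  if (!is.finite(alpha_F) || alpha_F <= 0)
    stop("'alpha_F' must be finite and > 0")
  beta_F / alpha_F
}

#' Nonlinear HetR degradation coefficient from dimer kinetics
#'
#' The quadratic loss term in the HetR equation lumps degradation through
#' dimerization: `mu = (k_b / alpha_R) * (1 - k_u / (k_u + alpha_d))`.
#'
#' @param kin a [DimerKinetics] object.
#' @param alpha_R HetR monomer degradation rate (1/h), > 0.
#' @return The coefficient `mu` (1/conc).
#' @export
muFromKinetics <- function(kin, alpha_R) {
  stopifnot(is(kin, "DimerKinetics"))
  if (!is.finite(alpha_R) || alpha_R <= 0)
    stop("'alpha_R' must be finite and > 0")
  if (kin@k_u + kin@alpha_d <= 0)
    stop("'k_u + alpha_d' must be > 0")
  (kin@k_b / alpha_R) * (1 - kin@k_u / (kin@k_u + kin@alpha_d))
}

#' Lumped activation constant from equilibrium constants
#'
#' `F_R = F_eq * K_F * K_R / 2`, combining the equilibrium HetF level with
#' the dimerization and activation constants into the single constant that
#' multiplies the HetR oligomer term of the regulatory function.
#'
#' @param F_eq equilibrium HetF concentration, >= 0.
#' @param kin a [DimerKinetics] object supplying `K_F` and `K_R`.
#' @return `F_R` (1/conc^2).
#' @export
frFromConstants <- function(F_eq, kin) {
  stopifnot(is(kin, "DimerKinetics"))
  if (!is.finite(F_eq) || F_eq < 0) stop("'F_eq' must be finite and >= 0")
  F_eq * kin@K_F * kin@K_R / 2
}

#' Construct a ModelParameters object
#'
#' All arguments are named after the model symbols; see
#' [ModelParameters-class] for meanings and units.  Unless
#' `check_M_R = FALSE`, construction enforces the default convention
#' `M_R = 12 * T_R` (the commitment integral equals holding HetR at the
#' threshold for 12 hours).
#'
#' @param beta_R,rho_R,rho_A,rho_S,rho_N,rho_G production rates.
#' @param alpha_R,alpha_A,alpha_S,alpha_N,alpha_I,alpha_G,alpha_F decay
#'   rates.
#' @param beta_F basal HetF production.
#' @param mu nonlinear HetR degradation coefficient.
#' @param c_S,c_N,d_I,d_G transport/conversion rates.
#' @param d_border terminal-cell leakage multiplier.
#' @param F_R lumped activation constant.
#' @param tau_A,K_d,K_G regulation scales.
#' @param hill_exponent 2 or 4.
#' @param T_R,M_R,T_min,lam,M_Lambda commitment and growth parameters.
#' @param check_M_R enforce `M_R == 12 * T_R` (default TRUE).
#' @return A validated [ModelParameters] object.
#' @export
modelParameters <- function(beta_R, rho_R, rho_A, rho_S, rho_N, rho_G,
                            alpha_R, alpha_A, alpha_S, alpha_N, alpha_I,
                            alpha_G, alpha_F, beta_F, mu, c_S, c_N,
                            d_I, d_G, d_border, F_R, tau_A, K_d, K_G,
                            hill_exponent = 2, T_R, M_R = 12 * T_R,
                            T_min, lam, M_Lambda, check_M_R = TRUE) {
  if (check_M_R && !isTRUE(all.equal(M_R, 12 * T_R)))
    stop("M_R must equal 12 * T_R under the default convention; ",
         "pass check_M_R = FALSE to override")
  new("ModelParameters",
      beta_R = beta_R, rho_R = rho_R, rho_A = rho_A, rho_S = rho_S,
      rho_N = rho_N, rho_G = rho_G, alpha_R = alpha_R, alpha_A = alpha_A,
      alpha_S = alpha_S, alpha_N = alpha_N, alpha_I = alpha_I,
      alpha_G = alpha_G, alpha_F = alpha_F, beta_F = beta_F, mu = mu,
      c_S = c_S, c_N = c_N, d_I = d_I, d_G = d_G, d_border = d_border,
      F_R = F_R, tau_A = tau_A, K_d = K_d, K_G = K_G,
      hill_exponent = hill_exponent, T_R = T_R, M_R = M_R, T_min = T_min,
      lam = lam, M_Lambda = M_Lambda)
}

#' Wild-type parameter preset
#'
#' The calibrated stand-in parameter set shipped with the package.  It was
#' obtained by fitting the model's own pattern statistics (mean vegetative
#' interval near ten cells and heterocyst percentage near ten percent over
#' 24-72 h, terminal-heterocyst preference in the patA background, no
#' differentiation without HetF) with the package's annealing machinery and
#' manual refinement; the commitment and growth block (`K_d`, `lam`,
#' `M_Lambda`, `T_R`, `M_R`, `T_min`) is fixed by design: growth 0.08 um/h,
#' maximum size 4 um, threshold-holding convention `M_R = 12 * T_R` and a
#' 5 h minimum commitment time.
#'
#' Concentrations are in arbitrary units scaled so that the commitment
#' threshold `T_R = 1`.
#'
#' @param hill_exponent 2 (default, dimer regulation) or 4 (tetramer
#'   variant).
#' @return A [ModelParameters] object.
#' @export
wildTypeParameters <- function(hill_exponent = 2) {
  kin <- dimerKinetics(k_b = 0.1, k_u = 1, alpha_d = 1, K_R = 1, K_F = 1)
  alpha_R <- 0.5
  F_eq <- hetfEquilibrium(beta_F = 1, alpha_F = 1)
  modelParameters(
    beta_R = 0.2, rho_R = 1.8, rho_A = 1.0, rho_S = 8.0,
    rho_N = 9.0, rho_G = 6.0,
    alpha_R = alpha_R, alpha_A = 0.5, alpha_S = 0.5, alpha_N = 0.5,
    alpha_I = 0.4, alpha_G = 0.3, alpha_F = 1, beta_F = 1,
    mu = muFromKinetics(kin, alpha_R),
    c_S = 0.3, c_N = 0.5, d_I = 6.0, d_G = 6.0, d_border = 1.0,
    F_R = frFromConstants(F_eq, kin), tau_A = 0.2,
    K_d = 0.5, K_G = 2.0, hill_exponent = hill_exponent,
    T_R = 1, M_R = 12, T_min = 5, lam = 0.08, M_Lambda = 4)
}

#' Construct NoiseSettings
#'
#' @param omega_phi genetic noise amplitude (>= 0).
#' @param omega_lambda growth noise amplitude (>= 0).
#' @param seed integer RNG seed.
#' @return A [NoiseSettings] object.
#' @export
noiseSettings <- function(omega_phi = 0.07, omega_lambda = 0.05, seed = 1L) {
  new("NoiseSettings", omega_phi = omega_phi, omega_lambda = omega_lambda,
      seed = as.integer(seed))
}

#' Construct a SimulationConfig
#'
#' @param dt,t_end,record_every,n_initial_cells,initial_size_policy,initial_concentration_policy
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig] object.
#' @export
simulationConfig <- function(dt = 0.01, t_end = 72, record_every = 1,
                             n_initial_cells = 30L,
                             initial_size_policy = "uniform",
                             initial_concentration_policy = "zero") {
  new("SimulationConfig", dt = dt, t_end = t_end,
      record_every = record_every,
      n_initial_cells = as.integer(n_initial_cells),
      initial_size_policy = initial_size_policy,
      initial_concentration_policy = initial_concentration_policy)
}

.MUTANT_TABLE <- list(
  WT          = c(S = 1,   N = 1, A = 1, F = 1),
  dpatS       = c(S = 0.1, N = 1, A = 1, F = 1),
  dpatX       = c(S = 0.9, N = 1, A = 1, F = 1),
  dpatSdpatX  = c(S = 0,   N = 1, A = 1, F = 1),
  dhetN       = c(S = 1,   N = 0, A = 1, F = 1),
  dpatA       = c(S = 1,   N = 1, A = 0, F = 1),
  dhetF       = c(S = 1,   N = 1, A = 1, F = 0),
  dpatAdhetN  = c(S = 1,   N = 0, A = 0, F = 1),
  dpatAdpatS  = c(S = 0.1, N = 1, A = 0, F = 1)
)

#' Named mutant presets
#'
#' Loss-of-function backgrounds are modeled by zeroing the corresponding
#' production rate, except patS deletion which retains 10\% of the combined
#' PatS+PatX production (the patX redundancy) and patX deletion which
#' removes only that 10\%.  `no_border_leak = TRUE` additionally sets the
#' terminal-cell leakage to zero (the control used to show that terminal
#' heterocysts require leakage).
#'
#' @param name one of `"WT"`, `"dpatS"`, `"dpatX"`, `"dpatSdpatX"`,
#'   `"dhetN"`, `"dpatA"`, `"dhetF"`, `"dpatAdhetN"`, `"dpatAdpatS"`.
#' @param no_border_leak set the `d_border` factor to 0.
#' @return A [MutantSpec] object.
#' @examples
#' mutantSpec("dpatS")
#' mutantSpec("dpatA", no_border_leak = TRUE)
#' @export
mutantSpec <- function(name = "WT", no_border_leak = FALSE) {
  if (!name %in% names(.MUTANT_TABLE))
    stop("unknown mutant '", name, "'; known: ",
         paste(names(.MUTANT_TABLE), collapse = ", "))
  f <- .MUTANT_TABLE[[name]]
  lab <- if (no_border_leak) paste0(name, "+no_border_leak") else name
  new("MutantSpec", rho_S_factor = unname(f["S"]),
      rho_N_factor = unname(f["N"]), rho_A_factor = unname(f["A"]),
      beta_F_factor = unname(f["F"]),
      d_border_factor = if (no_border_leak) 0 else 1,
      label = lab)
}

#' Combine two mutant overlays
#'
#' Factors compose multiplicatively, so double and triple mutants are the
#' product of their single-mutant overlays.
#'
#' @param a,b [MutantSpec] objects.
#' @return The combined [MutantSpec].
#' @export
combineMutants <- function(a, b) {
  stopifnot(is(a, "MutantSpec"), is(b, "MutantSpec"))
  new("MutantSpec",
      rho_S_factor = a@rho_S_factor * b@rho_S_factor,
      rho_N_factor = a@rho_N_factor * b@rho_N_factor,
      rho_A_factor = a@rho_A_factor * b@rho_A_factor,
      beta_F_factor = a@beta_F_factor * b@beta_F_factor,
      d_border_factor = a@d_border_factor * b@d_border_factor,
      label = paste(a@label, b@label, sep = "*"))
}

#' Apply a mutant overlay to a parameter set
#'
#' Returns a copy of `params` with `rho_S`, `rho_N`, `rho_A`, `beta_F` and
#' `d_border` multiplied by their overlay factors.  Because the lumped
#' activation constant `F_R` is proportional to the equilibrium HetF level
#' `beta_F / alpha_F`, the `beta_F` factor is also applied to `F_R`, so the
#' hetF deletion abolishes all regulated production.
#'
#' Production rates scaled to zero are replaced by a tiny positive floor
#' (1e-12, dynamically indistinguishable from zero) so the result remains a
#' valid parameter object.
#'
#' @param params a [ModelParameters] object.
#' @param mutant a [MutantSpec] object.
#' @return A new [ModelParameters]; the input is untouched.
#' @export
applyMutant <- function(params, mutant) {
  stopifnot(is(params, "ModelParameters"), is(mutant, "MutantSpec"))
  eps <- 1e-12
  p <- params
  p@rho_S <- max(params@rho_S * mutant@rho_S_factor, eps)
  p@rho_N <- max(params@rho_N * mutant@rho_N_factor, eps)
  p@rho_A <- max(params@rho_A * mutant@rho_A_factor, eps)
  p@beta_F <- params@beta_F * mutant@beta_F_factor
  p@F_R <- params@F_R * mutant@beta_F_factor
  p@d_border <- params@d_border * mutant@d_border_factor
  validObject(p)
  p
}

#' @describeIn ModelParameters-class compact display of all parameters.
#' @param object a [ModelParameters] object.
#' @export
setMethod("show", "ModelParameters", function(object) {
  nms <- slotNames(object)
  v <- vapply(nms, function(nm) slot(object, nm), numeric(1))
  cat("ModelParameters (time in h, length in um)\n")
  print(signif(v, 4))
  invisible(object)
})

setMethod("show", "MutantSpec", function(object) {
  cat("MutantSpec:", object@label, "\n",
      sprintf("  rho_S x%.2g  rho_N x%.2g  rho_A x%.2g  beta_F x%.2g  d_border x%.2g\n",
              object@rho_S_factor, object@rho_N_factor, object@rho_A_factor,
              object@beta_F_factor, object@d_border_factor))
  invisible(object)
})
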