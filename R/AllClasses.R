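#' @import methods
NULL

SPECIES <- c("R", "A", "S", "N", "I", "G")

#' Kinetic constants of HetR dimerization and HetF activation
#'
#' Holds the microscopic constants of HetR monomer-dimer kinetics and of the
#' activation of HetR dimers by HetF.  These constants never enter the
#' integrator directly: they exist only to derive the lumped nonlinear
#' degradation coefficient (see [muFromKinetics()]) and the lumped activation
#' constant (see [frFromConstants()]).
#'
#' @slot k_b monomer-monomer binding rate.
#' @slot k_u dimer unbinding rate.
#' @slot alpha_d dimer degradation rate (per hour).
#' @slot K_R equilibrium constant of HetR dimerization.
#' @slot K_F equilibrium constant of HetF activation of the dimer.
#' @export
setClass("DimerKinetics",
  representation(k_b = "numeric", k_u = "numeric", alpha_d = "numeric",
                 K_R = "numeric", K_F = "numeric"),
  prototype(k_b = 1, k_u = 1, alpha_d = 1, K_R = 1, K_F = 1),
  validity = function(object) {
    v <- c(k_b = object@k_b, k_u = object@k_u, alpha_d = object@alpha_d,
           K_R = object@K_R, K_F = object@K_F)
    if (any(!is.finite(v)) || any(v < 0))
      return("all kinetic constants must be finite and >= 0")
    TRUE
  })

#' Full parameter set of the filament model
#'
#' One object holds every rate, affinity and threshold of the per-cell
#' regulatory dynamics (HetR, PatA, combined PatS+PatX, HetN, the mobile
#' hexapeptide inhibitor and fixed nitrogen), the boundary-leakage
#' multiplier, and the commitment and growth parameters.
#'
#' Units: time in hours, cell length in micrometres, concentrations in
#' arbitrary units.  Dilution by growth is folded into the linear alpha
#' rates.
#'
#' @slot beta_R basal HetR production (conc/h).
#' @slot rho_R,rho_A,rho_S,rho_N,rho_G maximum regulated production rates
#'   (conc/h).
#' @slot alpha_R,alpha_A,alpha_S,alpha_N,alpha_I,alpha_G,alpha_F linear
#'   degradation+dilution rates (1/h).
#' @slot beta_F basal HetF production (conc/h); 0 for the hetF deletion.
#' @slot mu nonlinear HetR degradation coefficient (1/conc).
#' @slot c_S,c_N membrane conversion/export rates of PatS and HetN into the
#'   mobile hexapeptide (1/h).
#' @slot d_I,d_G intercellular transport rates of hexapeptide and fixed
#'   nitrogen (1/h).
#' @slot d_border dimensionless multiplier (>= 0) on `d_I`, `d_G` for
#'   leakage from the two terminal cells to the medium.
#' @slot F_R lumped activation constant (1/conc^2); equals
#'   `F_eq * K_F * K_R / 2`.
#' @slot tau_A PatA activation scale (conc).
#' @slot K_d hexapeptide-HetR inhibition scale (conc).
#' @slot K_G fixed-nitrogen inhibition scale (conc).
#' @slot hill_exponent HetR oligomer order in the regulatory function, 2
#'   (dimer) or 4 (tetramer).
#' @slot T_R mean commitment threshold on HetR (conc).
#' @slot M_R mean commitment integral (conc*h); by convention `12 * T_R`.
#' @slot T_min minimum time continuously above threshold before
#'   differentiation (h).
#' @slot lam cell growth rate (um/h).
#' @slot M_Lambda mean maximum cell size (um).
#' @seealso [modelParameters()], [wildTypeParameters()]
#' @export
setClass("ModelParameters",
  representation(
    beta_R = "numeric", rho_R = "numeric", rho_A = "numeric",
    rho_S = "numeric", rho_N = "numeric", rho_G = "numeric",
    alpha_R = "numeric", alpha_A = "numeric", alpha_S = "numeric",
    alpha_N = "numeric", alpha_I = "numeric", alpha_G = "numeric",
    alpha_F = "numeric", beta_F = "numeric", mu = "numeric",
    c_S = "numeric", c_N = "numeric", d_I = "numeric", d_G = "numeric",
    d_border = "numeric", F_R = "numeric", tau_A = "numeric",
    K_d = "numeric", K_G = "numeric", hill_exponent = "numeric",
    T_R = "numeric", M_R = "numeric", T_min = "numeric",
    lam = "numeric", M_Lambda = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    pos <- c("rho_R", "rho_A", "rho_S", "rho_N", "rho_G",
             "alpha_R", "alpha_A", "alpha_S", "alpha_N", "alpha_I",
             "alpha_G", "alpha_F", "c_S", "c_N", "d_I", "d_G",
             "tau_A", "K_d", "K_G", "T_R", "M_R", "T_min",
             "lam", "M_Lambda", "beta_R")
    for (nm in pos) {
      v <- slot(object, nm)
      if (length(v) != 1 || !is.finite(v) || v <= 0)
        msgs <- c(msgs, sprintf("'%s' must be a single finite value > 0", nm))
    }
    nonneg <- c("d_border", "beta_F", "F_R", "mu")
    for (nm in nonneg) {
      v <- slot(object, nm)
      if (length(v) != 1 || !is.finite(v) || v < 0)
        msgs <- c(msgs, sprintf("'%s' must be a single finite value >= 0", nm))
    }
    if (!object@hill_exponent %in% c(2, 4))
      msgs <- c(msgs, "'hill_exponent' must be 2 or 4")
    if (length(msgs)) msgs else TRUE
  })

#' Amplitudes of the genetic and growth noise
#'
#' @slot omega_phi dimensionless amplitude of the genetic (Langevin) noise;
#'   also parameterizes the cell-to-cell variance of the commitment
#'   thresholds.
#' @slot omega_lambda dimensionless amplitude of the growth noise; also
#'   parameterizes the variance of the maximum cell size.
#' @slot seed integer seed used by [runSimulation()].
#' @export
setClass("NoiseSettings",
  representation(omega_phi = "numeric", omega_lambda = "numeric",
                 seed = "integer"),
  prototype(omega_phi = 0.07, omega_lambda = 0.05, seed = 1L),
  validity = function(object) {
    if (object@omega_phi < 0 || object@omega_lambda < 0)
      return("noise amplitudes must be >= 0")
    TRUE
  })

#' Loss-of-function overlay on the wild-type parameters
#'
#' Each factor multiplies the corresponding wild-type rate; deletions set a
#' factor to 0, except patS deletion which keeps 10\% of the combined
#' PatS+PatX production (the patX redundancy).  Factors compose by
#' multiplication for double and triple mutants.
#'
#' @slot rho_S_factor multiplier on combined PatS+PatX production.
#' @slot rho_N_factor multiplier on HetN production.
#' @slot rho_A_factor multiplier on PatA production.
#' @slot beta_F_factor multiplier on basal HetF production (propagates to
#'   the lumped activation constant `F_R`).
#' @slot d_border_factor multiplier on the terminal-cell leakage rate.
#' @slot label human-readable mutant name.
#' @seealso [mutantSpec()], [applyMutant()]
#' @export
setClass("MutantSpec",
  representation(rho_S_factor = "numeric", rho_N_factor = "numeric",
                 rho_A_factor = "numeric", beta_F_factor = "numeric",
                 d_border_factor = "numeric", label = "character"),
  prototype(rho_S_factor = 1, rho_N_factor = 1, rho_A_factor = 1,
            beta_F_factor = 1, d_border_factor = 1, label = "WT"),
  validity = function(object) {
    v <- c(object@rho_S_factor, object@rho_N_factor, object@rho_A_factor,
           object@beta_F_factor, object@d_border_factor)
    if (any(!is.finite(v)) || any(v < 0))
      return("all mutant factors must be finite and >= 0")
    TRUE
  })

#' Integration and recording settings for one run
#'
#' @slot dt Euler-Maruyama step (h).
#' @slot t_end simulated duration after nitrogen step-down (h).
#' @slot record_every snapshot cadence (h).
#' @slot n_initial_cells number of vegetative cells at t = 0.
#' @slot initial_size_policy `"uniform"` draws initial sizes uniformly on
#'   `[M_Lambda/2, M_Lambda]` (desynchronizes divisions); `"half_max"`
#'   starts every cell at `M_Lambda/2`.
#' @slot initial_concentration_policy only `"zero"`: all species start at 0,
#'   the state right after combined nitrogen is removed.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", t_end = "numeric", record_every = "numeric",
                 n_initial_cells = "integer",
                 initial_size_policy = "character",
                 initial_concentration_policy = "character"),
  prototype(dt = 0.01, t_end = 72, record_every = 1,
            n_initial_cells = 30L, initial_size_policy = "uniform",
            initial_concentration_policy = "zero"),
  validity = function(object) {
    if (!(object@dt > 0 && object@dt <= object@record_every &&
          object@record_every <= object@t_end))
      return("need 0 < dt <= record_every <= t_end")
    if (object@n_initial_cells < 1L)
      return("n_initial_cells must be >= 1")
    if (!object@initial_size_policy %in% c("uniform", "half_max"))
      return("initial_size_policy must be 'uniform' or 'half_max'")
    if (!object@initial_concentration_policy %in% "zero")
      return("initial_concentration_policy must be 'zero'")
    TRUE
  })

#' State of a filament of cells
#'
#' The cells are stored column-wise: one row per cell, ordered left to
#' right along the filament.  Per-cell commitment thresholds are drawn once
#' at cell creation and never redrawn.
#'
#' @slot conc numeric matrix, one row per cell, columns `R, A, S, N, I, G`
#'   (HetR, PatA, PatS+PatX, HetN, hexapeptide, fixed nitrogen).
#' @slot size cell sizes (um).
#' @slot het logical, TRUE for heterocysts.
#' @slot tR,mR per-cell commitment threshold and integral target.
#' @slot mLambda per-cell maximum size.
#' @slot commitIntegral accumulated HetR integral while above threshold.
#' @slot commitClock time continuously above threshold (h).
#' @slot time simulation clock (h).
#' @export
setClass("Filament",
  representation(conc = "matrix", size = "numeric", het = "logical",
                 tR = "numeric", mR = "numeric", mLambda = "numeric",
                 commitIntegral = "numeric", commitClock = "numeric",
                 time = "numeric"),
  validity = function(object) {
    n <- nrow(object@conc)
    if (n < 1) return("filament must contain at least one cell")
    if (!identical(colnames(object@conc), SPECIES))
      return("conc columns must be R, A, S, N, I, G")
    lens <- c(length(object@size), length(object@het), length(object@tR),
              length(object@mR), length(object@mLambda),
              length(object@commitIntegral), length(object@commitClock))
    if (any(lens != n)) return("per-cell vectors must match nrow(conc)")
    if (any(object@conc < 0)) return("concentrations must be >= 0")
    if (any(object@size <= 0)) return("cell sizes must be > 0")
    if (any(object@commitIntegral < 0))
      return("commitIntegral must be >= 0")
    TRUE
  })

#' Production/degradation split of the deterministic drift
#'
#' `production` collects every positively signed term of the per-cell
#' equations (basal and regulated synthesis, conversion and transport
#' influx from neighbours); `degradation` collects every negatively signed
#' term (linear and nonlinear decay, conversion loss, transport efflux
#' including terminal leakage).  Their sum is the exact deterministic
#' right-hand side; their combination `production + |degradation|` sets the
#' local Langevin noise amplitude.
#'
#' @slot production matrix (cells x species), termwise >= 0.
#' @slot degradation matrix (cells x species), termwise <= 0.
#' @export
setClass("DriftDecomposition",
  representation(production = "matrix", degradation = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@production), dim(object@degradation)))
      return("production and degradation must have identical dimensions")
    if (any(object@production < 0)) return("production must be >= 0")
    if (any(object@degradation > 0)) return("degradation must be <= 0")
    TRUE
  })

#' Recorded time course of one simulation
#'
#' @slot snapshots list of [Filament] objects at strictly increasing times.
#' @slot params the post-overlay [ModelParameters] actually integrated.
#' @slot mutant the [MutantSpec] applied.
#' @slot noise the [NoiseSettings] used (including the seed).
#' @slot config the [SimulationConfig] used.
#' @export
setClass("Trajectory",
  representation(snapshots = "list", params = "ModelParameters",
                 mutant = "MutantSpec", noise = "NoiseSettings",
                 config = "SimulationConfig"),
  validity = function(object) {
    if (!length(object@snapshots)) return("no snapshots")
    tt <- vapply(object@snapshots, function(f) f@time, numeric(1))
    if (any(diff(tt) <= 0)) return("snapshot times must strictly increase")
    nh <- vapply(object@snapshots, function(f) sum(f@het), numeric(1))
    if (any(diff(nh) < 0)) return("heterocyst count must be non-decreasing")
    TRUE
  })

#' Pattern statistics of a single filament
#'
#' @slot intervals lengths of vegetative runs bounded by heterocysts on
#'   both sides (end-of-filament runs excluded).
#' @slot m mean vegetative interval (NA when no interval exists).
#' @slot p heterocyst percentage of the filament (0-100).
#' @slot cluster_histogram table of contiguous-heterocyst run lengths.
#' @slot terminal_count contiguous heterocysts at the two filament ends.
#' @slot mean_R_veg mean HetR over vegetative cells.
#' @export
setClass("PatternSummary",
  representation(intervals = "numeric", m = "numeric", p = "numeric",
                 cluster_histogram = "table", terminal_count = "numeric",
                 mean_R_veg = "numeric"))

#' Batch-aggregated pattern statistics
#'
#' Statistics are pooled within each batch of filaments and then averaged
#' across batches; `sd` columns are sample (n-1) standard deviations across
#' batches, mirroring replicate-based experimental error bars.
#'
#' @slot per_batch data.frame with one row per batch (columns `batch`, `m`,
#'   `p`, `terminal`, `mean_R_veg`, `n_cells`).
#' @slot mean,sd named numeric vectors of across-batch means and SDs.
#' @slot intervals list of pooled interval samples, one per batch.
#' @slot time_h the filament age at which statistics were taken.
#' @export
setClass("BatchResult",
  representation(per_batch = "data.frame", mean = "numeric", sd = "numeric",
                 intervals = "list", time_h = "numeric"))

#' Reference summary dataset for calibration
#'
#' Entries are keyed by condition and time.  Group `"O"` entries (wild
#' type, patS and hetN deletions) are compared on interval histogram, mean
#' interval and heterocyst percentage; group `"N"` entries (patA
#' backgrounds) are compared on histogram shape while their simulated
#' heterocyst percentage is penalized directly.
#'
#' @slot entries named list; each element has fields `condition`, `time_h`,
#'   `group` ("O" or "N"), `sample` (numeric), `m`, `p`.
#' @export
setClass("ReferenceDataset",
  representation(entries = "list"),
  validity = function(object) {
    for (e in object@entries) {
      if (!all(c("condition", "time_h", "group", "sample", "m", "p")
               %in% names(e)))
        return("each entry needs condition, time_h, group, sample, m, p")
      if (!e$group %in% c("O", "N")) return("group must be 'O' or 'N'")
    }
    TRUE
  })

#' Weights of the calibration energy
#'
#' @slot w1,w2,w3,w4 non-negative weights; `w1`, `w2` act on the "O" group
#'   (histogram distance; mean-interval and percentage errors), `w3`, `w4`
#'   on the "N" group (histogram distance; direct heterocyst-percentage
#'   penalty).  Defaults (1000, 10, 500, 1).
#' @export
setClass("EnergyWeights",
  representation(w1 = "numeric", w2 = "numeric", w3 = "numeric",
                 w4 = "numeric"),
  prototype(w1 = 1000, w2 = 10, w3 = 500, w4 = 1),
  validity = function(object) {
    if (any(c(object@w1, object@w2, object@w3, object@w4) < 0))
      return("weights must be >= 0")
    TRUE
  })

#' Result of one relative-sensitivity evaluation
#'
#' @slot parameter name of the perturbed parameter.
#' @slot baseline_X,perturbed_X parameter values before/after perturbation.
#' @slot frac relative perturbation applied.
#' @slot observable name of the observable.
#' @slot baseline_Y,perturbed_Y observable values.
#' @slot S the relative sensitivity `(dY/Y)/(dX/X)`.
#' @export
setClass("SensitivityResult",
  representation(parameter = "character", baseline_X = "numeric",
                 perturbed_X = "numeric", frac = "numeric",
                 observable = "character", baseline_Y = "numeric",
                 perturbed_Y = "numeric", S = "numeric"))

#' Continuum activator-inhibitor setup
#'
#' A non-diffusing activator and a diffusing inhibitor on a fixed domain
#' `[0, L]`, with either zero-flux or absorbing boundary conditions on the
#' inhibitor.  Used to show that absorbing boundaries alone produce
#' activator maxima at the domain ends.
#'
#' @slot beta_r basal activator production (> 0).
#' @slot rho_r,rho_s maximum regulated production rates.
#' @slot alpha_r,alpha_s linear decay rates.
#' @slot d inhibitor diffusivity.
#' @slot L domain length.
#' @slot f regulatory function `f(r, s)`, smooth, increasing in `r`,
#'   decreasing in `s`.
#' @slot bc `"zeroflux"` or `"absorbing"`.
#' @slot nx number of grid nodes (>= 3).
#' @export
setClass("ContinuumParams",
  representation(beta_r = "numeric", rho_r = "numeric", rho_s = "numeric",
                 alpha_r = "numeric", alpha_s = "numeric", d = "numeric",
                 L = "numeric", f = "function", bc = "character",
                 nx = "integer"),
  validity = function(object) {
    v <- c(object@beta_r, object@rho_r, object@rho_s, object@alpha_r,
           object@alpha_s, object@d, object@L)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all continuum rates and L must be finite and > 0")
    if (!object@bc %in% c("zeroflux", "absorbing"))
      return("bc must be 'zeroflux' or 'absorbing'")
    if (object@nx < 3L) return("nx must be >= 3")
    TRUE
  })
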