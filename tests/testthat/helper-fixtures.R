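# Small deterministic parameter set for unit tests (unrelated to the
# calibrated wild-type preset so tests do not silently depend on it).
testParams <- function(...) {
  p <- modelParameters(
    beta_R = 0.1, rho_R = 2, rho_A = 1, rho_S = 3, rho_N = 4, rho_G = 5,
    alpha_R = 0.5, alpha_A = 0.6, alpha_S = 0.7, alpha_N = 0.8,
    alpha_I = 0.9, alpha_G = 1.0, alpha_F = 1, beta_F = 1, mu = 0.2,
    c_S = 0.3, c_N = 0.4, d_I = 2, d_G = 3, d_border = 0.5, F_R = 1,
    tau_A = 0.5, K_d = 0.6, K_G = 0.7, hill_exponent = 2,
    T_R = 1, M_R = 12, T_min = 5, lam = 0.08, M_Lambda = 4)
  over <- list(...)
  for (nm in names(over)) slot(p, nm) <- over[[nm]]
  p
}

# Build a Filament directly from a heterocyst pattern and concentrations.
makeFilament <- function(het, conc = NULL, size = NULL, time = 0,
                         params = testParams()) {
  n <- length(het)
  if (is.null(conc)) conc <- matrix(0, n, 6)
  colnames(conc) <- c("R", "A", "S", "N", "I", "G")
  if (is.null(size)) size <- rep(params@M_Lambda / 2, n)
  new("Filament", conc = conc, size = size, het = as.logical(het),
      tR = rep(params@T_R, n), mR = rep(params@M_R, n),
      mLambda = rep(params@M_Lambda, n),
      commitIntegral = rep(0, n), commitClock = rep(0, n), time = time)
}

# Independent, cell-by-cell transcription of the model equations, written
# as plain scalar loops with no shared code with the package's vectorized
# drift kernel.  Returns the full right-hand side (drift) matrix.
oracleDrift <- function(conc, het, p) {
  n <- nrow(conc)
  h <- p@hill_exponent
  out <- matrix(0, n, 6)
  g <- function(j) {
    num <- p@F_R * conc[j, 1]^h * (1 + conc[j, 2] / p@tau_A)
    num / (1 + num + conc[j, 5]^2 / p@K_d^2 + conc[j, 6] / p@K_G)
  }
  for (j in seq_len(n)) {
    R <- conc[j, 1]; A <- conc[j, 2]; S <- conc[j, 3]
    Nn <- conc[j, 4]; I <- conc[j, 5]; G <- conc[j, 6]
    d <- as.numeric(het[j])
    gj <- g(j)
    out[j, 1] <- p@beta_R + gj * p@rho_R - p@alpha_R * R * (1 + 2 * p@mu * R)
    out[j, 2] <- gj * p@rho_A - p@alpha_A * A
    out[j, 3] <- (1 - d) * gj * p@rho_S - 2 * p@c_S * S - p@alpha_S * S
    out[j, 4] <- d * p@rho_N - 2 * p@c_N * Nn - p@alpha_N * Nn
    if (n == 1) {
      # symmetric extension: both faces leak to the medium
      out[j, 5] <- -2 * p@d_border * p@d_I * I - p@alpha_I * I
      out[j, 6] <- d * p@rho_G - 2 * p@d_border * p@d_G * G - p@alpha_G * G
    } else if (j == 1) {
      out[j, 5] <- p@c_S * conc[2, 3] + p@c_N * conc[2, 4] -
        p@d_border * p@d_I * I + p@d_I * (conc[2, 5] - I) - p@alpha_I * I
      out[j, 6] <- d * p@rho_G - p@d_border * p@d_G * G +
        p@d_G * (conc[2, 6] - G) - p@alpha_G * G
    } else if (j == n) {
      out[j, 5] <- p@c_S * conc[n - 1, 3] + p@c_N * conc[n - 1, 4] -
        p@d_border * p@d_I * I + p@d_I * (conc[n - 1, 5] - I) -
        p@alpha_I * I
      out[j, 6] <- d * p@rho_G - p@d_border * p@d_G * G +
        p@d_G * (conc[n - 1, 6] - G) - p@alpha_G * G
    } else {
      out[j, 5] <- p@c_S * (conc[j - 1, 3] + conc[j + 1, 3]) +
        p@c_N * (conc[j - 1, 4] + conc[j + 1, 4]) +
        p@d_I * (conc[j - 1, 5] - 2 * I + conc[j + 1, 5]) - p@alpha_I * I
      out[j, 6] <- d * p@rho_G +
        p@d_G * (conc[j - 1, 6] - 2 * G + conc[j + 1, 6]) - p@alpha_G * G
    }
  }
  colnames(out) <- c("R", "A", "S", "N", "I", "G")
  out
}

randomConc <- function(n) {
  matrix(stats::runif(6 * n, 0, 3), n, 6,
         dimnames = list(NULL, c("R", "A", "S", "N", "I", "G")))
}
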