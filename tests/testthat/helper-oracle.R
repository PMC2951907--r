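# Independent straight-line transcriptions of the flux equations, coded
# directly from the model definitions with no shared helpers, used as
# oracles for the package implementations. Plain exp/sinh arithmetic; only
# valid away from the removable singularity at dpsi = 0.

oracle_phi_reduced <- function(dpsi_mV, T_K = 298.15) {
  96485 * (dpsi_mV / 1000) / (8.314 * T_K)
}

oracle_ghk_rates <- function(k0, phi) {
  # standard constant-field rate coefficients for the charge-4 complex
  list(k_in = k0 * 4 * phi / (1 - exp(-4 * phi)),
       k_out = k0 * 4 * phi / (exp(4 * phi) - 1))
}

oracle_flux_previous <- function(ca_e, ca_x, dpsi, k_in0, k_out0, K_e0, K_x0,
                                 alpha_e, alpha_x, beta_e, beta_x,
                                 variant = "model1", T_K = 298.15) {
  phi <- oracle_phi_reduced(dpsi, T_K)
  K_e <- K_e0 * exp(-2 * alpha_e * phi)
  K_x <- K_x0 * exp(+2 * alpha_x * phi)
  k_in <- k_in0 * exp(+4 * beta_e * phi)
  k_out <- k_out0 * exp(-4 * beta_x * phi)
  re <- ca_e / K_e
  rx <- ca_x / K_x
  D <- 1 + re^2 + rx^2
  if (variant == "model2") D <- D + re + rx
  (k_in * re^2 - k_out * rx^2) / D
}

oracle_flux_present <- function(ca_e, ca_x, dpsi, k0, K0, alpha, nH,
                                variant = "model1", T_K = 298.15) {
  phi <- oracle_phi_reduced(dpsi, T_K)
  s <- 1 - 2 * alpha
  u <- 2 * s * phi / nH
  Phi <- (u / sinh(u))^nH
  k_in <- k0 * Phi * exp(+2 * s * phi)
  k_out <- k0 * Phi * exp(-2 * s * phi)
  K_e <- K0 * exp(-2 * alpha * phi)
  K_x <- K0 * exp(+2 * alpha * phi)
  re <- ca_e / K_e
  rx <- ca_x / K_x
  D <- 1 + re^2 + rx^2
  if (variant == "model2") D <- D + re + rx
  (k_in * re^2 - k_out * rx^2) / D
}

# random constraint-satisfying Eyring-barrier parameter sets
random_previous_params <- function(n, case = "case1", variant = "model1") {
  lapply(seq_len(n), function(i) {
    alpha <- stats::runif(1, 0, 0.2)
    beta_e <- stats::runif(1, 0.05, 0.95) * (1 - 2 * alpha)
    if (case == "case1") {
      apply_case(c(10^stats::runif(1, -2, 1), 10^stats::runif(1, -5.5, -3.5),
                   alpha, beta_e),
                 case = "case1", variant = variant)
    } else {
      K_e0 <- 10^stats::runif(1, -5.5, -3.5)
      apply_case(c(10^stats::runif(1, -2, 1), K_e0,
                   K_e0 * 10^stats::runif(1, -0.5, 0.5), alpha, beta_e),
                 case = "case2", variant = variant)
    }
  })
}

random_present_params <- function(n, variant = "model1") {
  lapply(seq_len(n), function(i) {
    mcu_params_present(k0 = 10^stats::runif(1, -3, 0.5),
                       K0 = 10^stats::runif(1, -5.5, -3.5),
                       alpha = stats::runif(1, 0, 0.2),
                       nH = stats::runif(1, 0.5, 6),
                       variant = variant)
  })
}
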