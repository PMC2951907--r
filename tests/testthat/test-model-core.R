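th <- thermo_context()

test_that("translocation factor is even, anchored at 1, and smooth across the series branch", {
  for (nH in c(0.3, 1, 2.65, 8)) {
    x <- seq(-10, 10, length.out = 401)
    expect_identical(phi_factor(x, nH), phi_factor(-x, nH))
    expect_identical(phi_factor(0, nH), 1)
    # series and direct branches agree around the switch point
    eps <- c(0.9e-4, 0.99e-4, 1.01e-4, 1.1e-4)
    direct <- (eps / (nH / 2) / sinh(2 * eps / nH))^nH
    expect_equal(phi_factor(eps, nH), direct, tolerance = 1e-12)
  }
  expect_error(phi_factor(1, 0), "positive")
  expect_error(phi_factor(1, -2), "positive")
})

test_that("nH = 1 reduces the rate constants to the constant-field (GHK) expressions", {
  p <- mcu_params_present(k0 = 0.37, K0 = 50e-6, alpha = 0, nH = 1)
  phi <- seq(-9.5, 9.5, length.out = 100)
  phi <- phi[phi != 0]
  rc <- rate_constants_present(p, phi)
  gh <- oracle_ghk_rates(0.37, phi)
  expect_equal(rc$k_in, gh$k_in, tolerance = 1e-10)
  expect_equal(rc$k_out, gh$k_out, tolerance = 1e-10)
})

test_that("Eyring-barrier binding and rate constants have the published potential dependence", {
  p <- packaged_params("previous/model1/case1")
  expect_equal(binding_constants_previous(p, 0),
               list(K_e = p$K_e0, K_x = p$K_x0))
  expect_equal(rate_constants_previous(p, 0),
               list(k_in = p$k_in0, k_out = p$k_out0))
  # alpha = 0 in the packaged set: binding constants potential-independent
  phi <- seq(-8, 8, length.out = 17)
  bc <- binding_constants_previous(p, phi)
  expect_equal(bc$K_e, rep(p$K_e0, 17))
  expect_equal(bc$K_x, rep(p$K_x0, 17))
  # displaced binding sites shift the constants exponentially (frozen oracle)
  pa <- mcu_params_previous(k_in0 = 0.3, K_e0 = 45.9e-6,
                            alpha_e = 0.1, beta_e = 0.113,
                            case = "case2")
  bca <- binding_constants_previous(pa, 1)
  expect_equal(bca$K_e, 3.757974157e-05, tolerance = 1e-9)
  expect_equal(bca$K_x, 5.60623866e-05, tolerance = 1e-9)
  # frozen oracle values for the liver set at 190 mV
  rc <- rate_constants_previous(p, reduced_potential(190, th))
  expect_equal(rc$k_in, 8.489253756, tolerance = 1e-9)
  expect_equal(rc$k_out, 1.206534583e-12, tolerance = 1e-9)
  # monotone in phi for nonnegative barrier displacements
  rcg <- rate_constants_previous(p, phi)
  expect_true(all(diff(rcg$k_in) > 0))
  expect_true(all(diff(rcg$k_out) < 0))
  # zero displacements freeze the rate constants
  p0 <- mcu_params_previous(k_in0 = 0.5, K_e0 = 1e-5, beta_e = 0, beta_x = 1,
                            case = "case2")
  p0$beta_x <- 0   # direct evaluation of the beta = 0 limit
  rc0 <- rate_constants_previous(p0, phi)
  expect_equal(rc0$k_in, rep(0.5, 17))
  expect_equal(rc0$k_out, rep(0.5, 17))
})

test_that("generalized-GHK rate constants share the even factor and opposite exponentials", {
  p <- packaged_params("present/model1/liver")
  expect_equal(rate_constants_present(p, 0), list(k_in = p$k0, k_out = p$k0))
  phi <- seq(-9, 9, length.out = 61)
  rc_fwd <- rate_constants_present(p, phi)
  rc_rev <- rate_constants_present(p, -phi)
  expect_equal(rc_fwd$k_in, rc_rev$k_out, tolerance = 1e-14)
  # frozen oracle values at 190 mV (liver, k0 = 0.0142, nH = 2.65)
  rc <- rate_constants_present(p, reduced_potential(190, th))
  expect_equal(rc$k_in, 8.490412514, tolerance = 1e-9)
  expect_equal(rc$k_out, 1.206699271e-12, tolerance = 1e-9)
})

test_that("flux denominator distinguishes full and partial cooperativity", {
  expect_identical(flux_denominator(0, 0, 1e-6, 1e-6, "model1"), 1)
  expect_identical(flux_denominator(0, 0, 1e-6, 1e-6, "model2"), 1)
  # ca_e = K_e, ca_x = K_x: transcribed saturation values
  expect_equal(flux_denominator(2e-6, 3e-6, 2e-6, 3e-6, "model1"), 3)
  expect_equal(flux_denominator(2e-6, 3e-6, 2e-6, 3e-6, "model2"), 5)
  g <- expand.grid(ca_e = c(1e-7, 1e-6, 1e-5), ca_x = c(1e-8, 1e-6))
  d1 <- flux_denominator(g$ca_e, g$ca_x, 2e-6, 5e-7, "model1")
  d2 <- flux_denominator(g$ca_e, g$ca_x, 2e-6, 5e-7, "model2")
  expect_true(all(d1 >= 1))
  expect_true(all(d2 - d1 >= 0))
  expect_error(flux_denominator(1e-6, 1e-6, -1e-6, 1e-6), "positive")
})

test_that("flux implementations match the independently transcribed oracles", {
  set.seed(421)
  n <- 100
  ca_e <- 10^runif(n, -7, -3.5)
  ca_x <- 10^runif(n, -8, -6)
  dpsi <- runif(n, -220, 220)
  dpsi[abs(dpsi) < 1] <- 25   # oracle is undefined at the 0/0 point
  for (variant in c("model1", "model2")) {
    pp <- packaged_params(paste0("previous/", variant, "/case1"))
    expect_equal(flux_previous(pp, ca_e, ca_x, dpsi, th),
                 oracle_flux_previous(ca_e, ca_x, dpsi, pp$k_in0, pp$k_out0,
                                      pp$K_e0, pp$K_x0, pp$alpha_e, pp$alpha_x,
                                      pp$beta_e, pp$beta_x, variant),
                 tolerance = 1e-10)
    pr <- packaged_params(paste0("present/", variant, "/liver"))
    expect_equal(flux_present(pr, ca_e, ca_x, dpsi, th),
                 oracle_flux_present(ca_e, ca_x, dpsi, pr$k0, pr$K0,
                                     pr$alpha, pr$nH, variant),
                 tolerance = 1e-10)
  }
  # and for a displaced-binding-site generalized-GHK set
  pa <- mcu_params_present(k0 = 0.1, K0 = 30e-6, alpha = 0.12, nH = 1.8)
  expect_equal(flux_present(pa, ca_e, ca_x, dpsi, th),
               oracle_flux_present(ca_e, ca_x, dpsi, 0.1, 30e-6, 0.12, 1.8),
               tolerance = 1e-10)
})

test_that("frozen oracle flux values for the packaged parameter sets", {
  p_prev <- packaged_params("previous/model1/case1")
  expect_equal(flux_previous(p_prev, 50e-6, 250e-9, 190, th),
               4.606842145, tolerance = 1e-9)
  p_pres <- packaged_params("present/model1/liver")
  expect_equal(flux_present(p_pres, 1e-6, 250e-9, 190, th),
               0.00408110012, tolerance = 1e-9)
  expect_equal(flux_present(p_pres, 50e-6, 250e-9, 190, th),
               4.635089094, tolerance = 1e-9)
})

test_that("detailed balance: flux vanishes at the Nernst concentration ratio", {
  set.seed(99)
  n_draw <- 250
  prev1 <- random_previous_params(n_draw %/% 2, "case1")
  prev2 <- random_previous_params(n_draw %/% 2, "case2")
  pres <- random_present_params(n_draw)
  for (p in c(prev1, prev2, pres)) {
    ca_e <- 10^runif(1, -7, -4)
    dpsi <- runif(1, -200, 220)
    phi <- reduced_potential(dpsi, th)
    ca_x <- ca_e * equilibrium_ratio(phi)
    J <- uniporter_flux(p, ca_e, ca_x, dpsi, th)
    # scale: the influx term the cancellation happens against
    if (inherits(p, "mcu_params_previous")) {
      scale <- rate_constants_previous(p, phi)$k_in *
        (ca_e / binding_constants_previous(p, phi)$K_e)^2
    } else {
      scale <- rate_constants_present(p, phi)$k_in *
        (ca_e / (p$K0 * exp(-2 * p$alpha * phi)))^2
    }
    expect_lt(abs(J), 1e-12 * scale)
  }
})

test_that("zero potential with equal concentrations gives exactly zero flux", {
  p1 <- packaged_params("previous/model1/case1")
  p2 <- packaged_params("present/model1/liver")
  for (ca in c(1e-7, 1e-6, 1e-5)) {
    expect_identical(flux_previous(p1, ca, ca, 0, th), 0)
    expect_identical(flux_present(p2, ca, ca, 0, th), 0)
  }
})

test_that("Ca2+ saturation reaches half its asymptote at the binding constant", {
  p <- packaged_params("present/model1/liver")
  half <- flux_present(p, p$K0, 250e-9, 190, th)
  asym <- rate_constants_present(p, reduced_potential(190, th))$k_in
  expect_equal(half / asym, 0.5, tolerance = 5e-3)
  # monotone increasing titration curve
  ca_grid <- exp(seq(log(1e-7), log(1e-3), length.out = 60))
  J <- flux_present(p, ca_grid, 250e-9, 190, th)
  expect_true(all(diff(J) > 0))
})

test_that("flux increases with membrane potential under uptake conditions", {
  dpsi <- seq(100, 210, length.out = 56)
  for (nm in c("previous/model1/case1", "present/model1/liver")) {
    p <- packaged_params(nm)
    J <- uniporter_flux(p, 10e-6, 250e-9, dpsi, th)
    expect_true(all(diff(J) > 0))
  }
})

test_that("flux factor E is smooth at zero for the generalized-GHK model only", {
  p_pres <- packaged_params("present/model1/liver")
  p_prev <- packaged_params("previous/model1/case1")
  expect_identical(e_factor(0, p_pres), 1)
  expect_identical(e_factor(0, p_prev), 1)
  # one-sided difference quotients at 0
  hs <- 10^-(3:6)
  right_pres <- (e_factor(hs, p_pres) - 1) / hs
  left_pres <- (1 - e_factor(-hs, p_pres)) / hs
  expect_equal(right_pres[4], left_pres[4], tolerance = 1e-3)
  # the present-model slope at 0 is 2 (from Phi e^{2 phi})
  expect_equal(right_pres[4], 2, tolerance = 1e-3)
  right_prev <- (e_factor(hs, p_prev) - 1) / hs
  left_prev <- (1 - e_factor(-hs, p_prev)) / hs
  expect_equal(right_prev[4], 4 * p_prev$beta_e, tolerance = 1e-3)
  expect_equal(left_prev[4], 4 * p_prev$beta_x, tolerance = 1e-3)
  expect_gt(abs(right_prev[4] - left_prev[4]), 1)  # the published kink
  # the generalized factor exceeds the Eyring-barrier one at low potential
  phi_low <- reduced_potential(seq(20, 120, length.out = 21), th)
  expect_true(all(e_factor(phi_low, p_pres) > e_factor(phi_low, p_prev)))
  expect_error(e_factor(1, structure(list(), class = "lm")), "params")
})

test_that("effective barrier parameters sum to one and are smooth at zero", {
  phi <- seq(-9, 9, length.out = 181)
  for (nH in c(0.7, 1, 2.65, 5)) {
    be <- beta_effective(phi, nH)
    expect_equal(be$beta_e + be$beta_x, rep(1, length(phi)), tolerance = 1e-14)
  }
  # nH = 1: consistent with the constant-field factor pushed through the
  # rate-constant comparison (beta_e = 1/2 + log(Phi_GHK) / (4 phi))
  ph <- c(-5, -1, 0.5, 3, 8)
  ghk <- oracle_ghk_rates(1, ph)
  expect_equal(beta_effective(ph, 1)$beta_e,
               log(ghk$k_in) / (4 * ph), tolerance = 1e-12)
  # central differences of beta_e converge at 0 (smoothness), slope -1/(6 nH)
  for (nH in c(1, 2.65)) {
    hs <- 10^-(2:5)
    cd <- (beta_effective(hs, nH)$beta_e - beta_effective(-hs, nH)$beta_e) /
      (2 * hs)
    expect_equal(cd[4], -1 / (6 * nH), tolerance = 1e-6)
    expect_equal(beta_effective(0, nH)$beta_e, 0.5)
  }
})
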