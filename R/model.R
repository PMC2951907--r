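#' Generalized translocation factor
#'
#' Even, dimensionless factor shared by the forward and reverse translocation
#' rate constants of the generalized-GHK formulation:
#' \deqn{\Phi(\tilde\varphi; nH) = \left[\frac{2\tilde\varphi/nH}
#'   {\sinh(2\tilde\varphi/nH)}\right]^{nH}.}
#' At `nH = 1` it is the standard constant-field (GHK) factor for the
#' charge-4 uniporter-2Ca2+ complex; as `nH` grows it flattens toward the
#' symmetric Eyring barrier limit. The removable singularity at
#' \eqn{\tilde\varphi = 0} is handled by a series branch, so
#' `phi_factor(0, nH) == 1` exactly.
#'
#' @param phi Reduced potential (dimensionless), vectorized.
#' @param nH Positive shape parameter.
#' @return \eqn{\Phi}, same length as `phi`.
#' @export
phi_factor <- function(phi, nH) {
  check_nH(nH)
  stopifnot(is.numeric(phi))
  exp(log_phi_factor(phi, nH))
}

check_nH <- function(nH) {
  if (!is.numeric(nH) || length(nH) != 1L || !is.finite(nH) || nH <= 0)
    stop("`nH` must be a positive finite scalar", call. = FALSE)
  invisible(nH)
}

log_phi_factor <- function(phi, nH) {
  nH * log_x_over_sinh(2 * phi / nH)
}

#' Voltage-dependent binding constants, Eyring-barrier formulation
#'
#' \eqn{K_e = K_{e,0} e^{-2\alpha_e\tilde\varphi}},
#' \eqn{K_x = K_{x,0} e^{+2\alpha_x\tilde\varphi}}: each bound Ca2+ (z = 2)
#' traverses the fraction \eqn{\alpha} of the potential profile on its way to
#' the binding site, favouring external binding and opposing internal binding
#' at positive potential.
#'
#' @param params An [mcu_params_previous()] object.
#' @param phi Reduced potential (dimensionless), vectorized.
#' @return List with components `K_e`, `K_x` (molar).
#' @export
binding_constants_previous <- function(params, phi) {
  stopifnot(inherits(params, "mcu_params_previous"), is.numeric(phi))
  list(K_e = params$K_e0 * exp(-2 * params$alpha_e * phi),
       K_x = params$K_x0 * exp(2 * params$alpha_x * phi))
}

#' Voltage-dependent rate constants, Eyring-barrier formulation
#'
#' \eqn{k_{in} = k_{in,0} e^{+4\beta_e\tilde\varphi}},
#' \eqn{k_{out} = k_{out,0} e^{-4\beta_x\tilde\varphi}}: the doubly occupied
#' complex (charge +4) crosses a single free-energy barrier located at
#' fractional positions \eqn{\beta_e} / \eqn{\beta_x} from the two faces.
#'
#' @inheritParams binding_constants_previous
#' @return List with components `k_in`, `k_out` (nmol/mg/s).
#' @export
rate_constants_previous <- function(params, phi) {
  stopifnot(inherits(params, "mcu_params_previous"), is.numeric(phi))
  list(k_in = params$k_in0 * exp(4 * params$beta_e * phi),
       k_out = params$k_out0 * exp(-4 * params$beta_x * phi))
}

#' Voltage-dependent rate constants, generalized-GHK formulation
#'
#' Both rate constants share the even factor \eqn{\Phi} and exponentials of
#' opposite sign over the translocation span \eqn{s = 1 - 2\alpha}:
#' \deqn{k_{in/out} = k_0\, \Phi(s\tilde\varphi; nH)\,
#'   e^{\pm 2 s \tilde\varphi},}
#' so that \eqn{k_{in}/k_{out} = e^{4 s\tilde\varphi}} and, together with the
#' binding-constant factors \eqn{e^{\mp 2\alpha\tilde\varphi}}, detailed
#' balance at the Nernst ratio \eqn{e^{2\tilde\varphi}} holds identically.
#' At the fitted `alpha = 0` this is the published form, and at `nH = 1` it
#' reduces to the standard constant-field expressions.
#'
#' @param params An [mcu_params_present()] object.
#' @param phi Reduced potential (dimensionless), vectorized.
#' @return List with components `k_in`, `k_out` (nmol/mg/s).
#' @export
rate_constants_present <- function(params, phi) {
  stopifnot(inherits(params, "mcu_params_present"), is.numeric(phi))
  s <- 1 - 2 * params$alpha
  lphi <- log_phi_factor(s * phi, params$nH)
  list(k_in = params$k0 * exp(lphi + 2 * s * phi),
       k_out = params$k0 * exp(lphi - 2 * s * phi))
}

#' Effective barrier-displacement parameters of the generalized-GHK model
#'
#' Equating the generalized-GHK rate constants with the Eyring-barrier forms
#' gives analytic, potential-dependent barrier parameters
#' \deqn{\beta_e(\tilde\varphi) = \tfrac12 +
#'   \frac{\ln\Phi(\tilde\varphi; nH)}{4\tilde\varphi}, \qquad
#'   \beta_x(\tilde\varphi) = \tfrac12 -
#'   \frac{\ln\Phi(\tilde\varphi; nH)}{4\tilde\varphi},}
#' which satisfy \eqn{\beta_e + \beta_x = 1} for every potential (the
#' thermodynamic constraint at \eqn{\alpha = 0}) and are smooth through
#' \eqn{\tilde\varphi = 0} (series branch:
#' \eqn{\beta_e = 1/2 - \tilde\varphi/(6 nH) + \tilde\varphi^3/(45 nH^3) -
#' \dots}).
#'
#' @inheritParams phi_factor
#' @return List with components `beta_e`, `beta_x` (dimensionless).
#' @export
beta_effective <- function(phi, nH) {
  check_nH(nH)
  stopifnot(is.numeric(phi))
  dev <- numeric(length(phi))
  small <- abs(phi) < 1e-4
  dev[small] <- -phi[small] / (6 * nH) + phi[small]^3 / (45 * nH^3)
  dev[!small] <- log_phi_factor(phi[!small], nH) / (4 * phi[!small])
  list(beta_e = 0.5 + dev, beta_x = 0.5 - dev)
}

#' Voltage-dependent flux factor E
#'
#' The scalar potential-dependent multiplier of the influx term, normalized
#' to 1 at zero potential: `k_in(phi) / k_in(0)`. For the generalized-GHK
#' formulation this is \eqn{\Phi(s\tilde\varphi; nH) e^{2 s\tilde\varphi}},
#' smooth and differentiable everywhere. For the Eyring-barrier formulation
#' the published constant parameters apply per transport direction —
#' \eqn{e^{4\beta_e\tilde\varphi}} for \eqn{\tilde\varphi \ge 0} and
#' \eqn{e^{4\beta_x\tilde\varphi}} for \eqn{\tilde\varphi < 0} (the barrier
#' seen from the other face) — which makes the factor continuous but
#' non-differentiable at 0; it is reproduced here as published, for
#' diagnostic comparison only.
#'
#' @param phi Reduced potential (dimensionless), vectorized.
#' @param params An [mcu_params_present()] or [mcu_params_previous()] object
#'   (the formulation is taken from the class).
#' @return Dimensionless factor, same length as `phi`.
#' @export
e_factor <- function(phi, params) {
  stopifnot(is.numeric(phi))
  if (inherits(params, "mcu_params_present")) {
    s <- 1 - 2 * params$alpha
    exp(log_phi_factor(s * phi, params$nH) + 2 * s * phi)
  } else if (inherits(params, "mcu_params_previous")) {
    beta <- ifelse(phi >= 0, params$beta_e, params$beta_x)
    exp(4 * beta * phi)
  } else {
    stop("`params` must be an mcu_params_present or mcu_params_previous object",
         call. = FALSE)
  }
}

#' Flux denominator (carrier saturation)
#'
#' Model 1 (fully cooperative binding of the two Ca2+) keeps only the empty
#' and doubly-occupied carrier states:
#' \eqn{D_1 = 1 + (c_e/K_e)^2 + (c_x/K_x)^2}. Model 2 (partial
#' cooperativity) adds the singly-occupied states:
#' \eqn{D_2 = D_1 + c_e/K_e + c_x/K_x}.
#'
#' @param ca_e,ca_x External / matrix free Ca2+ (molar), vectorized.
#' @param K_e,K_x Binding constants (molar).
#' @param variant `"model1"` or `"model2"`.
#' @return Dimensionless denominator, `>= 1`.
#' @export
flux_denominator <- function(ca_e, ca_x, K_e, K_x,
                             variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  if (any(K_e <= 0) || any(K_x <= 0))
    stop("binding constants must be positive", call. = FALSE)
  re <- ca_e / K_e
  rx <- ca_x / K_x
  D <- 1 + re^2 + rx^2
  if (variant == "model2") D <- D + re + rx
  D
}

check_conditions <- function(ca_e, ca_x, dpsi) {
  if (!is.numeric(ca_e) || any(!is.finite(ca_e)) || any(ca_e <= 0))
    stop("`ca_e` must be positive and finite (molar)", call. = FALSE)
  if (!is.numeric(ca_x) || any(!is.finite(ca_x)) || any(ca_x <= 0))
    stop("`ca_x` must be positive and finite (molar)", call. = FALSE)
  if (!is.numeric(dpsi) || any(!is.finite(dpsi)))
    stop("`dpsi` must be finite (mV)", call. = FALSE)
  invisible(NULL)
}

#' Uniporter Ca2+ flux
#'
#' Net Ca2+ flux through the uniporter (nmol/mg/s; positive = influx into
#' the matrix) at the given concentrations and membrane potential:
#' \deqn{J = \frac{k_{in} (c_e/K_e)^2 - k_{out} (c_x/K_x)^2}{D},}
#' with the voltage-dependent rate and binding constants of the formulation
#' selected by the class of `params` and the denominator of its variant.
#' All arguments are vectorized and recycled.
#'
#' @param params An [mcu_params_present()] or [mcu_params_previous()] object.
#' @param ca_e External (extra-matrix) free Ca2+, molar.
#' @param ca_x Matrix free Ca2+, molar (the fitting convention of the source
#'   data is 250 nM).
#' @param dpsi Membrane potential in mV (\eqn{\Psi_e - \Psi_x}; about
#'   +190 mV in energized, state-2 mitochondria).
#' @param thermo A [thermo_context()].
#' @return Numeric vector of fluxes, nmol/mg/s.
#' @examples
#' p <- packaged_params("present/model1/liver")
#' uniporter_flux(p, ca_e = 50e-6, ca_x = 250e-9, dpsi = 190)
#' @export
uniporter_flux <- function(params, ca_e, ca_x, dpsi,
                           thermo = thermo_context()) {
  UseMethod("uniporter_flux")
}

#' @export
uniporter_flux.mcu_params_previous <- function(params, ca_e, ca_x, dpsi,
                                               thermo = thermo_context()) {
  check_conditions(ca_e, ca_x, dpsi)
  phi <- reduced_potential(dpsi, thermo)
  bc <- binding_constants_previous(params, phi)
  rc <- rate_constants_previous(params, phi)
  re <- ca_e / bc$K_e
  rx <- ca_x / bc$K_x
  D <- flux_denominator(ca_e, ca_x, bc$K_e, bc$K_x, params$variant)
  (rc$k_in * re^2 - rc$k_out * rx^2) / D
}

#' @export
uniporter_flux.mcu_params_present <- function(params, ca_e, ca_x, dpsi,
                                              thermo = thermo_context()) {
  check_conditions(ca_e, ca_x, dpsi)
  phi <- reduced_potential(dpsi, thermo)
  K_e <- params$K0 * exp(-2 * params$alpha * phi)
  K_x <- params$K0 * exp(2 * params$alpha * phi)
  rc <- rate_constants_present(params, phi)
  re <- ca_e / K_e
  rx <- ca_x / K_x
  D <- flux_denominator(ca_e, ca_x, K_e, K_x, params$variant)
  (rc$k_in * re^2 - rc$k_out * rx^2) / D
}

#' @rdname uniporter_flux
#' @export
flux_previous <- function(params, ca_e, ca_x, dpsi, thermo = thermo_context()) {
  stopifnot(inherits(params, "mcu_params_previous"))
  uniporter_flux.mcu_params_previous(params, ca_e, ca_x, dpsi, thermo)
}

#' @rdname uniporter_flux
#' @export
flux_present <- function(params, ca_e, ca_x, dpsi, thermo = thermo_context()) {
  stopifnot(inherits(params, "mcu_params_present"))
  uniporter_flux.mcu_params_present(params, ca_e, ca_x, dpsi, thermo)
}
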