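#' Parameter set for the Eyring-barrier uniporter formulation
#'
#' The carrier binds two Ca2+ ions cooperatively and translocates the
#' doubly-occupied complex across the inner membrane over a single
#' free-energy barrier. Membrane-potential dependence is carried by four
#' dimensionless displacement parameters: `alpha_e`/`alpha_x` locate the
#' external/internal binding sites within the membrane and `beta_e`/`beta_x`
#' locate the translocation barrier. Thermodynamic consistency requires
#' `alpha_e + alpha_x + beta_e + beta_x = 1` and
#' `k_in0 * K_x0^2 = k_out0 * K_e0^2` (see [constraint_residuals()]).
#'
#' @param k_in0,k_out0 Forward/reverse translocation rate constants at
#'   `dpsi = 0`, nmol/mg/s. Total carrier density is absorbed into these.
#' @param K_e0,K_x0 External/internal Ca2+ dissociation constants at
#'   `dpsi = 0`, molar.
#' @param alpha_e,alpha_x Binding-site displacement parameters (dimensionless,
#'   `>= 0` in the constrained mode).
#' @param beta_e,beta_x Barrier displacement parameters (dimensionless).
#'   `beta_x` defaults to the value imposed by the thermodynamic constraint.
#' @param variant `"model1"` (fully cooperative binding; quadratic saturation
#'   terms only in the flux denominator) or `"model2"` (partial cooperativity;
#'   additional linear terms).
#' @param case `"case1"` (equal external/internal constants,
#'   `K_e0 = K_x0` and `k_in0 = k_out0`) or `"case2"` (distinct constants).
#'
#' @return An object of class `mcu_params_previous`.
#' @seealso [mcu_params_present()], [uniporter_flux()], [case2_family()]
#' @export
mcu_params_previous <- function(k_in0, k_out0 = k_in0,
                                K_e0, K_x0 = K_e0,
                                alpha_e = 0, alpha_x = alpha_e,
                                beta_e,
                                beta_x = 1 - alpha_e - alpha_x - beta_e,
                                variant = c("model1", "model2"),
                                case = c("case1", "case2")) {
  variant <- match.arg(variant)
  case <- match.arg(case)
  p <- structure(
    list(k_in0 = k_in0, k_out0 = k_out0, K_e0 = K_e0, K_x0 = K_x0,
         alpha_e = alpha_e, alpha_x = alpha_x,
         beta_e = beta_e, beta_x = beta_x,
         variant = variant, case = case),
    class = c("mcu_params_previous", "mcu_params")
  )
  validate_params_previous(p)
  p
}

validate_params_previous <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("k_in0", "k_out0", "K_e0", "K_x0"))
    if (!num1(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("`%s` must be a positive finite scalar", f), call. = FALSE)
  for (f in c("alpha_e", "alpha_x", "beta_e", "beta_x"))
    if (!num1(p[[f]]))
      stop(sprintf("`%s` must be a finite scalar", f), call. = FALSE)
  if (p$case == "case1") {
    if (!isTRUE(all.equal(p$K_e0, p$K_x0)) ||
        !isTRUE(all.equal(p$k_in0, p$k_out0)))
      stop("case1 requires K_e0 = K_x0 and k_in0 = k_out0", call. = FALSE)
  }
  invisible(p)
}

#' Parameter set for the generalized-GHK uniporter formulation
#'
#' Reformulation of the membrane-potential dependence of Ca2+ translocation:
#' the two rate constants share a common even translocation factor
#' \eqn{\Phi(\tilde\varphi; nH)} (see [phi_factor()]) multiplied by
#' exponentials of opposite sign, so detailed balance is built in and the
#' barrier parameters become smooth analytic functions of potential
#' ([beta_effective()]). Binding constants are equal on the two faces
#' (`K_e0 = K_x0 = K0`), as supported by the Case-1/Case-2 identifiability
#' analysis of the Eyring formulation.
#'
#' @param k0 Common translocation rate constant at `dpsi = 0`, nmol/mg/s.
#' @param K0 Common Ca2+ dissociation constant, molar.
#' @param alpha Binding-site displacement (dimensionless, `>= 0`; fitted
#'   value is 0).
#' @param nH Shape parameter of the translocation factor (`nH = 1` recovers
#'   the standard constant-field GHK factor; `nH -> Inf` approaches a
#'   symmetric Eyring barrier).
#' @param variant `"model1"` or `"model2"` (flux-denominator structure).
#'
#' @return An object of class `mcu_params_present`.
#' @export
mcu_params_present <- function(k0, K0, alpha = 0, nH,
                               variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(k0) || k0 <= 0) stop("`k0` must be positive", call. = FALSE)
  if (!num1(K0) || K0 <= 0) stop("`K0` must be positive", call. = FALSE)
  if (!num1(nH) || nH <= 0) stop("`nH` must be positive", call. = FALSE)
  if (!num1(alpha) || alpha < 0 || alpha >= 0.5)
    stop("`alpha` must lie in [0, 0.5)", call. = FALSE)
  structure(
    list(k0 = k0, K0 = K0, alpha = alpha, nH = nH, variant = variant),
    class = c("mcu_params_present", "mcu_params")
  )
}

#' @export
print.mcu_params_previous <- function(x, ...) {
  cat(sprintf("<mcu_params_previous> %s / %s (Eyring-barrier formulation)\n",
              x$variant, x$case))
  cat(sprintf("  k_in0 = %g, k_out0 = %g nmol/mg/s\n", x$k_in0, x$k_out0))
  cat(sprintf("  K_e0 = %g, K_x0 = %g M\n", x$K_e0, x$K_x0))
  cat(sprintf("  alpha_e = %g, alpha_x = %g, beta_e = %g, beta_x = %g\n",
              x$alpha_e, x$alpha_x, x$beta_e, x$beta_x))
  invisible(x)
}

#' @export
print.mcu_params_present <- function(x, ...) {
  cat(sprintf("<mcu_params_present> %s (generalized-GHK formulation)\n",
              x$variant))
  cat(sprintf("  k0 = %g nmol/mg/s, K0 = %g M, alpha = %g, nH = %g\n",
              x$k0, x$K0, x$alpha, x$nH))
  invisible(x)
}

#' Kinetic and thermodynamic constraint residuals
#'
#' The Eyring-barrier parameter set must satisfy two exact relations for the
#' flux to vanish at the Nernst-equilibrium concentration ratio:
#' the kinetic constraint \eqn{k_{in,0} K_{x,0}^2 = k_{out,0} K_{e,0}^2}
#' (zero-potential cycle balance) and the thermodynamic constraint
#' \eqn{\alpha_e + \alpha_x + \beta_e + \beta_x = 1} (the displacement
#' parameters tile the whole membrane). Residuals are reported as
#' dimensionless magnitudes: the kinetic residual relative
#' (`|k_in0 K_x0^2 / (k_out0 K_e0^2) - 1|`), the thermodynamic residual as
#' the absolute deviation of the displacement sum from 1.
#'
#' @param params An [mcu_params_previous()] object.
#' @param tol Tolerance below which the set is declared consistent.
#' @return A list of class `mcu_constraint_report` with elements
#'   `kinetic_residual`, `thermodynamic_residual`, `satisfied`, `tol`.
#' @export
constraint_residuals <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "mcu_params_previous"))
  kin <- abs(params$k_in0 * params$K_x0^2 /
               (params$k_out0 * params$K_e0^2) - 1)
  thermo <- abs(params$alpha_e + params$alpha_x +
                  params$beta_e + params$beta_x - 1)
  structure(
    list(kinetic_residual = kin,
         thermodynamic_residual = thermo,
         satisfied = (kin <= tol) && (thermo <= tol),
         tol = tol),
    class = "mcu_constraint_report"
  )
}

#' @export
print.mcu_constraint_report <- function(x, ...) {
  cat(sprintf("<constraint report> kinetic = %.3g, thermodynamic = %.3g (%s at tol %g)\n",
              x$kinetic_residual, x$thermodynamic_residual,
              if (x$satisfied) "satisfied" else "VIOLATED", x$tol))
  invisible(x)
}

#' Build a constrained Eyring-barrier parameter set from a free vector
#'
#' Maps the free-parameter vector of each identifiability case to a full
#' parameter set with the kinetic and thermodynamic constraints imposed by
#' construction. Case 1 has 4 free parameters `(k0, K0, alpha, beta_e)`
#' (equal constants on both faces). Case 2 has 5:
#' `(k_in0, K_e0, K_x0, alpha, beta_e)`, with `k_out0` tied through the
#' kinetic constraint. In both cases
#' `beta_x = 1 - 2*alpha - beta_e`.
#'
#' @param free Named or unnamed numeric vector (length 4 for case 1, 5 for
#'   case 2, in the order above).
#' @param case `"case1"` or `"case2"`.
#' @param variant `"model1"` or `"model2"`.
#' @return An [mcu_params_previous()] object.
#' @seealso [free_vector()] for the inverse mapping.
#' @export
apply_case <- function(free, case = c("case1", "case2"),
                       variant = c("model1", "model2")) {
  case <- match.arg(case)
  variant <- match.arg(variant)
  free <- as.numeric(free)
  if (case == "case1") {
    if (length(free) != 4L)
      stop("case1 free vector must have 4 elements (k0, K0, alpha, beta_e)",
           call. = FALSE)
    k0 <- free[1]; K0 <- free[2]; a <- free[3]; be <- free[4]
    mcu_params_previous(k_in0 = k0, k_out0 = k0, K_e0 = K0, K_x0 = K0,
                        alpha_e = a, alpha_x = a,
                        beta_e = be, beta_x = 1 - 2 * a - be,
                        variant = variant, case = "case1")
  } else {
    if (length(free) != 5L)
      stop("case2 free vector must have 5 elements (k_in0, K_e0, K_x0, alpha, beta_e)",
           call. = FALSE)
    k_in0 <- free[1]; K_e0 <- free[2]; K_x0 <- free[3]
    a <- free[4]; be <- free[5]
    mcu_params_previous(k_in0 = k_in0,
                        k_out0 = k_in0 * (K_x0 / K_e0)^2,
                        K_e0 = K_e0, K_x0 = K_x0,
                        alpha_e = a, alpha_x = a,
                        beta_e = be, beta_x = 1 - 2 * a - be,
                        variant = variant, case = "case2")
  }
}

#' Free-parameter vector of a constrained Eyring-barrier set
#'
#' Inverse of [apply_case()]: extracts the case's free parameters, so that
#' `apply_case(free_vector(p), p$case, p$variant)` reproduces `p` for any
#' set satisfying the constraints with `alpha_e = alpha_x`.
#'
#' @param params An [mcu_params_previous()] object.
#' @return Named numeric vector (length 4 or 5).
#' @export
free_vector <- function(params) {
  stopifnot(inherits(params, "mcu_params_previous"))
  if (params$case == "case1") {
    c(k0 = params$k_in0, K0 = params$K_e0,
      alpha = params$alpha_e, beta_e = params$beta_e)
  } else {
    c(k_in0 = params$k_in0, K_e0 = params$K_e0, K_x0 = params$K_x0,
      alpha = params$alpha_e, beta_e = params$beta_e)
  }
}

#' Case-2 scaling (non-identifiability) family
#'
#' For a Case-2 set with `alpha = 0`, scaling the internal constants as
#' `K_x0 -> m * K_x0` and `k_out0 -> m^2 * k_out0` preserves both
#' constraints and leaves the efflux numerator term exactly invariant; under
#' uptake-protocol conditions (matrix Ca2+ far below `K_x0`) the total flux
#' is essentially unchanged for any `m > 0`. The family is a diagnostic of
#' why Case 2 is not an estimable, distinct hypothesis.
#'
#' @param params A Case-2 [mcu_params_previous()] object.
#' @param m Positive scaling factor.
#' @return The scaled parameter set.
#' @export
case2_family <- function(params, m) {
  stopifnot(inherits(params, "mcu_params_previous"))
  if (params$case != "case2")
    stop("the scaling family is defined for case2 parameter sets", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("`m` must be a positive scalar", call. = FALSE)
  mcu_params_previous(k_in0 = params$k_in0, k_out0 = params$k_out0 * m^2,
                      K_e0 = params$K_e0, K_x0 = params$K_x0 * m,
                      alpha_e = params$alpha_e, alpha_x = params$alpha_x,
                      beta_e = params$beta_e, beta_x = params$beta_x,
                      variant = params$variant, case = "case2")
}
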