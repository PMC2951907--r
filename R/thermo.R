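#' Thermodynamic context for membrane-potential calculations
#'
#' Bundles the physical constants and temperature used to convert a membrane
#' potential (mV) into the dimensionless reduced potential
#' \eqn{\tilde\varphi = F \Delta\Psi / (R T)}.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param faraday Faraday constant in C/mol.
#' @param gas_constant Molar gas constant in J/(mol K).
#'
#' @return An object of class `thermo_context`.
#' @examples
#' th <- thermo_context()
#' reduced_potential(190, th)
#' @export
thermo_context <- function(temperature = 298.15,
                           faraday = 96485,
                           gas_constant = 8.314) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(faraday), faraday > 0,
            is.numeric(gas_constant), gas_constant > 0)
  structure(
    list(temperature = temperature,
         faraday = faraday,
         gas_constant = gas_constant),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %.2f K, F = %g C/mol, R = %g J/(mol K)\n",
              x$temperature, x$faraday, x$gas_constant))
  cat(sprintf("  RT/F = %.4f mV\n",
              1000 * x$gas_constant * x$temperature / x$faraday))
  invisible(x)
}

#' Reduced membrane potential
#'
#' Converts a membrane potential \eqn{\Delta\Psi} (in mV, defined as
#' \eqn{\Psi_e - \Psi_x}, outside minus matrix) into the dimensionless
#' reduced potential \eqn{\tilde\varphi = F \Delta\Psi / (R T)}.
#'
#' @param dpsi Membrane potential in mV; may be any finite value (vectorized).
#' @param thermo A [thermo_context()].
#'
#' @return Dimensionless reduced potential, same length as `dpsi`.
#' @export
reduced_potential <- function(dpsi, thermo = thermo_context()) {
  stopifnot(inherits(thermo, "thermo_context"), is.numeric(dpsi))
  if (length(dpsi) && any(!is.finite(dpsi)))
    stop("`dpsi` must be finite (mV)", call. = FALSE)
  thermo$faraday * (dpsi / 1000) / (thermo$gas_constant * thermo$temperature)
}

#' Equilibrium matrix/external Ca2+ concentration ratio
#'
#' Nernst-equilibrium ratio \eqn{[\mathrm{Ca}^{2+}]_x/[\mathrm{Ca}^{2+}]_e =
#' \exp(2\tilde\varphi)} for the divalent Ca2+ ion. Net uniporter flux is
#' exactly zero when the concentrations sit at this ratio (detailed balance).
#'
#' @param phi Reduced potential (dimensionless), vectorized.
#' @return `exp(2 * phi)`.
#' @export
equilibrium_ratio <- function(phi) {
  stopifnot(is.numeric(phi))
  if (length(phi) && any(!is.finite(phi)))
    stop("`phi` must be finite", call. = FALSE)
  exp(2 * phi)
}

# log(x / sinh(x)), computed stably; even in x, 0 at x = 0.
# Series branch below |x| < 1e-4 keeps the removable singularity smooth
# (switch error < 1e-12 relative): log(x/sinh x) = -x^2/6 + x^4/180 - ...
log_x_over_sinh <- function(x) {
  ax <- abs(x)
  out <- numeric(length(ax))
  small <- ax < 1e-4
  big <- ax > 30            # avoid overflow in sinh for very large arguments
  mid <- !small & !big
  out[small] <- -ax[small]^2 / 6 + ax[small]^4 / 180
  out[mid] <- log(ax[mid]) - log(sinh(ax[mid]))
  # log(sinh x) = x - log 2 + log1p(-exp(-2x)) for large x
  out[big] <- log(ax[big]) - (ax[big] - log(2) + log1p(-exp(-2 * ax[big])))
  out
}
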