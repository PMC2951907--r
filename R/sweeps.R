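#' Matrix-Ca2+ robustness envelope
#'
#' Evaluates the flux over a protocol's condition grid while sweeping matrix
#' free Ca2+ across a physiological range (default 100-500 nM, 17 log-spaced
#' points) and reports, per condition, the minimum, maximum and reference
#' flux (reference at the protocol's own `ca_x`, 250 nM by default). The
#' scalar robustness metric is the worst-case relative spread
#' `max((max - min) / reference)` over the conditions: a model whose
#' predictions are insensitive to matrix Ca2+ variation has a metric close
#' to zero under uptake conditions.
#'
#' @param params A parameter object (either formulation; [packaged_params()]
#'   results use the protocol-matched rate constant).
#' @param spec A [make_protocol()] specification or a protocol id string.
#' @param ca_x_range Length-2 range of matrix Ca2+ (molar).
#' @param n_ca_x Number of log-spaced matrix Ca2+ points.
#' @param thermo A [thermo_context()].
#' @return An object of class `mcu_sweep`: a data frame with the protocol
#'   conditions plus `flux_min`, `flux_max`, `flux_ref`, and attributes
#'   `metric` (worst-case relative spread) and `metadata`.
#' @export
matrix_ca_envelope <- function(params, spec,
                               ca_x_range = c(100e-9, 500e-9),
                               n_ca_x = 17L,
                               thermo = thermo_context()) {
  if (is.character(spec)) spec <- make_protocol(spec)
  stopifnot(inherits(spec, "protocol_spec"), inherits(params, "mcu_params"),
            length(ca_x_range) == 2L, all(ca_x_range > 0),
            ca_x_range[1] < ca_x_range[2], n_ca_x >= 2L)
  dataset_key <- sub("_titration$", "", spec$protocol_id)
  p <- params_for_dataset(params, dataset_key)
  cond <- protocol_conditions(spec)
  ca_x_grid <- exp(seq(log(ca_x_range[1]), log(ca_x_range[2]),
                       length.out = n_ca_x))
  fl <- vapply(ca_x_grid, function(cx)
    uniporter_flux(p, cond$ca_e, cx, cond$dpsi, thermo),
    numeric(nrow(cond)))
  if (nrow(cond) == 1L) fl <- matrix(fl, nrow = 1L)
  ref <- uniporter_flux(p, cond$ca_e, cond$ca_x, cond$dpsi, thermo)
  out <- cond
  out$flux_min <- apply(fl, 1L, min)
  out$flux_max <- apply(fl, 1L, max)
  out$flux_ref <- ref
  metric <- max((out$flux_max - out$flux_min) / abs(ref))
  structure(out,
            class = c("mcu_sweep", "data.frame"),
            sweep_type = "matrix_ca_envelope",
            metric = metric,
            metadata = list(protocol = spec, params = p,
                            ca_x_range = ca_x_range, n_ca_x = n_ca_x))
}

#' Robustness metric of an envelope sweep
#'
#' @param sweep An `mcu_sweep` from [matrix_ca_envelope()].
#' @return The worst-case relative flux spread across the matrix-Ca2+ range.
#' @export
envelope_metric <- function(sweep) {
  stopifnot(inherits(sweep, "mcu_sweep"))
  m <- attr(sweep, "metric")
  if (is.null(m)) stop("sweep has no envelope metric", call. = FALSE)
  m
}

#' Flux surface over external Ca2+ and membrane potential
#'
#' Pointwise flux evaluations (no interpolation) over the tensor grid
#' `(ca_e_grid, dpsi_grid)` at fixed matrix Ca2+ — the curve families shown
#' as uptake-vs-Ca2+ lines for a range of potentials and uptake-vs-potential
#' lines for a range of Ca2+ levels.
#'
#' @param params A parameter object (either formulation).
#' @param ca_e_grid External Ca2+ grid, molar.
#' @param dpsi_grid Membrane potential grid, mV.
#' @param ca_x Matrix Ca2+, molar (default 250 nM).
#' @param thermo A [thermo_context()].
#' @return An `mcu_sweep` data frame with columns `ca_e`, `dpsi`, `ca_x`,
#'   `flux`, one row per grid point.
#' @export
dpsi_family <- function(params, ca_e_grid, dpsi_grid, ca_x = 250e-9,
                        thermo = thermo_context()) {
  stopifnot(inherits(params, "mcu_params"),
            is.numeric(ca_e_grid), all(ca_e_grid > 0),
            is.numeric(dpsi_grid), all(is.finite(dpsi_grid)),
            is.numeric(ca_x), length(ca_x) == 1L, ca_x > 0)
  g <- expand.grid(ca_e = ca_e_grid, dpsi = dpsi_grid, KEEP.OUT.ATTRS = FALSE)
  g$ca_x <- ca_x
  g$flux <- uniporter_flux(params, g$ca_e, g$ca_x, g$dpsi, thermo)
  structure(g,
            class = c("mcu_sweep", "data.frame"),
            sweep_type = "dpsi_family",
            metadata = list(params = params, ca_x = ca_x))
}

#' Barrier-parameter and flux-factor curves versus membrane potential
#'
#' Tabulates, over a potential grid spanning zero, the analytic
#' potential-dependent barrier parameters of the generalized-GHK model
#' ([beta_effective()]), the corresponding constant parameters of the
#' Eyring-barrier model (which swap values across 0, see [e_factor()]), and
#' the two normalized flux factors E. The generalized-GHK curves are smooth
#' through 0; the Eyring-barrier factor has a kink there — the diagnostic
#' contrast between the two formulations.
#'
#' @param nH Shape parameter of the generalized-GHK model.
#' @param prev_params An [mcu_params_previous()] object supplying the
#'   constant barrier parameters (default: the packaged re-estimated set).
#' @param dpsi_grid Membrane potential grid in mV; must include negative and
#'   positive values and 0.
#' @param thermo A [thermo_context()].
#' @return An `mcu_sweep` data frame with columns `dpsi`, `phi`,
#'   `beta_e_present`, `beta_x_present`, `beta_e_previous`,
#'   `beta_x_previous`, `E_present`, `E_previous`.
#' @export
beta_and_e_curves <- function(nH = 2.65,
                              prev_params = packaged_params("previous/model1/case1"),
                              dpsi_grid = seq(-200, 200, length.out = 201),
                              thermo = thermo_context()) {
  check_nH(nH)
  stopifnot(inherits(prev_params, "mcu_params_previous"))
  if (min(dpsi_grid) >= 0 || max(dpsi_grid) <= 0 || !any(dpsi_grid == 0))
    stop("`dpsi_grid` must span negative and positive potentials and include 0",
         call. = FALSE)
  phi <- reduced_potential(dpsi_grid, thermo)
  be <- beta_effective(phi, nH)
  pres <- mcu_params_present(k0 = 1, K0 = 1e-6, alpha = 0, nH = nH,
                             variant = prev_params$variant)
  out <- data.frame(
    dpsi = dpsi_grid, phi = phi,
    beta_e_present = be$beta_e, beta_x_present = be$beta_x,
    beta_e_previous = ifelse(dpsi_grid >= 0, prev_params$beta_e,
                             prev_params$beta_x),
    beta_x_previous = ifelse(dpsi_grid >= 0, prev_params$beta_x,
                             prev_params$beta_e),
    E_present = e_factor(phi, pres),
    E_previous = e_factor(phi, prev_params))
  structure(out,
            class = c("mcu_sweep", "data.frame"),
            sweep_type = "beta_and_e_curves",
            metadata = list(nH = nH, prev_params = prev_params))
}

#' @export
print.mcu_sweep <- function(x, ...) {
  cat(sprintf("<mcu_sweep> %s, %d rows\n",
              attr(x, "sweep_type") %||% "sweep", nrow(x)))
  if (!is.null(attr(x, "metric")))
    cat(sprintf("  robustness metric (max relative spread): %.3g\n",
                attr(x, "metric")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a sweep as tidy CSV
#'
#' One row per grid point, with a provenance header; suitable for external
#' plotting. Repeated writes of the same sweep are byte-identical.
#'
#' @param sweep An `mcu_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "mcu_sweep"))
  df <- as.data.frame(sweep)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  hdr <- c(sprintf("# mcuflux %s sweep: %s",
                   as.character(utils::packageVersion("mcuflux")),
                   attr(sweep, "sweep_type") %||% "sweep"),
           sprintf("# config_hash: %s", config_hash(attr(sweep, "metadata"))),
           if (!is.null(attr(sweep, "metric")))
             sprintf("# envelope_metric: %s", fmt_num(attr(sweep, "metric"))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(df), collapse = ",")), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}
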