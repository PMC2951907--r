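#' Experimental protocol specification
#'
#' Describes one of the three classical initial-uptake-rate protocols the
#' estimation pipeline is built around:
#' \itemize{
#'   \item `heart_ca_titration` — Ca2+ titration in rat heart mitochondria
#'     at fixed potential (default 190 mV, state-2 respiration);
#'   \item `liver_ca_titration` — the same protocol in rat liver
#'     mitochondria;
#'   \item `liver_dpsi_titration` — membrane-potential titration in rat
#'     liver mitochondria at several fixed external Ca2+ levels
#'     (default 0.5 / 1.0 / 1.5 uM).
#' }
#' Defaults bracket the published measurement ranges (Ca2+ titrations:
#' 20 log-spaced points over 1-150 uM; potential titration: 15 points over
#' 60-190 mV per Ca2+ level; matrix Ca2+ fixed at 250 nM, the fitting
#' convention of the source data). Grids are user-overridable; the original
#' measurement grids are not published.
#'
#' @param protocol_id One of `"heart_ca_titration"`, `"liver_ca_titration"`,
#'   `"liver_dpsi_titration"`.
#' @param ca_e_grid Strictly increasing external Ca2+ grid, molar
#'   (titration protocols).
#' @param dpsi_grid Strictly increasing potential grid, mV (potential
#'   protocol).
#' @param dpsi_fixed Fixed potential, mV (titration protocols).
#' @param ca_e_levels External Ca2+ levels, molar (potential protocol).
#' @param ca_x Matrix free Ca2+, molar.
#' @return An object of class `protocol_spec`.
#' @export
make_protocol <- function(protocol_id = c("heart_ca_titration",
                                          "liver_ca_titration",
                                          "liver_dpsi_titration"),
                          ca_e_grid = NULL, dpsi_grid = NULL,
                          dpsi_fixed = 190,
                          ca_e_levels = c(0.5, 1.0, 1.5) * 1e-6,
                          ca_x = 250e-9) {
  protocol_id <- match.arg(protocol_id)
  is_dpsi <- protocol_id == "liver_dpsi_titration"
  if (is.null(ca_e_grid) && !is_dpsi)
    ca_e_grid <- exp(seq(log(1e-6), log(150e-6), length.out = 20))
  if (is.null(dpsi_grid) && is_dpsi)
    dpsi_grid <- seq(60, 190, length.out = 15)
  chk_grid <- function(g, nm, positive = TRUE) {
    if (is.null(g)) return(invisible(NULL))
    if (!is.numeric(g) || any(!is.finite(g)) || (positive && any(g <= 0)) ||
        is.unsorted(g, strictly = TRUE))
      stop(sprintf("`%s` must be a strictly increasing %sgrid", nm,
                   if (positive) "positive " else ""), call. = FALSE)
  }
  chk_grid(ca_e_grid, "ca_e_grid")
  chk_grid(dpsi_grid, "dpsi_grid", positive = FALSE)
  if (is_dpsi) chk_grid(sort(unique(ca_e_levels)), "ca_e_levels")
  if (is_dpsi && length(ca_e_levels) < 1L)
    stop("the potential-titration protocol needs at least one ca_e level",
         call. = FALSE)
  if (!is.numeric(ca_x) || length(ca_x) != 1L || ca_x <= 0)
    stop("`ca_x` must be a positive scalar (molar)", call. = FALSE)
  structure(
    list(protocol_id = protocol_id,
         ca_e_grid = ca_e_grid, dpsi_grid = dpsi_grid,
         dpsi_fixed = dpsi_fixed, ca_e_levels = ca_e_levels,
         ca_x = ca_x),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s\n", x$protocol_id))
  if (x$protocol_id == "liver_dpsi_titration") {
    cat(sprintf("  dpsi: %d points, %.0f-%.0f mV; ca_e levels: %s uM\n",
                length(x$dpsi_grid), min(x$dpsi_grid), max(x$dpsi_grid),
                paste(signif(x$ca_e_levels * 1e6, 3), collapse = ", ")))
  } else {
    cat(sprintf("  ca_e: %d points, %.3g-%.3g uM at dpsi = %.0f mV\n",
                length(x$ca_e_grid), min(x$ca_e_grid) * 1e6,
                max(x$ca_e_grid) * 1e6, x$dpsi_fixed))
  }
  cat(sprintf("  ca_x = %.0f nM\n", x$ca_x * 1e9))
  invisible(x)
}

#' Condition grid of a protocol
#'
#' @param spec A [make_protocol()] specification.
#' @return A data frame with columns `ca_e`, `ca_x` (molar), `dpsi` (mV),
#'   one row per measured condition.
#' @export
protocol_conditions <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (spec$protocol_id == "liver_dpsi_titration") {
    g <- expand.grid(dpsi = spec$dpsi_grid, ca_e = spec$ca_e_levels,
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(ca_e = g$ca_e, ca_x = spec$ca_x, dpsi = g$dpsi)
  } else {
    data.frame(ca_e = spec$ca_e_grid, ca_x = spec$ca_x,
               dpsi = spec$dpsi_fixed)
  }
}

# run code with a private, seeded RNG stream, restoring global state after
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic kinetic dataset
#'
#' Evaluates the model flux on the protocol's condition grid and applies
#' multiplicative Gaussian measurement noise:
#' \eqn{rate_i = J(c_i) (1 + cv\,\epsilon_i)}, \eqn{\epsilon_i \sim N(0,1)}
#' i.i.d. from a seeded generator. A synthetic stand-in for the undeposited
#' source data of the three classical protocols; with `noise_cv = 0` the
#' rates equal the model fluxes exactly, and identical
#' `(seed, spec, params)` reproduce the dataset bit-for-bit.
#'
#' If `params` came from [packaged_params()], the rate constant specific to
#' the protocol's source dataset is used automatically (the published fits
#' carry one rate constant per experimental preparation).
#'
#' @param params Parameter object ([mcu_params_present()],
#'   [mcu_params_previous()] or a [packaged_params()] result).
#' @param spec A [make_protocol()] specification (or a protocol id string).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (`>= 0`; default 0.05).
#' @param seed Integer seed for the noise stream.
#' @param thermo A [thermo_context()].
#' @return A `kinetic_dataset`: a data frame with columns `ca_e`, `ca_x`
#'   (molar), `dpsi` (mV), `rate` (nmol/mg/s), carrying the protocol and a
#'   provenance record (`seed`, `noise_cv`, generating parameters) as
#'   attributes.
#' @export
generate_dataset <- function(params, spec, noise_cv = 0.05, seed = 1L,
                             thermo = thermo_context()) {
  if (is.character(spec)) spec <- make_protocol(spec)
  stopifnot(inherits(spec, "protocol_spec"), inherits(params, "mcu_params"))
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("`noise_cv` must be a nonnegative scalar", call. = FALSE)
  dataset_key <- sub("_titration$", "", spec$protocol_id)
  params_used <- params_for_dataset(params, dataset_key)
  cond <- protocol_conditions(spec)
  mu <- uniporter_flux(params_used, cond$ca_e, cond$ca_x, cond$dpsi, thermo)
  eps <- if (noise_cv > 0) {
    with_local_seed(seed, stats::rnorm(nrow(cond)))
  } else rep(0, nrow(cond))
  ds <- cond
  ds$rate <- mu * (1 + noise_cv * eps)
  structure(ds,
            class = c("kinetic_dataset", "data.frame"),
            protocol = spec,
            provenance = list(type = "synthetic", seed = seed,
                              noise_cv = noise_cv, params = params_used))
}

#' Construct a kinetic dataset from raw columns
#'
#' Wraps user-supplied measurements (e.g. digitized from the original
#' figures) in the container the estimation functions expect.
#'
#' @param ca_e,ca_x External / matrix free Ca2+, molar.
#' @param dpsi Membrane potential, mV.
#' @param rate Measured initial uptake rate, nmol/mg/s.
#' @param rate_sd Optional per-point standard deviation.
#' @param protocol Optional [make_protocol()] spec.
#' @param provenance Optional provenance record (list).
#' @return A `kinetic_dataset`.
#' @export
kinetic_dataset <- function(ca_e, ca_x, dpsi, rate, rate_sd = NULL,
                            protocol = NULL, provenance = NULL) {
  check_conditions(ca_e, ca_x, dpsi)
  if (!is.numeric(rate) || any(!is.finite(rate)))
    stop("`rate` must be finite (nmol/mg/s)", call. = FALSE)
  ds <- data.frame(ca_e = ca_e, ca_x = ca_x, dpsi = dpsi, rate = rate)
  if (!is.null(rate_sd)) ds$rate_sd <- rate_sd
  structure(ds, class = c("kinetic_dataset", "data.frame"),
            protocol = protocol,
            provenance = provenance %||% list(type = "user"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kinetic_dataset <- function(x, ...) {
  prov <- attr(x, "provenance")
  spec <- attr(x, "protocol")
  cat(sprintf("<kinetic_dataset> %d rows%s%s\n", nrow(x),
              if (!is.null(spec)) paste0(", protocol ", spec$protocol_id) else "",
              if (!is.null(prov) && identical(prov$type, "synthetic"))
                sprintf(" (synthetic: seed %s, cv %.3g)", prov$seed, prov$noise_cv)
              else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Write / read a kinetic dataset as CSV
#'
#' Column schema (header mandatory, UTF-8, `.` decimal separator):
#' `dataset_id, protocol_id, ca_e_uM, ca_x_nM, dpsi_mV, rate_nmol_mg_s`
#' plus optional `rate_sd`. Unit suffixes are part of the column names on
#' purpose: the source literature mixes molar and micromolar conventions.
#' A provenance header (`#`-prefixed: package version, seed, config hash)
#' precedes the table; two writes of the same dataset are byte-identical.
#'
#' @param ds A `kinetic_dataset`.
#' @param path Output CSV path.
#' @param dataset_id Identifier written to the `dataset_id` column.
#' @return `path`, invisibly (`write_kinetic_csv`); a `kinetic_dataset`
#'   (`read_kinetic_csv`).
#' @export
write_kinetic_csv <- function(ds, path, dataset_id = "dataset1") {
  stopifnot(inherits(ds, "kinetic_dataset"))
  spec <- attr(ds, "protocol")
  prov <- attr(ds, "provenance") %||% list(type = "user")
  protocol_id <- if (!is.null(spec)) spec$protocol_id else "custom"
  out <- data.frame(
    dataset_id = dataset_id,
    protocol_id = protocol_id,
    ca_e_uM = fmt_num(ds$ca_e * 1e6),
    ca_x_nM = fmt_num(ds$ca_x * 1e9),
    dpsi_mV = fmt_num(ds$dpsi),
    rate_nmol_mg_s = fmt_num(ds$rate))
  if (!is.null(ds$rate_sd)) out$rate_sd <- fmt_num(ds$rate_sd)
  hdr <- c(
    sprintf("# mcuflux %s kinetic dataset", as.character(utils::packageVersion("mcuflux"))),
    sprintf("# provenance: %s", prov$type %||% "user"),
    if (identical(prov$type, "synthetic"))
      c(sprintf("# seed: %s", prov$seed),
        sprintf("# noise_cv: %s", fmt_num(prov$noise_cv)),
        sprintf("# params_hash: %s", config_hash(prov$params))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(out), collapse = ",")), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @param path Path of a CSV following the schema above.
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("ca_e_uM", "ca_x_nM", "dpsi_mV", "rate_nmol_mg_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("dataset CSV '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("dataset CSV '%s': non-numeric or missing values at data line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  kinetic_dataset(ca_e = df$ca_e_uM * 1e-6, ca_x = df$ca_x_nM * 1e-9,
                  dpsi = df$dpsi_mV, rate = df$rate_nmol_mg_s,
                  rate_sd = df$rate_sd,
                  provenance = list(type = "user_csv", path = path))
}

fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.12g", v), character(1))
}

# stable short hash of an R object's deparsed form (base tools only)
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(x)), tf)
  unname(tools::md5sum(tf))
}
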