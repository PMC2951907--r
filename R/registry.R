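#' Packaged published parameter sets
#'
#' Returns one of the parameter sets shipped with the package, transcribed
#' from the published fits to the three classical uptake experiments (rat
#' heart Ca2+ titration, rat liver Ca2+ titration, rat liver membrane
#' potential titration) and normalized to internal units (molar, mV,
#' nmol/mg/s). The binding constant and the shape/barrier parameters are
#' shared within a tissue; the rate constant is dataset-specific because the
#' source experiments used different mitochondrial preparations (and
#' different buffer Mg2+, which the rate constants absorb implicitly).
#'
#' Accepted names (case-insensitive):
#' \itemize{
#'   \item `"present/model1/liver"`, `"present/model1/heart"`,
#'     `"present/model2/liver"`, ... — generalized-GHK sets; a bare tissue
#'     resolves to its Ca2+-titration rate constant, while
#'     `".../liver_dpsi"` (or `".../liver_ca"`, `".../heart_ca"`) selects the
#'     dataset-specific one.
#'   \item `"previous/model1/case1"`, `"previous/model2/case2"`, ... —
#'     Eyring-barrier sets; defaults to the liver Ca2+-titration rate
#'     constant, with `".../heart_ca"` etc. selecting a dataset. Case 2
#'     returns the `m = 1` baseline of the scaling family.
#' }
#'
#' The returned object carries a `k0_by_dataset` attribute (named vector
#' over `heart_ca`, `liver_ca`, `liver_dpsi`) and a `K0_by_dataset`
#' attribute, which [generate_dataset()] uses to pick the rate constant
#' matching a protocol.
#'
#' @param name Registry name, e.g. `"present/model1/liver"`.
#' @return An [mcu_params_present()] or [mcu_params_previous()] object.
#' @export
packaged_params <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  parts <- strsplit(tolower(trimws(name)), "/", fixed = TRUE)[[1]]
  if (length(parts) < 3L || !parts[1] %in% c("present", "previous") ||
      !parts[2] %in% c("model1", "model2"))
    stop(sprintf("unknown packaged parameter set '%s'", name), call. = FALSE)
  formulation <- parts[1]; variant <- parts[2]
  tab <- if (formulation == "present") "table2" else "table1"
  path <- system.file("extdata", "params",
                      sprintf("params_%s_%s.json", tab, variant),
                      package = "mcuflux", mustWork = TRUE)
  reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)

  dataset_key <- function(x) {
    switch(x,
           liver = "liver_ca", heart = "heart_ca",
           liver_ca = "liver_ca", heart_ca = "heart_ca",
           liver_dpsi = "liver_dpsi",
           liver_ca_titration = "liver_ca", heart_ca_titration = "heart_ca",
           liver_dpsi_titration = "liver_dpsi",
           stop(sprintf("unknown tissue/dataset '%s' in packaged name", x),
                call. = FALSE))
  }

  k0_by_dataset <- vapply(reg$datasets, function(d) d$k0_nmol_mg_s, 0)
  K0_by_dataset <- vapply(reg$datasets, function(d) {
    if (!is.null(d$K0_M)) d$K0_M else d$K0_uM * 1e-6
  }, 0)

  if (formulation == "present") {
    key <- dataset_key(parts[3])
    d <- reg$datasets[[key]]
    if (is.null(d)) stop(sprintf("unknown packaged parameter set '%s'", name),
                         call. = FALSE)
    p <- mcu_params_present(k0 = k0_by_dataset[[key]],
                            K0 = K0_by_dataset[[key]],
                            alpha = reg$shared$alpha, nH = reg$shared$nH,
                            variant = variant)
  } else {
    case <- parts[3]
    if (!case %in% c("case1", "case2"))
      stop(sprintf("unknown packaged parameter set '%s' (expected .../case1 or .../case2)",
                   name), call. = FALSE)
    key <- if (length(parts) >= 4L) dataset_key(parts[4]) else "liver_ca"
    d <- reg$datasets[[key]]
    if (is.null(d)) stop(sprintf("unknown packaged parameter set '%s'", name),
                         call. = FALSE)
    k0 <- k0_by_dataset[[key]]; K0 <- K0_by_dataset[[key]]
    p <- mcu_params_previous(k_in0 = k0, k_out0 = k0, K_e0 = K0, K_x0 = K0,
                             alpha_e = reg$shared$alpha,
                             alpha_x = reg$shared$alpha,
                             beta_e = reg$shared$beta_e,
                             beta_x = reg$shared$beta_x,
                             variant = variant, case = case)
  }
  attr(p, "k0_by_dataset") <- k0_by_dataset
  attr(p, "K0_by_dataset") <- K0_by_dataset
  attr(p, "registry_name") <- tolower(trimws(name))
  p
}

#' Names of all packaged parameter sets
#'
#' @return Character vector of registry names accepted by [packaged_params()].
#' @export
packaged_params_names <- function() {
  c(as.vector(outer(c("present/model1", "present/model2"),
                    c("heart", "liver", "liver_dpsi"), paste, sep = "/")),
    as.vector(outer(c("previous/model1", "previous/model2"),
                    c("case1", "case2",
                      "case1/heart_ca", "case2/heart_ca",
                      "case1/liver_dpsi", "case2/liver_dpsi"),
                    paste, sep = "/")))
}

# swap a packaged parameter object's rate/binding constants to those of a
# specific source dataset (heart_ca / liver_ca / liver_dpsi), if known
params_for_dataset <- function(params, dataset) {
  kb <- attr(params, "k0_by_dataset")
  Kb <- attr(params, "K0_by_dataset")
  if (is.null(kb) || !dataset %in% names(kb)) return(params)
  if (inherits(params, "mcu_params_present")) {
    p <- mcu_params_present(k0 = kb[[dataset]], K0 = Kb[[dataset]],
                            alpha = params$alpha, nH = params$nH,
                            variant = params$variant)
  } else {
    p <- mcu_params_previous(k_in0 = kb[[dataset]], k_out0 = kb[[dataset]],
                             K_e0 = Kb[[dataset]], K_x0 = Kb[[dataset]],
                             alpha_e = params$alpha_e, alpha_x = params$alpha_x,
                             beta_e = params$beta_e, beta_x = params$beta_x,
                             variant = params$variant, case = params$case)
  }
  attr(p, "k0_by_dataset") <- kb
  attr(p, "K0_by_dataset") <- Kb
  p
}
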