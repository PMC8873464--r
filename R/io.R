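## Plate CSV dialect: a long-format data CSV (well, time_h, fluorescence)
## plus a per-well metadata CSV (well, m0_uM, seed_pct, compound, molar_ratio,
## replicate).  Concentrations are micromolar and seed doses percent in the
## files (the plate reader's units); molar and fractions in memory.

#' Read a kinetic plate CSV pair
#'
#' @param data_csv Long-format CSV with columns `well`, `time_h`,
#'   `fluorescence`.
#' @param meta_csv Metadata CSV with columns `well`, `m0_uM`, `seed_pct`,
#'   `compound`, `molar_ratio`, `replicate`.
#' @return A long-format kinetic tibble in internal units (`m0_M`,
#'   `seed_fraction`).
#' @export
read_plate_csv <- function(data_csv, meta_csv) {
  d <- readr::read_csv(data_csv, show_col_types = FALSE)
  m <- readr::read_csv(meta_csv, show_col_types = FALSE)
  .check_tht_data(d)
  need <- c("well", "m0_uM", "seed_pct", "compound", "molar_ratio", "replicate")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    abort(paste0("metadata missing columns: ", paste(miss, collapse = ", ")),
          class = "amylokin_invalid_input")
  }
  m <- dplyr::mutate(m, m0_M = .data$m0_uM * 1e-6,
                     seed_fraction = .data$seed_pct / 100) |>
    dplyr::select(-"m0_uM", -"seed_pct")
  dplyr::inner_join(d, m, by = "well")
}

#' Write a kinetic dataset as a plate CSV pair
#'
#' @param data A long-format kinetic tibble (internal units).
#' @param data_csv,meta_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plate_csv <- function(data, data_csv, meta_csv) {
  .check_tht_data(data)
  readr::write_csv(data[, c("well", "time_h", "fluorescence")], data_csv)
  meta <- data |>
    dplyr::distinct(.data$well, .keep_all = TRUE) |>
    dplyr::transmute(.data$well, m0_uM = .data$m0_M * 1e6,
                     seed_pct = .data$seed_fraction * 100,
                     compound = .data$compound,
                     molar_ratio = .data$molar_ratio,
                     replicate = .data$replicate)
  readr::write_csv(meta, meta_csv)
  invisible(c(data_csv, meta_csv))
}

#' Write a half-time summary CSV
#'
#' Columns: the grouping metadata plus `mean_t50_h`, `sd_t50_h`, `n`.
#'
#' @param t50_summary Output of [summarize_t50()].
#' @param path Output file.
#' @export
write_t50_csv <- function(t50_summary, path) {
  readr::write_csv(t50_summary, path)
  invisible(path)
}

#' Serialise a parameter set to JSON
#'
#' Keys: `k_n`, `k_plus`, `k_2`, `K_M`, `k_minus`, `n_c`, `n_2`, `model`.
#'
#' @param params A [kinetic_params()] object.
#' @param model Model id stored alongside the constants.
#' @param path Output file.
#' @export
write_params_json <- function(params, model, path) {
  x <- unclass(params)
  if (!is.finite(x$K_M)) x$K_M <- NULL   # Inf encoded as an absent key
  x$model <- model_id(model)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path JSON file written by [write_params_json()].
#' @return A list with elements `params` ([kinetic_params()]) and `model`.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- model_id(x$model)
  x$model <- NULL
  if (is.null(x$K_M)) x$K_M <- Inf   # Inf is not representable in JSON
  list(params = do.call(kinetic_params, x), model = model)
}

#' Write a global-fit report as JSON
#'
#' @param fit A `global_fit` object.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "global_fit"))
  report <- list(
    model = fit$spec$model,
    fixed = fit$spec$fixed,
    estimates = purrr::pmap(fit$estimates,
                            function(parameter, value, unit)
                              list(parameter = parameter, value = value,
                                   unit = unit)),
    objective = fit$objective,
    n_traces = fit$n_traces,
    converged = fit$converged,
    seed = fit$spec$rng_seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a per-dose modulator ratio CSV
#'
#' Columns: `dose_molar_ratio`, `varied_param`, `K_app_over_K`.
#'
#' @param mod_fit A `modulator_fit` object.
#' @param path Output file.
#' @export
write_modulator_csv <- function(mod_fit, path) {
  stopifnot(inherits(mod_fit, "modulator_fit"))
  tab <- dplyr::transmute(mod_fit$table,
                          dose_molar_ratio = .data$dose,
                          varied_param = mod_fit$varied,
                          K_app_over_K = .data$K_app_over_K)
  readr::write_csv(tab, path)
  invisible(path)
}
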