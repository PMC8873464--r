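#' Microscopic rate constants of the assembly model
#'
#' Bundles the rate constants and reaction orders of the nucleation-dependent
#' fibril growth model.  Internal units are molar for concentrations and hours
#' for time, matching plate-reader time axes.
#'
#' @param k_n Primary nucleation rate constant, M^(1 - n_c) h^-1.
#' @param k_plus Elongation rate constant, M^-1 h^-1.
#' @param k_2 Secondary nucleation rate constant, M^(-n_2) h^-1.  Zero for
#'   models without secondary nucleation.
#' @param K_M Saturation constant of multi-step secondary nucleation, in units
#'   of M^n_2; `Inf` means the single-step (unsaturated) form.  Reported to
#'   users as `sqrt(K_M)` (the monomer concentration of half-saturation) when
#'   `n_2 = 2`.
#' @param k_minus Fragmentation rate constant, h^-1.
#' @param n_c Reaction order of primary nucleation (integer >= 1).
#' @param n_2 Reaction order of secondary nucleation (integer >= 1).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(k_n = 0.65, k_plus = 1e6, k_2 = 3.2e8, K_M = 1e-10)
#' @export
kinetic_params <- function(k_n = 0, k_plus = 0, k_2 = 0, K_M = Inf,
                           k_minus = 0, n_c = 2L, n_2 = 2L) {
  vals <- c(k_n = k_n, k_plus = k_plus, k_2 = k_2, k_minus = k_minus)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("rate constants must be finite and >= 0", class = "amylokin_invalid_input")
  }
  if (!is.finite(K_M) && !identical(K_M, Inf) || (is.finite(K_M) && K_M <= 0)) {
    abort("K_M must be > 0 (possibly Inf)", class = "amylokin_invalid_input")
  }
  if (n_c < 1 || n_2 < 1 || n_c != round(n_c) || n_2 != round(n_2)) {
    abort("n_c and n_2 must be integers >= 1", class = "amylokin_invalid_input")
  }
  structure(
    list(k_n = k_n, k_plus = k_plus, k_2 = k_2, K_M = K_M,
         k_minus = k_minus, n_c = as.integer(n_c), n_2 = as.integer(n_2)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  (molar, hours)\n")
  cat(sprintf("  k_n     = %.4g M^(1-n_c) h^-1\n", x$k_n))
  cat(sprintf("  k_plus  = %.4g M^-1 h^-1\n", x$k_plus))
  cat(sprintf("  k_2     = %.4g M^(-n_2) h^-1\n", x$k_2))
  cat(sprintf("  K_M     = %.4g M^n_2  (sqrt = %.4g M)\n", x$K_M, sqrt(x$K_M)))
  cat(sprintf("  k_minus = %.4g h^-1\n", x$k_minus))
  cat(sprintf("  n_c = %d, n_2 = %d\n", x$n_c, x$n_2))
  cat(sprintf("  combined: k_plus*k_n = %.4g, k_plus*k_2 = %.4g\n",
              x$k_plus * x$k_n, x$k_plus * x$k_2))
  invisible(x)
}

#' Combined rate constants reported by global fits
#'
#' The products identifiable from normalised unseeded kinetics, plus the
#' half-saturation concentration of secondary nucleation.
#'
#' @param params A [kinetic_params()] object.
#' @return A tibble with columns `parameter`, `value`, `unit`.
#' @export
combined_constants <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  tibble(
    parameter = c("k_plus_k_n", "k_plus_k_2", "sqrt_K_M"),
    value = c(params$k_plus * params$k_n,
              params$k_plus * params$k_2,
              sqrt(params$K_M)),
    unit = c(sprintf("M^%d h^-2", -params$n_c),
             sprintf("M^%d h^-2", -params$n_2 - 1L),
             "M")
  )
}

## Model ids of the nested family ---------------------------------------------

.model_ids <- c("PE", "PEF", "PES", "PEMS")

#' Nested kinetic model identifiers
#'
#' `PE` = primary nucleation + elongation; `PEF` adds fragmentation; `PES`
#' adds (single-step) secondary nucleation; `PEMS` adds multi-step, saturating
#' secondary nucleation.  `PEMS` with `K_M -> Inf` reduces to `PES`; `PES`
#' with `k_2 = 0` reduces to `PE`.
#'
#' @param model Character scalar, one of `"PE"`, `"PEF"`, `"PES"`, `"PEMS"`.
#' @return The validated model id.
#' @export
model_id <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% .model_ids) {
    abort(sprintf("model must be one of %s", paste(.model_ids, collapse = ", ")),
          class = "amylokin_invalid_input")
  }
  model
}

## Restrict a parameter set to the processes a model contains.
## PES uses the unsaturated secondary form (K_M = Inf); PEMS requires finite K_M.
.params_for_model <- function(params, model) {
  model <- model_id(model)
  p <- params
  if (model %in% c("PE", "PEF")) p$k_2 <- 0
  if (model != "PEF") p$k_minus <- 0
  if (model %in% c("PE", "PEF", "PES")) p$K_M <- Inf
  if (model == "PEMS" && !is.finite(params$K_M)) {
    abort("PEMS requires a finite K_M > 0", class = "amylokin_invalid_input")
  }
  p
}
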