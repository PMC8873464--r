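## ThT curve processing: normalisation, half times, scaling analysis.
##
## Kinetic data travel as long-format tibbles with one row per (well, time)
## and per-well metadata columns: well, time_h, fluorescence, m0_M,
## seed_fraction, compound, molar_ratio, replicate.

.trace_meta_cols <- c("m0_M", "seed_fraction", "compound", "molar_ratio",
                      "replicate")

.check_tht_data <- function(data, value_col = "fluorescence") {
  need <- c("well", "time_h", value_col)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
          class = "amylokin_invalid_input")
  }
  invisible(data)
}

#' Normalise ThT traces to relative fibril mass
#'
#' Maps each fluorescence trace to a mass fraction
#' `(F - baseline) / (plateau - baseline)`, using the means of the first and
#' last `window_frac` of points (at least 3 each) as baseline and plateau.
#' Traces whose growth is immediate (seeded at >= 5 % v/v) use the first
#' point alone as baseline, since no flat pre-growth window exists.
#' Traces with no growth (plateau <= baseline beyond noise) are flagged
#' `non_sigmoidal` rather than erroring.
#'
#' @param data Long-format kinetic tibble with columns `well`, `time_h`,
#'   `fluorescence` plus any metadata columns (carried through).
#' @param window_frac Fraction of points used for the baseline and plateau
#'   windows (default 0.05).
#' @return The input with columns `mass_fraction`, `baseline`, `plateau`,
#'   `non_sigmoidal` added.
#' @export
normalize_traces <- function(data, window_frac = 0.05) {
  .check_tht_data(data)
  data |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_h)
      if (nrow(df) < 8) abort("traces need >= 8 time points",
                              class = "amylokin_invalid_input")
      if (any(!is.finite(df$fluorescence))) {
        abort("non-finite fluorescence", class = "amylokin_invalid_input")
      }
      n <- nrow(df)
      k <- max(3L, ceiling(window_frac * n))
      seeded <- "seed_fraction" %in% names(df) && df$seed_fraction[1] >= 0.05
      base <- if (seeded) df$fluorescence[1] else mean(df$fluorescence[seq_len(k)])
      plat <- mean(df$fluorescence[seq.int(n - k + 1L, n)])
      span <- plat - base
      noise <- stats::sd(df$fluorescence[seq_len(k)])
      flat <- span <= 0 || (!seeded && is.finite(noise) && span < 3 * noise)
      df$baseline <- base
      df$plateau <- plat
      df$non_sigmoidal <- flat
      df$mass_fraction <- if (flat) NA_real_ else (df$fluorescence - base) / span
      df
    }) |>
    dplyr::ungroup()
}

#' Half time of a normalised trace
#'
#' The half time is the time at which the signal reaches half of the span
#' between baseline and plateau: the first upward crossing of
#' `mass_fraction = 0.5`, located by linear interpolation between the
#' bracketing samples.  Traces that never cross within the observation window
#' get `t50 = NA` and `censored = TRUE` ("t50 > t_max"), as happens for
#' strongly inhibited doses.
#'
#' @param data Output of [normalize_traces()] (or any tibble with `well`,
#'   `time_h`, `mass_fraction` and metadata columns).
#' @return One row per well: metadata columns plus `t50_h` and `censored`.
#' @export
compute_t50 <- function(data) {
  .check_tht_data(data, value_col = "mass_fraction")
  data |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_h)
      meta <- df[1, intersect(.trace_meta_cols, names(df)), drop = FALSE]
      t50 <- .t50_crossing(df$time_h, df$mass_fraction)
      dplyr::bind_cols(meta, tibble(t50_h = t50, censored = is.na(t50)))
    }) |>
    dplyr::ungroup()
}

## First upward 0.5-crossing by linear interpolation; NA if none.
.t50_crossing <- function(times, y, level = 0.5) {
  if (all(is.na(y))) return(NA_real_)
  above <- y >= level
  idx <- which(!above[-length(above)] & above[-1])
  if (is.na(above[1]) || length(idx) == 0) {
    if (!is.na(above[1]) && above[1]) return(times[1])
    return(NA_real_)
  }
  i <- idx[1]
  t0 <- times[i]; t1 <- times[i + 1]
  y0 <- y[i]; y1 <- y[i + 1]
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Summarise half times over replicates
#'
#' @param t50s Output of [compute_t50()].
#' @param ... Grouping columns (defaults to all metadata columns present
#'   except `replicate`).
#' @return A tibble with `mean_t50_h`, `sd_t50_h`, `n` per group.
#' @export
summarize_t50 <- function(t50s, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    cols <- setdiff(intersect(.trace_meta_cols, names(t50s)), "replicate")
    groups <- rlang::syms(cols)
  }
  t50s |>
    dplyr::filter(!.data$censored) |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(mean_t50_h = mean(.data$t50_h),
                     sd_t50_h = stats::sd(.data$t50_h),
                     n = dplyr::n(), .groups = "drop")
}

#' Power-law fit of half time versus initial monomer concentration
#'
#' Fits `t50 = A * m0^gamma` by ordinary least squares of `log(t50)` on
#' `log(m0)`.  The exponent gamma is the standard diagnostic of the dominant
#' assembly mechanism.
#'
#' @param data A tibble with columns `m0_M` and `t50_h` (e.g. from
#'   [compute_t50()] or [summarize_t50()] after renaming), or pass the two
#'   vectors via `m0` and `t50`.
#' @param m0,t50 Optional numeric vectors overriding `data`.
#' @return An object of class `power_law_fit` with elements `A`, `gamma`,
#'   `gamma_se`, `residuals_log` and the underlying `lm` fit.  `tidy()` and
#'   `glance()` methods are available.
#' @examples
#' fit_power_law(m0 = c(8, 16, 32) * 1e-6, t50 = 2 * (c(8, 16, 32) * 1e-6)^-1.5)
#' @export
fit_power_law <- function(data = NULL, m0 = NULL, t50 = NULL) {
  if (is.null(m0)) m0 <- data$m0_M
  if (is.null(t50)) t50 <- data[["t50_h"]] %||% data[["mean_t50_h"]]
  keep <- !is.na(m0) & !is.na(t50)
  m0 <- m0[keep]; t50 <- t50[keep]
  if (length(unique(m0)) < 3 || any(m0 <= 0) || any(t50 <= 0)) {
    abort("need >= 3 distinct positive m0 values with positive t50",
          class = "amylokin_invalid_input")
  }
  fit <- lm(log(t50) ~ log(m0))
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(A = exp(coef(fit)[[1]]), gamma = coef(fit)[[2]],
         gamma_se = sm[2, 2], A_log_se = sm[1, 2],
         residuals_log = stats::residuals(fit),
         m0 = m0, t50 = t50, fit = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit>  t50 = A * m0^gamma\n  gamma = %.3f +/- %.3f\n  A = %.4g h M^(-gamma)\n",
              x$gamma, x$gamma_se, x$A))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("log_A", "gamma"),
         estimate = c(log(x$A), x$gamma),
         std.error = c(x$A_log_se, x$gamma_se))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(gamma = x$gamma, gamma_se = x$gamma_se, A = x$A,
         r.squared = suppressWarnings(summary(x$fit))$r.squared,
         n = length(x$m0))
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  df <- tibble(m0_uM = object$m0 * 1e6, t50_h = object$t50)
  grid <- tibble(m0_uM = exp(seq(log(min(df$m0_uM)), log(max(df$m0_uM)),
                                 length.out = 50)))
  grid$t50_h <- object$A * (grid$m0_uM * 1e-6)^object$gamma
  ggplot2::ggplot(df, ggplot2::aes(.data$m0_uM, .data$t50_h)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(m[0] ~ (mu * M)), y = expression(t[50] ~ (h)),
                  title = sprintf("gamma = %.2f +/- %.2f",
                                  object$gamma, object$gamma_se))
}
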