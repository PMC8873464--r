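## Ligand-binding spectroscopy fits: Stern-Volmer quenching (linear and
## modified log-log forms), SPR steady-state 1:1 isotherms, CID dissociation
## midpoints, and NMR chemical-shift-perturbation arithmetic.

.check_titration <- function(data) {
  if (!all(c("Q_M", "F") %in% names(data))) {
    abort("titration needs columns Q_M and F", class = "amylokin_invalid_input")
  }
  if (any(data$F <= 0) || any(data$Q_M < 0)) {
    abort("need F > 0 and Q_M >= 0", class = "amylokin_invalid_input")
  }
  invisible(data)
}

#' Stern-Volmer quenching fit
#'
#' Fits `F0/F = 1 + K_SV * Q` with the intercept constrained to 1 (the form
#' of the equation), returning the Stern-Volmer constant and a linearity
#' diagnostic.  `F0` defaults to the intensity at `Q = 0`.
#'
#' @param data A tibble with columns `Q_M` (quencher concentration, M,
#'   including 0) and `F` (emission intensity, a.u.).
#' @param F0 Unquenched intensity; default `F` at the smallest `Q`.
#' @return An object of class `sv_fit` with `K_SV` (M^-1), `r.squared` and the
#'   underlying data; `tidy()`/`glance()` methods available.
#' @examples
#' t <- generate_quench_titration(K = 1.34e4)
#' fit_stern_volmer(t)$K_SV
#' @export
fit_stern_volmer <- function(data, F0 = NULL) {
  .check_titration(data)
  if (nrow(data) < 3) {
    abort("need >= 3 titration points", class = "amylokin_invalid_input")
  }
  F0 <- F0 %||% data$F[which.min(data$Q_M)]
  y <- F0 / data$F - 1
  q <- data$Q_M
  K_SV <- sum(q * y) / sum(q^2)          # through-origin least squares
  fitted <- K_SV * q
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(K_SV = K_SV,
                 r.squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 F0 = F0, data = data),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("<sv_fit>  K_SV = %.4g M^-1 (R^2 = %.4f)\n", x$K_SV, x$r.squared))
  invisible(x)
}

#' @export
tidy.sv_fit <- function(x, ...) {
  tibble(term = "K_SV", estimate = x$K_SV, unit = "M^-1")
}

#' @export
glance.sv_fit <- function(x, ...) {
  tibble(K_SV = x$K_SV, r.squared = x$r.squared, n = nrow(x$data))
}

#' Bimolecular quenching rate constant and mechanism classification
#'
#' `k_q = K_SV / tau0`.  Quenching faster than the diffusion-limited
#' collisional maximum (~2e10 M^-1 s^-1) cannot be dynamic, so such fits are
#' classified `"static"`; otherwise `"dynamic-compatible"`.
#'
#' @param K_SV Stern-Volmer constant (M^-1).
#' @param tau0 Unquenched fluorophore lifetime (s); default 1e-9 (tyrosine).
#' @return A list with `k_q` (M^-1 s^-1) and `mechanism`.
#' @examples
#' quenching_rate_constant(1.34e4)  # ~1.3e13, static
#' @export
quenching_rate_constant <- function(K_SV, tau0 = 1e-9) {
  if (!is.finite(tau0) || tau0 <= 0) {
    abort("tau0 must be > 0", class = "amylokin_invalid_input")
  }
  if (K_SV < 0) abort("K_SV must be >= 0", class = "amylokin_invalid_input")
  k_q <- K_SV / tau0
  list(k_q = k_q,
       mechanism = if (k_q > 2e10) "static" else "dynamic-compatible")
}

#' Modified Stern-Volmer (double-log) binding fit
#'
#' Fits `log10((F0 - F)/F) = log10(K_b) + n * log10(Q)` by least squares on
#' the points with `0 < F < F0` at `Q > 0`, yielding the binding constant
#' `K_b`, the binding-site number `n`, and `K_d = 1/K_b`.
#'
#' @inheritParams fit_stern_volmer
#' @return An object of class `msv_fit` with `K_b` (M^-n), `n_sites`,
#'   `K_d` (M).
#' @examples
#' t <- generate_quench_titration(K = 3.125e4, mode = "K_b")
#' fit_modified_stern_volmer(t)$K_d * 1e6  # ~32 uM
#' @export
fit_modified_stern_volmer <- function(data, F0 = NULL) {
  .check_titration(data)
  F0 <- F0 %||% data$F[which.min(data$Q_M)]
  d <- data[data$Q_M > 0, ]
  bad <- d$F >= F0
  if (any(bad)) {
    warn(sprintf("%d point(s) with F >= F0 at Q > 0 dropped", sum(bad)))
    d <- d[!bad, ]
  }
  if (nrow(d) < 3) {
    abort("fewer than 3 usable points", class = "amylokin_invalid_input")
  }
  x <- log10(d$Q_M)
  y <- log10((F0 - d$F) / d$F)
  fit <- lm(y ~ x)
  K_b <- 10^coef(fit)[[1]]
  n <- coef(fit)[[2]]
  structure(list(K_b = K_b, n_sites = n, K_d = 1 / K_b,
                 r.squared = suppressWarnings(summary(fit))$r.squared,
                 fit = fit, data = d, F0 = F0),
            class = "msv_fit")
}

#' @export
print.msv_fit <- function(x, ...) {
  cat(sprintf("<msv_fit>  K_b = %.4g M^-n, n = %.3f, K_d = %.4g M\n",
              x$K_b, x$n_sites, x$K_d))
  invisible(x)
}

#' @export
tidy.msv_fit <- function(x, ...) {
  tibble(term = c("K_b", "n_sites", "K_d"),
         estimate = c(x$K_b, x$n_sites, x$K_d),
         unit = c("M^-n", "", "M"))
}

#' @export
glance.msv_fit <- function(x, ...) {
  tibble(K_b = x$K_b, n_sites = x$n_sites, K_d = x$K_d,
         r.squared = x$r.squared, n = nrow(x$data))
}

#' SPR steady-state 1:1 isotherm fit
#'
#' Least-squares fit of `R = R_max * C / (K_d + C)` to steady-state responses.
#' At `C = K_d` the model predicts half-saturation.  A warning (not an error)
#' is issued when responses are non-monotone beyond noise; a flat all-zero
#' response returns `R_max = 0` with `K_d` flagged unidentifiable.
#'
#' @param data A tibble with columns `conc_M` and `response_RU`.
#' @return An object of class `spr_fit` with `K_d` (M), `R_max` (RU),
#'   `K_d_identifiable`.
#' @examples
#' iso <- generate_spr_isotherm(K_d = 240e-6, R_max = 50)
#' fit_spr_steady_state(iso)$K_d * 1e6  # 240
#' @export
fit_spr_steady_state <- function(data) {
  if (!all(c("conc_M", "response_RU") %in% names(data))) {
    abort("need columns conc_M and response_RU", class = "amylokin_invalid_input")
  }
  if (nrow(data) < 4) {
    abort("need >= 4 concentrations", class = "amylokin_invalid_input")
  }
  d <- dplyr::arrange(data, .data$conc_M)
  if (all(abs(d$response_RU) < .Machine$double.eps^0.5)) {
    return(structure(list(K_d = NA_real_, R_max = 0,
                          K_d_identifiable = FALSE, fit = NULL, data = d),
                     class = "spr_fit"))
  }
  drops <- diff(d$response_RU)
  if (any(drops < -0.05 * max(abs(d$response_RU)))) {
    warn("responses are non-monotone beyond noise; isotherm fit may be poor")
  }
  start <- list(R_max = max(d$response_RU) * 1.5,
                K_d = d$conc_M[which.min(abs(d$response_RU -
                                               max(d$response_RU) / 2))])
  fit <- minpack.lm::nlsLM(
    response_RU ~ R_max * conc_M / (K_d + conc_M),
    data = d, start = start,
    lower = c(R_max = 0, K_d = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  structure(list(K_d = est[["K_d"]], R_max = est[["R_max"]],
                 K_d_identifiable = TRUE, fit = fit, data = d),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("<spr_fit>  K_d = %.4g M, R_max = %.4g RU%s\n", x$K_d, x$R_max,
              if (x$K_d_identifiable) "" else "  [K_d unidentifiable]"))
  invisible(x)
}

#' @export
tidy.spr_fit <- function(x, ...) {
  tibble(term = c("K_d", "R_max"), estimate = c(x$K_d, x$R_max),
         unit = c("M", "RU"))
}

#' CID dissociation midpoint
#'
#' Four-parameter logistic fit of bound fraction versus trap voltage,
#' returning the midpoint: the voltage at which half the gas-phase complex
#' has dissociated, a relative measure of gas-phase stability.
#'
#' @param data A tibble with columns `trap_V` and `bound_fraction` (in [0,1],
#'   decreasing trend).
#' @return An object of class `cid_fit` with `midpoint_V`, `slope`, `upper`,
#'   `lower`, and `no_transition` (TRUE for constant data).
#' @examples
#' cid <- generate_cid_curve(midpoint_V = 16.5)
#' fit_cid_midpoint(cid)$midpoint_V
#' @export
fit_cid_midpoint <- function(data) {
  if (!all(c("trap_V", "bound_fraction") %in% names(data))) {
    abort("need columns trap_V and bound_fraction", class = "amylokin_invalid_input")
  }
  d <- dplyr::arrange(data, .data$trap_V)
  span <- max(d$bound_fraction) - min(d$bound_fraction)
  if (span < 0.05) {
    return(structure(list(midpoint_V = NA_real_, slope = NA_real_,
                          upper = NA_real_, lower = NA_real_,
                          no_transition = TRUE, fit = NULL, data = d),
                     class = "cid_fit"))
  }
  if (any(diff(d$bound_fraction) > 0.1 * span)) {
    warn("bound fraction is non-monotone beyond noise")
  }
  mid0 <- .t50_crossing(d$trap_V, 1 - (d$bound_fraction - min(d$bound_fraction)) / span)
  if (is.na(mid0)) mid0 <- mean(range(d$trap_V))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      bound_fraction ~ lower + (upper - lower) / (1 + exp(slope * (trap_V - mid))),
      data = d,
      start = list(upper = max(d$bound_fraction), lower = min(d$bound_fraction),
                   slope = 1, mid = mid0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## degenerate (step-like) data: the logistic gradient is singular, but
    ## the midpoint is still well defined by the half-crossing
    return(structure(list(midpoint_V = mid0, slope = NA_real_,
                          upper = max(d$bound_fraction),
                          lower = min(d$bound_fraction),
                          no_transition = FALSE, fit = NULL, data = d),
                     class = "cid_fit"))
  }
  est <- coef(fit)
  structure(list(midpoint_V = est[["mid"]], slope = est[["slope"]],
                 upper = est[["upper"]], lower = est[["lower"]],
                 no_transition = FALSE, fit = fit, data = d),
            class = "cid_fit")
}

#' @export
print.cid_fit <- function(x, ...) {
  if (x$no_transition) cat("<cid_fit>  no transition detected\n")
  else cat(sprintf("<cid_fit>  midpoint = %.2f V\n", x$midpoint_V))
  invisible(x)
}

#' @export
tidy.cid_fit <- function(x, ...) {
  tibble(term = c("midpoint_V", "slope", "upper", "lower"),
         estimate = c(x$midpoint_V, x$slope, x$upper, x$lower))
}

#' Amide chemical-shift perturbation
#'
#' Combines amide 1H and 15N chemical-shift changes as
#' `sqrt(5 * dH^2 + dN^2)`: the nitrogen axis is down-weighted for its wider
#' ppm range.  Vectorised; symmetric under sign flips of either input.
#'
#' @param delta_H,delta_N Chemical-shift changes (ppm).
#' @return CSP values (ppm).
#' @examples
#' compute_csp(0.01, 0.1)  # sqrt(0.0105)
#' @export
compute_csp <- function(delta_H, delta_N) {
  if (any(!is.finite(delta_H)) || any(!is.finite(delta_N))) {
    abort("inputs must be finite", class = "amylokin_invalid_input")
  }
  sqrt(5 * delta_H^2 + delta_N^2)
}
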