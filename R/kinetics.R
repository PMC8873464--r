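#' Time derivatives of the assembly moment equations
#'
#' Evaluates the closed-form right-hand side of the moment equations for the
#' chosen model at a single state:
#' \deqn{dP/dt = k_n m^{n_c} + k_- M + k_2 m^{n_2} M / (1 + m^{n_2}/K_M)}
#' \deqn{dM/dt = 2 k_+ m P, \qquad m = m_{total} - M.}
#' The factor 2 reflects growth at both fibril ends; it is absorbed into the
#' combined constants reported by fits but is stated and fixed here.
#'
#' @param state Named list or vector with elements `m`, `P`, `M_fib` (molar).
#' @param params A [kinetic_params()] object.
#' @param model A model id (see [model_id()]).
#' @param m_total Total monomer-equivalent concentration (M).
#' @return Named numeric vector `c(dP = , dM_fib = )` in M h^-1.
#' @export
assembly_rates <- function(state, params, model, m_total) {
  state <- as.list(state)
  m <- state$m; P <- state$P; M <- state$M_fib
  if (any(!is.finite(c(m, P, M, m_total))) || any(c(m, P, M, m_total) < 0)) {
    abort("state and m_total must be finite and non-negative",
          class = "amylokin_invalid_input")
  }
  p <- .params_for_model(params, model)
  sat <- if (is.finite(p$K_M)) 1 / (1 + m^p$n_2 / p$K_M) else 1
  dP <- p$k_n * m^p$n_c + p$k_minus * M + p$k_2 * m^p$n_2 * M * sat
  dM <- 2 * p$k_plus * m * P
  c(dP = dP, dM_fib = dM)
}

#' Initial state for a seeded assembly reaction
#'
#' Seeds are dosed as a volume fraction of a preformed fibril stock.  The dose
#' fixes seed mass; seed number is set through an assumed mean fibril length
#' (monomers per seed fibril), since a v/v dose carries no number information.
#'
#' @param fraction_vv Seed dose as volume fraction in `[0, 1)` (0.30 = 30 % v/v).
#' @param m0 Initial free monomer concentration (M).
#' @param stock_mass_conc Monomer-equivalent concentration of the fibril stock
#'   (M); default 32e-6 (a 32 uM aggregation reaction grown to completion).
#' @param mean_seed_length Average monomers per seed fibril (> 1); default 500,
#'   a sonicated-seed scale.
#' @return A list with elements `m`, `P`, `M_fib` (the initial state) and
#'   `m_total = m0 + M_fib`.
#' @examples
#' seed_state(0.10, m0 = 10e-6)  # M_fib(0) = 3.2 uM, P(0) = 6.4 nM
#' @export
seed_state <- function(fraction_vv, m0, stock_mass_conc = 32e-6,
                       mean_seed_length = 500) {
  if (!is.finite(fraction_vv) || fraction_vv < 0 || fraction_vv >= 1) {
    abort("fraction_vv must be in [0, 1)", class = "amylokin_invalid_input")
  }
  if (m0 < 0 || mean_seed_length <= 1 || stock_mass_conc < 0) {
    abort("need m0 >= 0, stock_mass_conc >= 0, mean_seed_length > 1",
          class = "amylokin_invalid_input")
  }
  M0 <- fraction_vv * stock_mass_conc
  list(m = m0, P = M0 / mean_seed_length, M_fib = M0, m_total = m0 + M0)
}

#' Simulate an assembly trajectory
#'
#' Integrates the moment equations with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, compiled right-hand side).  Tolerances default to
#' rtol = 1e-8 and atol = 1e-12 * `m_total` because the fibril number
#' concentration spans many orders of magnitude through the lag phase.
#'
#' @param params A [kinetic_params()] object.
#' @param model Model id (`"PE"`, `"PEF"`, `"PES"`, `"PEMS"`).
#' @param m_total Total monomer-equivalent concentration (M).  Defaults to
#'   `initial$m_total` when a seeded initial state is given.
#' @param times Strictly increasing time grid starting at 0 (hours).
#' @param initial Initial state as returned by [seed_state()]; default is the
#'   unseeded state (all monomer, no fibrils).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `assembly_trajectory` with columns `time_h`,
#'   `m_M`, `P_M`, `Mfib_M`, `mass_fraction`; the generating `params`, `model`
#'   and `m_total` are attached as attributes.
#' @examples
#' p <- kinetic_params(k_n = 0.65, k_plus = 1e6, k_2 = 3.2e8, K_M = 1e-10)
#' traj <- simulate_assembly(p, "PEMS", m_total = 10e-6,
#'                           times = seq(0, 42, by = 0.5))
#' @export
simulate_assembly <- function(params, model, m_total = NULL,
                              times = seq(0, 42, by = 0.2),
                              initial = NULL, rtol = 1e-8, atol = NULL) {
  model <- model_id(model)
  if (is.null(initial)) {
    if (is.null(m_total)) abort("supply m_total or a seeded initial state",
                                class = "amylokin_invalid_input")
    initial <- list(m = m_total, P = 0, M_fib = 0, m_total = m_total)
  }
  m_total <- m_total %||% initial$m_total
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing and start at 0",
          class = "amylokin_invalid_input")
  }
  if (any(c(initial$m, initial$P, initial$M_fib) < 0)) {
    abort("initial state must be non-negative", class = "amylokin_invalid_input")
  }
  p <- .params_for_model(params, model)

  if (m_total <= 0) {
    out <- cbind(times, 0, 0)
  } else {
    parms <- c(p$k_n, p$k_plus, p$k_2,
               if (is.finite(p$K_M)) p$K_M else -1,
               p$k_minus, p$n_c, p$n_2, m_total)
    atol <- atol %||% (1e-12 * m_total)
    y0 <- c(P = initial$P, M = initial$M_fib)
    out <- deSolve::lsoda(
      y = y0, times = times, func = "assembly_derivs", parms = parms,
      dllname = "amylokin", initfunc = "assembly_init",
      rtol = rtol, atol = c(atol * 1e-3, atol), maxsteps = 50000
    )
    if (attr(out, "istate")[1] < 0) {
      abort(paste0("ODE solver failed for parameter set: ",
                   paste(sprintf("%s=%.3g", names(parms), parms), collapse = ", ")),
            class = "amylokin_solver_failure")
    }
  }
  M <- pmin(pmax(out[, 3], 0), m_total)
  traj <- tibble(
    time_h = times,
    m_M = m_total - M,
    P_M = pmax(out[, 2], 0),
    Mfib_M = M,
    mass_fraction = if (m_total > 0) M / m_total else 0
  )
  structure(traj, params = params, model = model, m_total = m_total,
            class = c("assembly_trajectory", class(traj)))
}

#' Analytic half-time scaling exponents
#'
#' Closed-form limits of the scaling exponent gamma in `t50 ~ A * m0^gamma`
#' for the regime that dominates the kinetics: `-n_c/2` when primary
#' nucleation dominates, `-(n_2 + 1)/2` for unsaturated secondary nucleation,
#' and `-1/2` when secondary nucleation is fully saturated (the nucleation
#' step loses its monomer dependence).  Used as the oracle for
#' scaling-property tests.
#'
#' @param model Model id.
#' @param n_c,n_2 Reaction orders.
#' @param regime One of `"primary"`, `"secondary-unsaturated"`,
#'   `"secondary-saturated"`.
#' @return The exponent (dimensionless, negative).
#' @examples
#' halftime_exponent("PES", n_2 = 2, regime = "secondary-unsaturated")  # -1.5
#' @export
halftime_exponent <- function(model, n_c = 2L, n_2 = 2L,
                              regime = c("primary", "secondary-unsaturated",
                                         "secondary-saturated")) {
  model <- model_id(model)
  regime <- match.arg(regime)
  has_secondary <- model %in% c("PES", "PEMS")
  if (regime == "primary") return(-n_c / 2)
  if (!has_secondary) {
    abort(sprintf("model %s has no secondary nucleation; regime '%s' undefined",
                  model, regime), class = "amylokin_invalid_input")
  }
  if (regime == "secondary-unsaturated") return(-(n_2 + 1) / 2)
  if (model != "PEMS") {
    abort("the saturated regime requires the multi-step (PEMS) model",
          class = "amylokin_invalid_input")
  }
  -1 / 2
}

#' Write a simulated trajectory to CSV
#'
#' @param traj An `assembly_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "assembly_trajectory"))
  readr::write_csv(as_tibble(traj)[, c("time_h", "m_M", "P_M", "Mfib_M")], path)
  invisible(path)
}

#' @export
autoplot.assembly_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("m_M", "Mfib_M"),
                            names_to = "species", values_to = "conc_M")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$conc_M * 1e6,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(m_M = "steelblue", Mfib_M = "firebrick"),
      labels = c(m_M = "monomer", Mfib_M = "fibril mass")) +
    ggplot2::labs(x = "time (h)", y = "concentration (µM)",
                  colour = NULL,
                  title = sprintf("%s model, m_total = %.3g µM",
                                  attr(object, "model"),
                                  attr(object, "m_total") * 1e6))
}
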