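## Global fitting of normalised ThT datasets to the nested kinetic models.
##
## Normalised unseeded kinetics identify only the combined constants
## k_plus*k_n, k_plus*k_2 and the saturation constant K_M.  The fitter makes
## this explicit: k_plus is pinned internally (default 1e6 M^-1 h^-1) and the
## microscopic k_n, k_2, K_M are optimised in natural-log space; products are
## reported.  Freeing k_plus itself is only allowed when seeded traces are
## present, where fibril mass at t = 0 breaks the degeneracy.

.free_param_names <- c("k_plus_k_n", "k_plus_k_2", "K_M", "k_plus", "k_minus")

#' Default free parameters for each model
#'
#' @param model Model id.
#' @return Character vector of free parameter names.
#' @export
default_free <- function(model) {
  switch(model_id(model),
         PE = "k_plus_k_n",
         PEF = c("k_plus_k_n", "k_minus"),
         PES = c("k_plus_k_n", "k_plus_k_2"),
         PEMS = c("k_plus_k_n", "k_plus_k_2", "K_M"))
}

## Map a log-space theta for the free set onto a kinetic_params object.
.theta_to_params <- function(theta, free, base) {
  p <- unclass(base)
  for (i in seq_along(free)) {
    v <- exp(theta[i])
    switch(free[i],
           k_plus_k_n = p$k_n <- v,
           k_plus_k_2 = p$k_2 <- v,
           K_M = p$K_M <- v,
           k_plus = p$k_plus <- v,
           k_minus = p$k_minus <- v)
  }
  do.call(kinetic_params, p)
}

## Precompute per-condition observation structure: one ODE solve per distinct
## (m0, seed_fraction) serves every replicate trace of that condition.
.prep_conditions <- function(data, seed_template) {
  .check_tht_data(data, value_col = "mass_fraction")
  if (!"m0_M" %in% names(data)) {
    abort("traces must carry m0_M metadata", class = "amylokin_invalid_input")
  }
  if (!"seed_fraction" %in% names(data)) data$seed_fraction <- 0
  data |>
    dplyr::filter(!is.na(.data$mass_fraction)) |>
    dplyr::group_by(.data$m0_M, .data$seed_fraction) |>
    dplyr::group_map(function(df, key) {
      times <- sort(unique(df$time_h))
      if (times[1] > 0) times <- c(0, times)
      traces <- df |>
        dplyr::group_by(.data$well) |>
        dplyr::group_map(function(tr, k) {
          list(idx = match(tr$time_h, times), obs = tr$mass_fraction)
        })
      init <- if (key$seed_fraction > 0) {
        seed_state(key$seed_fraction, key$m0_M,
                   stock_mass_conc = seed_template$stock_mass_conc,
                   mean_seed_length = seed_template$mean_seed_length)
      } else NULL
      list(m0 = key$m0_M, seed_fraction = key$seed_fraction,
           times = times, init = init, traces = traces)
    })
}

## Mean squared residual between simulated normalised fibril mass and the
## observed mass fractions, pooled over all points of all traces.
.kinetic_objective <- function(conditions, model) {
  function(params) {
    sse <- 0; npt <- 0L
    for (cond in conditions) {
      m_total <- if (is.null(cond$init)) cond$m0 else cond$init$m_total
      traj <- tryCatch(
        simulate_assembly(params, model, m_total = m_total,
                          times = cond$times, initial = cond$init),
        amylokin_solver_failure = function(e) NULL)
      if (is.null(traj)) return(1e6)
      M0 <- if (is.null(cond$init)) 0 else cond$init$M_fib
      pred <- (traj$Mfib_M - M0) / (m_total - M0)
      for (tr in cond$traces) {
        r <- tr$obs - pred[tr$idx]
        sse <- sse + sum(r^2)
        npt <- npt + length(r)
      }
    }
    sse / npt
  }
}

## Basin hopping: descent over local Nelder-Mead optimisations started from
## log-space Gaussian perturbations (SD 1) of the incumbent, followed by a
## BFGS polish of the best basin.
.basin_hop <- function(obj, start, n_hops, polish = TRUE) {
  local_fit <- function(theta) {
    if (length(theta) == 1L) {
      optim(theta, obj, method = "Brent", lower = theta - 8, upper = theta + 8)
    } else {
      optim(theta, obj, method = "Nelder-Mead",
            control = list(maxit = 600, reltol = 1e-12))
    }
  }
  best <- local_fit(start)
  for (hop in seq_len(n_hops)) {
    cand <- tryCatch(local_fit(best$par + rnorm(length(start), 0, 1)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value) best <- cand
  }
  if (polish && length(start) > 1L) {
    pol <- tryCatch(
      optim(best$par, obj, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) best <- pol
  }
  best
}

## Heuristic log-space starting centres for the free parameters, from the
## apparent half times of the data; refined by a coarse log-grid search.
.start_grid <- function(free, conditions, base, model, obj) {
  m_bar <- mean(vapply(conditions, function(c) c$m0, 0))
  t50s <- vapply(conditions, function(cond) {
    obs <- cond$traces[[1]]$obs
    t50 <- .t50_crossing(cond$times[cond$traces[[1]]$idx], obs)
    if (is.na(t50)) max(cond$times) else t50
  }, 0)
  kappa <- 5 / stats::quantile(t50s, 0.5, names = FALSE)
  centre <- vapply(free, function(nm) {
    switch(nm,
           k_plus_k_n = log(kappa^2 / (2 * base$k_plus * m_bar^base$n_c) * 1e-2),
           k_plus_k_2 = log(kappa^2 / (2 * base$k_plus * m_bar^(base$n_2 + 1))),
           K_M = log(m_bar^base$n_2),
           k_plus = log(base$k_plus),
           k_minus = log(kappa * 1e-3))
  }, 0)
  offsets <- if (length(free) <= 3) c(-4.6, 0, 4.6) else c(-2.3, 0, 2.3)
  grid <- as.matrix(expand.grid(rep(list(offsets), length(free))))
  vals <- apply(grid, 1, function(off) obj(centre + off))
  centre + grid[which.min(vals), ]
}

#' Global fit of a kinetic dataset
#'
#' Minimises the pooled mean squared residual between simulated normalised
#' fibril mass and the observed mass fractions, with the same rate constants
#' shared across every trace at every concentration.  Optimisation is basin
#' hopping (default 10 hops) around a derivative-free local optimiser in
#' natural-log parameter space, then a gradient polish; results are
#' deterministic given `rng_seed`.
#'
#' @param data Normalised long-format kinetic tibble (see [normalize_traces()])
#'   with `m0_M` and, for seeded traces, `seed_fraction` metadata.
#' @param model Model id to fit.
#' @param free Free parameters, a subset of `k_plus_k_n`, `k_plus_k_2`,
#'   `K_M`, `k_plus`, `k_minus`; default [default_free()] for the model.
#'   `k_plus` may only be freed when seeded traces are present.
#' @param base A [kinetic_params()] giving values for everything not freed
#'   (reaction orders, pinned constants).  Default: all-zero rates with
#'   `k_plus = k_plus_fixed` and `n_c = n_2 = 2`.
#' @param n_c,n_2 Reaction orders used when `base` is not supplied.
#' @param n_basin_hops Number of basin hops (default 10).
#' @param rng_seed Integer seed controlling hop perturbations.
#' @param k_plus_fixed Pinned elongation rate constant (M^-1 h^-1) resolving
#'   the k_plus degeneracy of unseeded normalised data.
#' @param seed_template Fibril stock description used to build seeded initial
#'   states from `seed_fraction` metadata.
#' @param init Optional named list of starting values on the natural scale
#'   (e.g. `list(k_plus_k_n = 1e6)`), bypassing the heuristic start.
#' @return An object of class `global_fit`: spec, fitted `params`, reported
#'   `estimates` (combined constants with units), `objective` (mean squared
#'   residual), per-trace `residuals`, `converged`.
#' @export
fit_global <- function(data, model = "PEMS", free = NULL, base = NULL,
                       n_c = 2L, n_2 = 2L, n_basin_hops = 10L, rng_seed = 1L,
                       k_plus_fixed = 1e6,
                       seed_template = .seed_template_default,
                       init = NULL) {
  model <- model_id(model)
  free <- free %||% default_free(model)
  if (!all(free %in% .free_param_names)) {
    abort("unknown free parameter name", class = "amylokin_invalid_input")
  }
  conditions <- .prep_conditions(data, seed_template)
  if (length(conditions) == 0) {
    abort("no usable traces (all non-sigmoidal?)", class = "amylokin_invalid_input")
  }
  if ("k_plus" %in% free &&
      all(vapply(conditions, function(c) c$seed_fraction, 0) == 0)) {
    abort(paste("k_plus is not identifiable from unseeded normalised data;",
                "fit combined constants instead or provide seeded traces"),
          class = "amylokin_not_identifiable")
  }
  base <- base %||% kinetic_params(k_n = 0, k_plus = k_plus_fixed, k_2 = 0,
                                   K_M = if (model == "PEMS") 1 else Inf,
                                   k_minus = 0, n_c = n_c, n_2 = n_2)
  obj <- function(theta) {
    p <- tryCatch(.theta_to_params(theta, free, base),
                  error = function(e) NULL)
    if (is.null(p)) return(1e6)
    .kinetic_objective(conditions, model)(p)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)

  start <- if (!is.null(init)) {
    log(unlist(init)[free])
  } else {
    .start_grid(free, conditions, base, model, obj)
  }
  best <- .basin_hop(obj, start, n_basin_hops)
  params <- .theta_to_params(best$par, free, base)

  fitted_curves <- .predicted_curves(conditions, params, model)
  res <- .per_trace_residuals(conditions, params, model)

  structure(list(
    spec = list(model = model, free = free, n_basin_hops = n_basin_hops,
                rng_seed = rng_seed, k_plus_fixed = k_plus_fixed,
                fixed = list(n_c = base$n_c, n_2 = base$n_2)),
    params = params,
    estimates = .report_estimates(params, free),
    objective = best$value,
    residuals = res,
    fitted_curves = fitted_curves,
    n_traces = length(unique(data$well)),
    converged = is.finite(best$value) && best$value < 1e6,
    data = data
  ), class = "global_fit")
}

.report_estimates <- function(params, free) {
  all <- tibble(
    parameter = c("k_plus_k_n", "k_plus_k_2", "sqrt_K_M", "k_plus", "k_minus"),
    value = c(params$k_plus * params$k_n, params$k_plus * params$k_2,
              sqrt(params$K_M), params$k_plus, params$k_minus),
    unit = c(sprintf("M^%d h^-2", -params$n_c),
             sprintf("M^%d h^-2", -params$n_2 - 1L),
             "M", "M^-1 h^-1", "h^-1")
  )
  keep <- c(k_plus_k_n = "k_plus_k_n", k_plus_k_2 = "k_plus_k_2",
            K_M = "sqrt_K_M", k_plus = "k_plus", k_minus = "k_minus")[free]
  dplyr::filter(all, .data$parameter %in% keep)
}

.predicted_curves <- function(conditions, params, model) {
  purrr::map(conditions, function(cond) {
    m_total <- if (is.null(cond$init)) cond$m0 else cond$init$m_total
    traj <- simulate_assembly(params, model, m_total = m_total,
                              times = cond$times, initial = cond$init)
    M0 <- if (is.null(cond$init)) 0 else cond$init$M_fib
    tibble(m0_M = cond$m0, seed_fraction = cond$seed_fraction,
           time_h = cond$times,
           predicted = (traj$Mfib_M - M0) / (m_total - M0))
  }) |> purrr::list_rbind()
}

.per_trace_residuals <- function(conditions, params, model) {
  purrr::map(conditions, function(cond) {
    m_total <- if (is.null(cond$init)) cond$m0 else cond$init$m_total
    traj <- simulate_assembly(params, model, m_total = m_total,
                              times = cond$times, initial = cond$init)
    M0 <- if (is.null(cond$init)) 0 else cond$init$M_fib
    pred <- (traj$Mfib_M - M0) / (m_total - M0)
    purrr::map(cond$traces, function(tr) tr$obs - pred[tr$idx])
  }) |> purrr::list_flatten()
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit>  model %s, %d traces, objective (MSE) = %.4g%s\n",
              x$spec$model, x$n_traces, x$objective,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.global_fit <- function(x, ...) x$estimates

#' @export
glance.global_fit <- function(x, ...) {
  tibble(model = x$spec$model, objective = x$objective,
         n_traces = x$n_traces, n_free = length(x$spec$free),
         converged = x$converged, rng_seed = x$spec$rng_seed)
}

#' @export
autoplot.global_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$mass_fraction,
                                  group = .data$well,
                                  colour = factor(.data$m0_M * 1e6))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(data = object$fitted_curves,
                       ggplot2::aes(y = .data$predicted,
                                    group = interaction(.data$m0_M,
                                                        .data$seed_fraction)),
                       linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "relative fibril mass",
                  colour = expression(m[0] ~ (mu * M)),
                  title = sprintf("%s global fit, MSE = %.3g",
                                  object$spec$model, object$objective))
}

#' Rank nested kinetic models on one dataset
#'
#' Fits each candidate model with its default free parameters and an identical
#' hop budget, and ranks by objective.  Ties (objectives within `tie_tol`
#' relative) are broken toward the model with fewer free parameters.  The
#' default tie band is wide (50 %) on purpose: genuine mechanistic misfit
#' inflates the objective by an order of magnitude, whereas sub-50 %
#' differences are within the systematic floor left by per-curve window
#' normalisation, which more flexible models partially absorb.
#'
#' @inheritParams fit_global
#' @param models Character vector of model ids (>= 2).
#' @param tie_tol Relative objective difference treated as a tie.
#' @return A tibble (one row per model, ranked) with attribute `"best"` giving
#'   the selected model id and `"fits"` the underlying `global_fit` objects.
#' @export
compare_models <- function(data, models = c("PE", "PEF", "PES", "PEMS"),
                           n_basin_hops = 10L, rng_seed = 1L, tie_tol = 0.5,
                           ...) {
  if (length(models) < 1) {
    abort("supply at least one model id", class = "amylokin_invalid_input")
  }
  fits <- purrr::map(models, function(m) {
    fit_global(data, model = m, n_basin_hops = n_basin_hops,
               rng_seed = rng_seed, ...)
  })
  tab <- purrr::map(fits, glance) |> purrr::list_rbind() |>
    dplyr::arrange(.data$objective)
  contenders <- tab$objective <= min(tab$objective) * (1 + tie_tol)
  best <- tab$model[contenders][which.min(tab$n_free[contenders])]
  tab$rank <- seq_len(nrow(tab))
  tab$selected <- tab$model == best
  structure(tab, best = best, fits = setNames(fits, models))
}

#' Seeded-regime fit
#'
#' Identical objective machinery to [fit_global()] with initial conditions
#' built from each trace's seed metadata, and only the declared subset free;
#' all other constants are pinned at `base`.  With 30 % (v/v) seeds the
#' reaction is elongation-dominated and `free = "k_plus"` is identifiable.
#'
#' @inheritParams fit_global
#' @param base Reference [kinetic_params()] providing every pinned constant.
#' @export
fit_seeded <- function(data, base, free, n_basin_hops = 10L, rng_seed = 1L,
                       seed_template = .seed_template_default, ...) {
  fit_global(data, model = "PEMS", free = free, base = base,
             n_basin_hops = n_basin_hops, rng_seed = rng_seed,
             seed_template = seed_template, ...)
}

#' Single-rate-constant dissection of a modulator dose series
#'
#' For each dose, every parameter is pinned at the zero-dose reference and the
#' one declared rate constant is scaled by a free factor `alpha`; the reported
#' `K_app_over_K = alpha` is the fold-change of that constant at that dose.
#' Doses whose curves never grow within the observation window are reported
#' as upper bounds (`alpha_is_upper_bound`), using the largest alpha whose
#' predicted curve stays below the detection level.
#'
#' @param data Normalised kinetic tibble with a `dose` column (as produced by
#'   [generate_modulator_dataset()] + [normalize_traces()]), or a named list
#'   of tibbles keyed by dose.
#' @param reference A `global_fit` on the zero-dose dataset, or a
#'   [kinetic_params()] object.
#' @param varied One of `"k_plus_k_n"`, `"k_plus_k_2"`, `"k_plus"`.
#' @param model Model id (default `"PEMS"`).
#' @param seed_template As in [fit_global()].
#' @return An object of class `modulator_fit`: tibble of per-dose ratios plus
#'   the reference.  `tidy()` returns the ratio table.
#' @export
fit_modulator <- function(data, reference, varied = c("k_plus_k_n",
                                                      "k_plus_k_2", "k_plus"),
                          model = "PEMS",
                          seed_template = .seed_template_default) {
  varied <- match.arg(varied)
  ref_params <- if (inherits(reference, "global_fit")) reference$params
                else reference
  stopifnot(inherits(ref_params, "kinetic_params"))
  datasets <- if (is.data.frame(data)) split(data, data$dose) else data

  rows <- purrr::imap(datasets, function(d, dose) {
    grew <- !all(is.na(d$mass_fraction))
    if (!grew) {
      ## no growth in window: alpha bounded above by the value that would
      ## just reach the 0.5 level at t_max
      ub <- .alpha_upper_bound(d, ref_params, varied, model, seed_template)
      return(tibble(dose = dose, K_app_over_K = ub, objective = NA_real_,
                    alpha_is_upper_bound = TRUE))
    }
    conditions <- .prep_conditions(d, seed_template)
    obj <- function(la) {
      p <- scale_params(ref_params, varied, exp(la))
      .kinetic_objective(conditions, model)(p)
    }
    opt <- optimize(obj, lower = log(1e-8), upper = log(1e8), tol = 1e-8)
    tibble(dose = dose, K_app_over_K = exp(opt$minimum),
           objective = opt$objective, alpha_is_upper_bound = FALSE)
  }) |> purrr::list_rbind()

  structure(list(table = rows, varied = varied, reference = ref_params,
                 model = model),
            class = "modulator_fit")
}

## Largest alpha whose predicted curve stays below half-completion in-window.
.alpha_upper_bound <- function(d, ref_params, varied, model, seed_template) {
  times <- sort(unique(d$time_h))
  m0 <- d$m0_M[1]
  f <- function(la) {
    p <- scale_params(ref_params, varied, exp(la))
    traj <- simulate_assembly(p, model, m_total = m0, times = times)
    max(traj$mass_fraction) - 0.5
  }
  root <- tryCatch(stats::uniroot(f, c(log(1e-8), log(1)))$root,
                   error = function(e) log(1e-8))
  exp(root)
}

#' @export
print.modulator_fit <- function(x, ...) {
  cat(sprintf("<modulator_fit>  varied = %s (%s model)\n", x$varied, x$model))
  print(x$table)
  invisible(x)
}

#' @export
tidy.modulator_fit <- function(x, ...) {
  dplyr::mutate(x$table, varied = x$varied)
}

#' @export
autoplot.modulator_fit <- function(object, ...) {
  tab <- dplyr::mutate(object$table, dose = as.numeric(.data$dose))
  ggplot2::ggplot(tab, ggplot2::aes(.data$dose, .data$K_app_over_K)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "molar ratio (compound : peptide)",
                  y = expression(K[app] / K),
                  title = sprintf("fold-change of %s", object$varied))
}
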