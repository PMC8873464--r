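## Synthetic plate-reader data with recorded ground truth.
##
## Every generator returns a long-format kinetic tibble (the same dialect the
## trace-processing functions read) and attaches a `truth` attribute carrying
## the generating parameters, so parameter-recovery tests need no hidden
## state.  All randomness flows through R's RNG; callers seed it (directly or
## via the design's `rng_seed`) for byte-reproducible datasets.

#' Default generating parameters for the synthetic plate
#'
#' A multi-step secondary-nucleation (PEMS) parameter set calibrated so that
#' an unseeded 10 uM reaction has a half time of about 15 h, secondary
#' nucleation outpaces primary nucleation by many orders of magnitude
#' (k_2/k_n of order 5e8 M^-1), and half-saturation of secondary nucleation
#' falls inside the assayed 8-32 uM range so the highest concentrations
#' deviate from the unsaturated power law.
#'
#' @return A [kinetic_params()] object.
#' @export
default_true_params <- function() {
  kinetic_params(k_n = .default_kn, k_plus = 1e6, k_2 = .default_kn * 5e8,
                 K_M = (10e-6)^2, n_c = 2L, n_2 = 2L)
}

#' Synthetic plate design
#'
#' Mirrors a concentration-series ThT experiment: an 8-32 uM monomer series,
#' the standard seed-dose grid, 3 technical replicates, a 0-42 h observation
#' window sampled every 0.2 h, and additive Gaussian noise of 2 % of the
#' fluorescence amplitude.
#'
#' @param m0_list Initial monomer concentrations (M).
#' @param seed_fractions Seed doses (v/v fractions).
#' @param replicates Technical replicates per condition.
#' @param dt,t_max Sampling interval and window (h).
#' @param noise_sd Gaussian noise SD as a fraction of the amplitude.
#' @param baseline,amplitude Fluorescence offset and span (a.u.).
#' @param rng_seed Integer seed used by the generators.
#' @return A list of class `plate_design`.
#' @export
plate_design <- function(m0_list = c(8, 12, 16, 20, 32) * 1e-6,
                         seed_fractions = c(0, 0.00063, 0.0025, 0.01, 0.025,
                                            0.05, 0.10, 0.20, 0.30),
                         replicates = 3L, dt = 0.2, t_max = 42,
                         noise_sd = 0.02, baseline = 50, amplitude = 200,
                         rng_seed = 1L) {
  stopifnot(noise_sd >= 0, replicates >= 1, dt > 0, t_max > dt, amplitude > 0)
  structure(list(m0_list = m0_list, seed_fractions = seed_fractions,
                 replicates = as.integer(replicates), dt = dt, t_max = t_max,
                 noise_sd = noise_sd, baseline = baseline,
                 amplitude = amplitude, rng_seed = as.integer(rng_seed)),
            class = "plate_design")
}

#' Fluorescence trace from a simulated trajectory
#'
#' ThT fluorescence is modelled as proportional to fibril mass:
#' `F(t) = baseline + amplitude * M_fib(t)/m_total + eps`,
#' `eps ~ N(0, (noise_sd * amplitude)^2)` (homoscedastic per trace).
#'
#' @param traj An `assembly_trajectory`.
#' @param baseline,amplitude,noise_sd See [plate_design()].
#' @return A tibble with `time_h` and `fluorescence`.
#' @export
fluorescence_from_mass <- function(traj, baseline = 50, amplitude = 200,
                                   noise_sd = 0.02) {
  stopifnot(amplitude > 0)
  n <- nrow(traj)
  eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd * amplitude) else 0
  tibble(time_h = traj$time_h,
         fluorescence = baseline + amplitude * traj$mass_fraction + eps)
}

## One well: simulate, add fluorescence, attach metadata.
.simulate_well <- function(params, model, m0, seed_fraction, seed_template,
                           design, well, replicate, compound = "DMSO",
                           molar_ratio = 0) {
  times <- seq(0, design$t_max, by = design$dt)
  init <- if (seed_fraction > 0) {
    seed_state(seed_fraction, m0,
               stock_mass_conc = seed_template$stock_mass_conc,
               mean_seed_length = seed_template$mean_seed_length)
  } else NULL
  traj <- simulate_assembly(params, model,
                            m_total = if (is.null(init)) m0 else NULL,
                            times = times, initial = init)
  fl <- fluorescence_from_mass(traj, design$baseline, design$amplitude,
                               design$noise_sd)
  dplyr::mutate(fl, well = well, m0_M = m0, seed_fraction = seed_fraction,
                compound = compound, molar_ratio = molar_ratio,
                replicate = replicate)
}

.seed_template_default <- list(stock_mass_conc = 32e-6, mean_seed_length = 500)

#' Generate an unseeded concentration-series dataset
#'
#' One trace per (m0, replicate) over the design's concentration series, as
#' in a concentration-dependent aggregation experiment.
#'
#' @param params Generating [kinetic_params()]; default [default_true_params()].
#' @param model Generating model id.
#' @param design A [plate_design()].
#' @return A long-format kinetic tibble with a `truth` attribute (list with
#'   `params`, `model`, `design`).
#' @export
generate_unseeded_dataset <- function(params = default_true_params(),
                                      model = "PEMS",
                                      design = plate_design()) {
  set.seed(design$rng_seed)
  grid <- tidyr::expand_grid(m0 = design$m0_list,
                             replicate = seq_len(design$replicates))
  out <- purrr::pmap(grid, function(m0, replicate) {
    .simulate_well(params, model, m0, 0, .seed_template_default, design,
                   well = sprintf("m%03.0f_r%d", m0 * 1e6 * 10, replicate),
                   replicate = replicate)
  }) |> purrr::list_rbind()
  structure(out, truth = list(params = params, model = model, design = design))
}

#' Generate a seeded-growth dataset
#'
#' One trace per (seed fraction, replicate) at a single monomer concentration,
#' as in a self-seeding experiment.  At a 30 % (v/v) dose the lag phase is
#' abolished: fibril mass is already growing at the first sampled time point.
#'
#' @inheritParams generate_unseeded_dataset
#' @param m0 Monomer concentration (M); default 10 uM.
#' @param seed_template Fibril stock description: `stock_mass_conc` (M) and
#'   `mean_seed_length` (monomers per seed).
#' @export
generate_seeded_dataset <- function(params = default_true_params(),
                                    model = "PEMS",
                                    design = plate_design(),
                                    m0 = 10e-6,
                                    seed_template = .seed_template_default) {
  set.seed(design$rng_seed)
  grid <- tidyr::expand_grid(frac = design$seed_fractions,
                             replicate = seq_len(design$replicates))
  out <- purrr::pmap(grid, function(frac, replicate) {
    .simulate_well(params, model, m0, frac, seed_template, design,
                   well = sprintf("s%05.0f_r%d", frac * 1e5, replicate),
                   replicate = replicate)
  }) |> purrr::list_rbind()
  structure(out, truth = list(params = params, model = model, design = design,
                              m0 = m0, seed_template = seed_template))
}

#' Generate a modulator dose series
#'
#' For each dose, exactly one rate constant (or combined constant) of the
#' reference parameter set is multiplied by the dose's factor `alpha`; this is
#' the single-rate-constant regime a mechanism-dissection fit should recover.
#'
#' @inheritParams generate_seeded_dataset
#' @param varied One of `"k_plus_k_n"`, `"k_plus_k_2"`, `"k_plus"`.
#' @param alphas Named numeric vector: names are molar-ratio labels, values
#'   the scale factors (1 = DMSO reference).
#' @param seed_fraction Seed dose shared by all traces (0 for unseeded).
#' @return A kinetic tibble with a `dose` column (molar ratio label) and a
#'   `truth` attribute recording `alphas` and `varied`.
#' @export
generate_modulator_dataset <- function(params = default_true_params(),
                                       model = "PEMS",
                                       design = plate_design(),
                                       varied = c("k_plus_k_n", "k_plus_k_2",
                                                  "k_plus"),
                                       alphas = c(`0` = 1, `3` = 0.5, `7` = 0.1),
                                       m0 = 10e-6, seed_fraction = 0,
                                       seed_template = .seed_template_default) {
  varied <- match.arg(varied)
  set.seed(design$rng_seed)
  out <- purrr::imap(alphas, function(alpha, dose) {
    p <- scale_params(params, varied, alpha)
    grid <- tibble(replicate = seq_len(design$replicates))
    purrr::pmap(grid, function(replicate) {
      .simulate_well(p, model, m0, seed_fraction, seed_template, design,
                     well = sprintf("d%s_r%d", dose, replicate),
                     replicate = replicate, compound = "modulator",
                     molar_ratio = as.numeric(dose))
    }) |> purrr::list_rbind() |> dplyr::mutate(dose = dose)
  }) |> purrr::list_rbind()
  structure(out, truth = list(params = params, model = model, design = design,
                              varied = varied, alphas = alphas,
                              m0 = m0, seed_fraction = seed_fraction,
                              seed_template = seed_template))
}

#' Scale one (combined) rate constant of a parameter set
#'
#' `k_plus_k_n` scales `k_n`, `k_plus_k_2` scales `k_2` (with `k_plus` fixed,
#' scaling the microscopic constant scales the product), and `k_plus` scales
#' the elongation rate constant itself.
#'
#' @param params A [kinetic_params()] object.
#' @param which One of `"k_plus_k_n"`, `"k_plus_k_2"`, `"k_plus"`.
#' @param alpha Positive scale factor.
#' @return A new `kinetic_params` object.
#' @export
scale_params <- function(params, which, alpha) {
  stopifnot(alpha > 0)
  p <- unclass(params)
  switch(which,
         k_plus_k_n = p$k_n <- p$k_n * alpha,
         k_plus_k_2 = p$k_2 <- p$k_2 * alpha,
         k_plus = p$k_plus <- p$k_plus * alpha,
         abort("unknown parameter name", class = "amylokin_invalid_input"))
  do.call(kinetic_params, p)
}

#' Generate a fluorescence-quenching titration
#'
#' In `"K_SV"` mode intensities follow the linear Stern-Volmer relation
#' `F0/F = 1 + K_SV * Q`; in `"K_b"` mode the quenched fraction follows the
#' log-log binding form `(F0 - F)/F = K_b * Q^n`.
#'
#' @param K Constant: K_SV (M^-1) in `"K_SV"` mode, K_b (M^-n) in `"K_b"` mode.
#' @param mode Which generating relation to use.
#' @param n_sites Binding-site number (only used in `"K_b"` mode).
#' @param F0 Unquenched intensity (a.u.).
#' @param Q Quencher concentrations (M), including 0.
#' @param noise_sd Relative Gaussian noise on F.
#' @return A tibble `(Q_M, F)` with a `truth` attribute.
#' @export
generate_quench_titration <- function(K = 1.34e4, mode = c("K_SV", "K_b"),
                                      n_sites = 1, F0 = 1e6,
                                      Q = c(0, seq(10e-6, 150e-6, by = 20e-6)),
                                      noise_sd = 0) {
  mode <- match.arg(mode)
  if (length(Q) < 2) {
    abort("titration needs quencher points beyond Q = 0 (degenerate grid)",
          class = "amylokin_invalid_input")
  }
  f <- switch(mode,
              K_SV = F0 / (1 + K * Q),
              K_b = F0 / (1 + K * Q^n_sites))
  if (noise_sd > 0) f <- f * (1 + rnorm(length(f), 0, noise_sd))
  structure(tibble(Q_M = Q, F = f),
            truth = list(K = K, mode = mode, n_sites = n_sites, F0 = F0,
                         noise_sd = noise_sd))
}

#' Generate a steady-state SPR isotherm
#'
#' Responses follow the 1:1 binding isotherm `R = R_max * C / (K_d + C)`.
#'
#' @param K_d Dissociation constant (M).
#' @param R_max Saturation response (RU).
#' @param conc Analyte concentrations (M).
#' @param noise_sd Absolute Gaussian noise on the response (RU).
#' @return A tibble `(conc_M, response_RU)` with a `truth` attribute.
#' @export
generate_spr_isotherm <- function(K_d = 240e-6, R_max = 50,
                                  conc = c(7.5, 15, 30, 60, 120, 240, 480,
                                           960) * 1e-6,
                                  noise_sd = 0) {
  r <- R_max * conc / (K_d + conc)
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  structure(tibble(conc_M = conc, response_RU = r),
            truth = list(K_d = K_d, R_max = R_max, noise_sd = noise_sd))
}

#' Generate a CID dissociation curve
#'
#' Bound fraction versus trap voltage follows a descending logistic with the
#' given midpoint.
#'
#' @param midpoint_V Dissociation midpoint (V).
#' @param slope Logistic steepness (V^-1).
#' @param upper,lower Plateau bound fractions.
#' @param voltage Trap voltages (V).
#' @param noise_sd Absolute Gaussian noise on the bound fraction.
#' @return A tibble `(trap_V, bound_fraction)` with a `truth` attribute.
#' @export
generate_cid_curve <- function(midpoint_V = 16.5, slope = 1.2, upper = 1,
                               lower = 0, voltage = seq(5, 35, by = 1),
                               noise_sd = 0) {
  f <- lower + (upper - lower) / (1 + exp(slope * (voltage - midpoint_V)))
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  structure(tibble(trap_V = voltage, bound_fraction = f),
            truth = list(midpoint_V = midpoint_V, slope = slope,
                         upper = upper, lower = lower, noise_sd = noise_sd))
}

## Calibrated once so that the default PEMS plate has t50(10 uM) = 15 h
## (root-finding on the simulated half time) and frozen; see methods vignette.
.default_kn <- 0.6497
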