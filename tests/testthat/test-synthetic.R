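test_that("fluorescence generation is proportional, reproducible, and quiet at zero noise", {
  p <- kinetic_params(k_n = 0, k_plus = 1e6)
  traj <- simulate_assembly(p, "PE", m_total = 1e-5, times = seq(0, 10, 0.5))
  fl <- fluorescence_from_mass(traj, baseline = 50, amplitude = 200, noise_sd = 0)
  expect_true(all(fl$fluorescence == 50))  # zero trajectory -> constant baseline

  p2 <- truth_params()
  traj2 <- simulate_assembly(p2, "PEMS", m_total = 1e-5, times = seq(0, 42, 0.2))
  set.seed(11)
  a <- fluorescence_from_mass(traj2, noise_sd = 0.02)
  set.seed(11)
  b <- fluorescence_from_mass(traj2, noise_sd = 0.02)
  expect_identical(a, b)  # same RNG state -> bit-identical trace

  # noiseless fluorescence round-trips through normalisation to fibril mass
  nd <- normalize_traces(
    dplyr::mutate(fluorescence_from_mass(traj2, noise_sd = 0),
                  well = "w", m0_M = 1e-5, seed_fraction = 0))
  expect_lt(max(abs(nd$mass_fraction - traj2$mass_fraction)), 0.01)
})

test_that("unseeded datasets look like concentration-dependent sigmoids", {
  d <- generate_unseeded_dataset(design = plate_design(noise_sd = 0,
                                                       replicates = 1))
  expect_s3_class(d, "tbl_df")
  expect_true(!is.null(attr(d, "truth")$params))

  nd <- normalize_traces(d)
  t50 <- compute_t50(nd)
  ord <- order(t50$m0_M)
  expect_true(all(diff(t50$t50_h[ord]) < 0))  # t50 falls as m0 rises

  # sigmoidal: near-complete growth, and a quiet first decile
  shape <- nd |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      mx = max(.data$mass_fraction),
      early = mean(.data$mass_fraction[.data$time_h <= max(.data$time_h) * 0.1]))
  expect_true(all(shape$mx > 0.9))
  expect_true(all(shape$early < 0.05))
})

test_that("replicates are identical at zero noise and k_n = 0 gives flat plates", {
  d <- generate_unseeded_dataset(design = plate_design(
    m0_list = 10e-6, noise_sd = 0, replicates = 3))
  by_rep <- split(d$fluorescence, d$replicate)
  expect_identical(by_rep[[1]], by_rep[[2]])
  expect_identical(by_rep[[1]], by_rep[[3]])

  p0 <- kinetic_params(k_n = 0, k_plus = 1e6, k_2 = 3e8, K_M = 1e-10)
  d0 <- generate_unseeded_dataset(params = p0, design = plate_design(
    m0_list = 10e-6, noise_sd = 0, replicates = 1))
  expect_true(all(d0$fluorescence == d0$fluorescence[1]))
})

test_that("identical design seeds give byte-identical datasets", {
  d1 <- generate_unseeded_dataset(design = plate_design(rng_seed = 3))
  d2 <- generate_unseeded_dataset(design = plate_design(rng_seed = 3))
  expect_identical(d1, d2)
})

test_that("a zero seed fraction reduces seeded generation to the unseeded case", {
  des <- plate_design(m0_list = 10e-6, seed_fractions = 0, replicates = 2,
                      rng_seed = 8)
  a <- generate_seeded_dataset(design = des, m0 = 10e-6)
  b <- generate_unseeded_dataset(design = des)
  expect_equal(a$fluorescence, b$fluorescence)
  expect_equal(a$time_h, b$time_h)
})

test_that("seeding monotonically shortens the half time and 30 % seeds abolish the lag", {
  des <- plate_design(noise_sd = 0, replicates = 1)
  d <- generate_seeded_dataset(design = des)
  t50 <- compute_t50(normalize_traces(d))
  ord <- order(t50$seed_fraction)
  expect_true(all(diff(t50$t50_h[ord]) < 0))

  # fibril mass is already present and growing at the first sampled point
  p <- truth_params()
  traj <- simulate_assembly(p, "PEMS", times = seq(0, 42, 0.2),
                            initial = seed_state(0.30, 10e-6))
  expect_gt(traj$mass_fraction[2], 0.05)
  expect_gt(traj$Mfib_M[2], traj$Mfib_M[1])
})

test_that("modulator series shift half times in the dosed direction", {
  des <- plate_design(m0_list = 10e-6, noise_sd = 0, replicates = 1)
  d <- generate_modulator_dataset(design = des, varied = "k_plus_k_n",
                                  alphas = c(`0` = 1, `3` = 0.5, `7` = 0.1))
  expect_equal(attr(d, "truth")$alphas, c(`0` = 1, `3` = 0.5, `7` = 0.1))
  t50 <- compute_t50(normalize_traces(d))
  ord <- order(as.numeric(t50$molar_ratio))
  expect_true(all(diff(t50$t50_h[ord]) > 0))  # inhibitor: t50 rises with dose

  acc <- generate_modulator_dataset(design = des, varied = "k_plus_k_n",
                                    alphas = c(`0` = 1, `1` = 10))
  t50a <- compute_t50(normalize_traces(acc))
  expect_lt(t50a$t50_h[t50a$molar_ratio == 1],
            t50a$t50_h[t50a$molar_ratio == 0])  # accelerator direction

  # an unscaled dose reproduces the reference kinetics
  ref <- generate_unseeded_dataset(design = des)
  t50r <- compute_t50(normalize_traces(ref))
  expect_equal(t50$t50_h[t50$molar_ratio == 0], t50r$t50_h, tolerance = 1e-6)
})

test_that("quench titrations round-trip and degenerate grids are rejected", {
  t <- generate_quench_titration(K = 1.34e4, mode = "K_SV", noise_sd = 0)
  expect_equal(fit_stern_volmer(t)$K_SV, 1.34e4, tolerance = 1e-10)
  expect_error(generate_quench_titration(Q = 0),
               class = "amylokin_invalid_input")
  set.seed(21); a <- generate_quench_titration(noise_sd = 0.01)
  set.seed(21); b <- generate_quench_titration(noise_sd = 0.01)
  expect_identical(a, b)
})

test_that("every generator records its generating truth", {
  expect_named(attr(generate_spr_isotherm(), "truth"),
               c("K_d", "R_max", "noise_sd"))
  expect_named(attr(generate_cid_curve(), "truth"),
               c("midpoint_V", "slope", "upper", "lower", "noise_sd"))
  expect_named(attr(generate_quench_titration(), "truth"),
               c("K", "mode", "n_sites", "F0", "noise_sd"))
  d <- generate_seeded_dataset(design = plate_design(
    seed_fractions = 0.025, replicates = 1, noise_sd = 0))
  expect_true(all(c("params", "model", "design") %in% names(attr(d, "truth"))))
})
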