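# Global-fit machinery.  Datasets are kept small (one replicate, noiseless
# where the check allows) so the whole file runs in a couple of minutes; the
# full replicated-recovery study lives in the acceptance suite.

test_that("a noiseless dataset initialised at truth is fitted to machine residuals", {
  truth <- truth_params()
  d <- generate_unseeded_dataset(design = plate_design(noise_sd = 0,
                                                       replicates = 1))
  nd <- normalize_traces(d)
  fit <- fit_global(nd, "PEMS", n_basin_hops = 0,
                    init = list(k_plus_k_n = truth$k_n,
                                k_plus_k_2 = truth$k_2,
                                K_M = truth$K_M))
  # residual floor is set by the window normalisation, not the optimizer
  expect_lt(fit$objective, 1e-5)
  est <- setNames(fit$estimates$value, fit$estimates$parameter)
  expect_equal(est[["k_plus_k_n"]], truth$k_plus * truth$k_n, tolerance = 0.05)
  expect_equal(est[["k_plus_k_2"]], truth$k_plus * truth$k_2, tolerance = 0.02)
  expect_equal(est[["sqrt_K_M"]], sqrt(truth$K_M), tolerance = 0.02)
})

test_that("noisy combined constants are recovered within 20 % from a cold start", {
  truth <- truth_params()
  d <- generate_unseeded_dataset(design = plate_design(rng_seed = 42))
  fit <- fit_global(normalize_traces(d), "PEMS", rng_seed = 42)
  est <- setNames(fit$estimates$value, fit$estimates$parameter)
  expect_lt(abs(log(est[["k_plus_k_n"]] / (truth$k_plus * truth$k_n))), log(1.2))
  expect_lt(abs(log(est[["k_plus_k_2"]] / (truth$k_plus * truth$k_2))), log(1.2))
  expect_lt(abs(log(est[["sqrt_K_M"]] / sqrt(truth$K_M))), log(1.2))
  expect_true(fit$converged)
})

test_that("fits are deterministic given the RNG seed", {
  d <- generate_unseeded_dataset(design = plate_design(
    m0_list = c(10, 20) * 1e-6, replicates = 1, rng_seed = 5))
  nd <- normalize_traces(d)
  f1 <- fit_global(nd, "PEMS", n_basin_hops = 3, rng_seed = 9)
  f2 <- fit_global(nd, "PEMS", n_basin_hops = 3, rng_seed = 9)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("secondary-nucleation data force a large misfit on the primary-only model", {
  des <- plate_design(replicates = 1, rng_seed = 13)
  d_pems <- generate_unseeded_dataset(design = des)
  fit_bad <- fit_global(normalize_traces(d_pems), "PE", rng_seed = 13)

  p_pe <- kinetic_params(k_n = 50, k_plus = 1e6)
  d_pe <- generate_unseeded_dataset(params = p_pe, model = "PE", design = des)
  fit_good <- fit_global(normalize_traces(d_pe), "PE", rng_seed = 13)

  expect_gt(fit_bad$objective / fit_good$objective, 10)
})

test_that("model comparison selects the generating model, with parsimony on ties", {
  des <- plate_design(replicates = 1, rng_seed = 17)
  p_pe <- kinetic_params(k_n = 50, k_plus = 1e6)
  d_pe <- generate_unseeded_dataset(params = p_pe, model = "PE", design = des)
  cmp <- compare_models(normalize_traces(d_pe), models = c("PE", "PEMS"),
                        rng_seed = 17)
  expect_identical(attr(cmp, "best"), "PE")  # nested models tie; fewest free wins

  expect_error(compare_models(normalize_traces(d_pe), models = character(0)),
               class = "amylokin_invalid_input")
})

test_that("freeing k_plus without seeded traces is refused as unidentifiable", {
  d <- generate_unseeded_dataset(design = plate_design(
    m0_list = 10e-6, replicates = 1, noise_sd = 0))
  expect_error(
    fit_global(normalize_traces(d), "PEMS",
               free = c("k_plus", "k_plus_k_2", "K_M")),
    class = "amylokin_not_identifiable")
})

test_that("strongly seeded reactions identify the elongation rate constant", {
  truth <- truth_params()
  d <- generate_seeded_dataset(design = plate_design(
    seed_fractions = 0.30, noise_sd = 0, replicates = 1))
  fit <- fit_seeded(normalize_traces(d), base = truth, free = "k_plus",
                    rng_seed = 1)
  expect_equal(fit$params$k_plus, truth$k_plus, tolerance = 0.01)
})

test_that("a halved secondary-nucleation constant is recovered from 2.5 % seeded data", {
  truth <- truth_params()
  gen <- scale_params(truth, "k_plus_k_2", 0.5)
  d <- generate_seeded_dataset(params = gen, design = plate_design(
    seed_fractions = 0.025, rng_seed = 23))
  fit <- fit_seeded(normalize_traces(d), base = truth, free = "k_plus_k_2",
                    rng_seed = 23)
  expect_equal(fit$params$k_2 / truth$k_2, 0.5, tolerance = 0.2)
})

test_that("zero-seed data give the same answer through the seeded and global paths", {
  des <- plate_design(m0_list = 10e-6, seed_fractions = 0, replicates = 1,
                      rng_seed = 31)
  d <- generate_seeded_dataset(design = des)
  nd <- normalize_traces(d)
  f1 <- fit_seeded(nd, base = truth_params(), free = default_free("PEMS"),
                   rng_seed = 4)
  f2 <- fit_global(nd, "PEMS", base = truth_params(), rng_seed = 4)
  expect_equal(f1$estimates, f2$estimates)
})

test_that("modulator dissection recovers per-dose fold changes and the null dose", {
  truth <- truth_params()
  des <- plate_design(m0_list = 10e-6, rng_seed = 37)
  d <- generate_modulator_dataset(design = des, varied = "k_plus_k_n",
                                  alphas = c(`0` = 1, `7` = 0.1))
  mf <- fit_modulator(normalize_traces(d), truth, varied = "k_plus_k_n")
  a <- setNames(mf$table$K_app_over_K, mf$table$dose)
  expect_equal(a[["0"]], 1, tolerance = 0.1)
  expect_equal(a[["7"]], 0.1, tolerance = 0.2)
})

test_that("fitting the wrong single constant fits worse than the generating one", {
  truth <- truth_params()
  des <- plate_design(m0_list = 10e-6, rng_seed = 41)
  d <- generate_modulator_dataset(design = des, varied = "k_plus_k_2",
                                  alphas = c(`7` = 0.1), seed_fraction = 0.10)
  nd <- normalize_traces(d)
  matched <- fit_modulator(nd, truth, varied = "k_plus_k_2")
  mismatched <- fit_modulator(nd, truth, varied = "k_plus_k_n")
  expect_gt(min(mismatched$table$objective), 2 * min(matched$table$objective))
})
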