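test_that("rate equations vanish when monomer is exhausted", {
  p <- kinetic_params(k_n = 1e2, k_plus = 1e6, k_2 = 1e9)
  st <- list(m = 0, P = 5e-9, M_fib = 1e-5)
  d <- assembly_rates(st, p, "PES", m_total = 1e-5)
  expect_identical(unname(d["dM_fib"]), 0)
  expect_identical(unname(d["dP"]), 0)  # all nucleation terms carry m

  # fragmentation is monomer-independent and survives
  pf <- kinetic_params(k_n = 1e2, k_plus = 1e6, k_minus = 0.1)
  df <- assembly_rates(st, pf, "PEF", m_total = 1e-5)
  expect_equal(unname(df["dP"]), 0.1 * 1e-5)
})

test_that("no nucleation and no seeds means no growth", {
  p <- kinetic_params(k_n = 0, k_plus = 1e6)
  d <- assembly_rates(list(m = 1e-5, P = 0, M_fib = 0), p, "PE", 1e-5)
  expect_equal(unname(d), c(0, 0))
  traj <- simulate_assembly(p, "PE", m_total = 1e-5, times = seq(0, 42, 0.5))
  expect_true(all(traj$Mfib_M == 0))
})

test_that("zero total monomer yields an all-zero trajectory", {
  p <- kinetic_params(k_n = 10, k_plus = 1e6, k_2 = 1e9)
  traj <- simulate_assembly(p, "PES", m_total = 0, times = seq(0, 10, 0.5))
  expect_true(all(traj$Mfib_M == 0) && all(traj$P_M == 0) && all(traj$m_M == 0))
})

test_that("saturating secondary nucleation reduces to the single-step form as K_M grows", {
  st <- list(m = 8e-6, P = 2e-9, M_fib = 2e-6)
  base <- list(k_n = 1, k_plus = 1e6, k_2 = 1e9, n_c = 2L, n_2 = 2L)
  p_pes <- do.call(kinetic_params, base)
  p_pems <- do.call(kinetic_params, c(base, list(K_M = 1e12 * st$m^2)))
  d1 <- assembly_rates(st, p_pems, "PEMS", 1e-5)
  d2 <- assembly_rates(st, p_pes, "PES", 1e-5)
  expect_equal(d1, d2, tolerance = 1e-6)

  # and on whole trajectories, within 1e-5 relative on fibril mass
  times <- seq(0, 42, 0.2)
  t_pems <- simulate_assembly(p_pems, "PEMS", m_total = 1e-5, times = times)
  t_pes <- simulate_assembly(p_pes, "PES", m_total = 1e-5, times = times)
  rel <- abs(t_pems$Mfib_M - t_pes$Mfib_M) / 1e-5
  expect_lt(max(rel), 1e-5)

  # PES with k_2 = 0 is exactly PE
  p0 <- kinetic_params(k_n = 1, k_plus = 1e6, k_2 = 0)
  expect_equal(simulate_assembly(p0, "PES", m_total = 1e-5, times = times),
               simulate_assembly(p0, "PE", m_total = 1e-5, times = times),
               ignore_attr = TRUE)
})

test_that("adaptive solver matches the fixed-step RK4 oracle on random draws", {
  set.seed(401)
  for (i in 1:20) {
    p <- kinetic_params(
      k_n = 10^runif(1, -2, 1),
      k_plus = 1e6,
      k_2 = 10^runif(1, 7, 9.5),
      K_M = if (i %% 2) (10^runif(1, -6, -4.5))^2 else Inf,
      n_c = 2L, n_2 = 2L)
    model <- if (is.finite(p$K_M)) "PEMS" else "PES"
    m0 <- runif(1, 5e-6, 3e-5)
    times <- seq(0, 42, length.out = 50)
    traj <- simulate_assembly(p, model, m_total = m0, times = times)
    oracle <- rk4_trajectory(p, model, m0, times, n_steps = 1e4)
    rel <- abs(traj$Mfib_M - rk4_at(oracle, times)) / m0
    expect_lt(max(rel), 1e-4)
  }
})

test_that("trajectories conserve mass and fibril mass never decreases", {
  set.seed(402)
  times <- seq(0, 42, 0.2)
  for (i in 1:10) {
    p <- kinetic_params(k_n = 10^runif(1, -2, 1), k_plus = 1e6,
                        k_2 = 10^runif(1, 7, 9.5), K_M = (1e-5)^2)
    init <- if (i %% 2) seed_state(0.05, 1e-5) else NULL
    traj <- simulate_assembly(p, "PEMS", m_total = if (is.null(init)) 1e-5 else NULL,
                              times = times, initial = init)
    m_total <- attr(traj, "m_total")
    expect_lt(max(abs(traj$m_M + traj$Mfib_M - m_total)), 1e-6 * m_total)
    expect_true(all(diff(traj$Mfib_M) > -1e-9 * m_total))
  }
})

test_that("seeded initial states follow the v/v dose arithmetic", {
  s <- seed_state(0.10, m0 = 10e-6, stock_mass_conc = 32e-6,
                  mean_seed_length = 500)
  expect_equal(s$M_fib, 3.2e-6)
  expect_equal(s$P, 6.4e-9)
  expect_equal(s$m_total, 13.2e-6)

  expect_equal(seed_state(0.30, 10e-6)$M_fib, 9.6e-6)
  s0 <- seed_state(0, 10e-6)
  expect_equal(c(s0$m, s0$P, s0$M_fib), c(10e-6, 0, 0))
  expect_error(seed_state(1, 10e-6), class = "amylokin_invalid_input")
})

test_that("analytic half-time exponents and their regime guards", {
  expect_equal(halftime_exponent("PE", n_c = 2, regime = "primary"), -1)
  expect_equal(halftime_exponent("PES", n_2 = 2, regime = "secondary-unsaturated"), -1.5)
  expect_equal(halftime_exponent("PEMS", n_2 = 2, regime = "secondary-saturated"), -0.5)
  expect_equal(halftime_exponent("PES", n_2 = 3, regime = "secondary-unsaturated"), -2)
  expect_error(halftime_exponent("PE", regime = "secondary-unsaturated"),
               class = "amylokin_invalid_input")
  expect_error(halftime_exponent("PES", regime = "secondary-saturated"),
               class = "amylokin_invalid_input")
})

test_that("invalid states and parameters are rejected", {
  p <- kinetic_params(k_n = 1, k_plus = 1e6)
  expect_error(assembly_rates(list(m = -1e-6, P = 0, M_fib = 0), p, "PE", 1e-5),
               class = "amylokin_invalid_input")
  expect_error(kinetic_params(k_n = -1), class = "amylokin_invalid_input")
  expect_error(kinetic_params(n_c = 0), class = "amylokin_invalid_input")
  expect_error(simulate_assembly(p, "PEMS", m_total = 1e-5,
                                 times = seq(0, 10, 0.5)),
               class = "amylokin_invalid_input")  # PEMS needs finite K_M
  expect_error(simulate_assembly(p, "PE", m_total = 1e-5, times = c(1, 2)),
               class = "amylokin_invalid_input")  # grid must start at 0
})
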