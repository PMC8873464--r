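# Independent oracles used across the suite.

# Fixed-step classical RK4 over the pure-R rate equations: the brute-force
# reference the adaptive solver is checked against.
rk4_trajectory <- function(params, model, m_total, times, initial = NULL,
                           n_steps = 1e4) {
  if (is.null(initial)) initial <- list(m = m_total, P = 0, M_fib = 0)
  h_grid <- seq(0, max(times), length.out = n_steps + 1)
  h <- h_grid[2] - h_grid[1]
  P <- initial$P; M <- initial$M_fib
  out_P <- numeric(n_steps + 1); out_M <- numeric(n_steps + 1)
  out_P[1] <- P; out_M[1] <- M
  deriv <- function(P, M) {
    m <- max(m_total - M, 0)
    assembly_rates(list(m = m, P = max(P, 0), M_fib = M), params, model, m_total)
  }
  for (i in seq_len(n_steps)) {
    k1 <- deriv(P, M)
    k2 <- deriv(P + h / 2 * k1[1], M + h / 2 * k1[2])
    k3 <- deriv(P + h / 2 * k2[1], M + h / 2 * k2[2])
    k4 <- deriv(P + h * k3[1], M + h * k3[2])
    P <- P + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    M <- M + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    M <- min(M, m_total)
    out_P[i + 1] <- P; out_M[i + 1] <- M
  }
  list(times = h_grid, P = out_P, M_fib = out_M)
}

# Interpolate an RK4 trajectory onto arbitrary times.
rk4_at <- function(rk4, times) {
  stats::approx(rk4$times, rk4$M_fib, xout = times, ties = "ordered")$y
}

# Level-crossing by bisection on a dense noiseless trajectory (t50 oracle).
bisect_t50 <- function(params, model, m_total, level = 0.5, t_hi = 100) {
  f <- function(t) {
    tr <- simulate_assembly(params, model, m_total = m_total,
                            times = c(0, max(t, 1e-6)))
    tr$mass_fraction[nrow(tr)] - level
  }
  stats::uniroot(f, c(1e-6, t_hi), tol = 1e-8)$root
}

# Default-scale PEMS truth used by fitting tests.
truth_params <- function() default_true_params()

# Simulated half time on a dense grid, for scaling-exponent checks.
sim_t50 <- function(params, model, m0, t_max = 400, n = 4001) {
  tr <- simulate_assembly(params, model, m_total = m0,
                          times = seq(0, t_max, length.out = n))
  stats::approx(tr$mass_fraction, tr$time_h, xout = 0.5, ties = "ordered")$y
}
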