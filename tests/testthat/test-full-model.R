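test_that("full-model derivative vanishes without currents and at Na balance", {
  p0 <- full_model_params(g_naf = 0, g_nap = 0, g_nap_native = 0, g_k1 = 0,
                          g_k2 = 0, g_ka = 0, g_h = 0, g_caf = 0, g_cas = 0,
                          g_leak = 0, i_pump_max = 0, i_pump_max_native = 0)
  d <- full_rhs(full_state(-0.05, 0.012), p0)
  expect_equal(d[["v_m"]], 0)
  expect_equal(d[["na_i"]], 0)
  # with no pump and V at the Na+ reversal, the Na+ flux balances to zero
  p1 <- full_model_params(i_pump_max = 0, i_pump_max_native = 0)
  v_rev <- nernst_ena(p1$na_o, 0.012)
  d1 <- full_rhs(full_state(v_rev, 0.012), p1)
  expect_equal(d1[["na_i"]], 0)
})

test_that("full-model currents match a term-by-term hand evaluation", {
  p <- full_model_params(g_nap = 6, i_pump_max = 0.3)
  V <- -0.05
  st <- full_state(V, 0.012)
  cur <- full_currents(st, p)
  # independent evaluation of each printed current term
  f <- function(A, B) 1 / (1 + exp(A * (V + B)))
  ena <- 0.02526 * log(0.115 / 0.012)
  sp <- 1 / (1 + exp((0.012 - 0.012) / 0.0016))
  fh <- 1 / (1 + 2 * exp(180 * (V + 0.047)) + exp(500 * (V + 0.047)))
  expected <- c(
    i_naf = 150 * f(-150, 0.029)^3 * f(500, 0.03) * (V - ena),
    i_nap = 6 * f(-120, 0.039) * (V - ena),
    i_nap_native = 5 * f(-120, 0.039) * (V - ena),
    i_k1 = 80 * f(-143, 0.021)^2 * f(111, 0.028) * (V + 0.07),
    i_k2 = 80 * f(-83, 0.02)^2 * (V + 0.07),
    i_ka = 100 * f(-130, 0.044)^2 * f(160, 0.063) * (V + 0.07),
    i_h = 4 * fh^2 * (V + 0.021),
    i_caf = 5 * f(-600, 0.0467)^2 * f(350, 0.055) * (V - 0.135),
    i_cas = 4 * f(-420, 0.0472)^2 * f(360, 0.055) * (V - 0.135),
    i_pump = 0.3 * sp, i_pump_native = 0.1 * sp,
    i_leak = 7 * (V + 0.045))
  expect_equal(cur, expected, tolerance = 1e-12)
  d <- full_rhs(st, p)
  expect_equal(d[["v_m"]], -sum(expected) / 0.25, tolerance = 1e-12)
  expect_equal(d[["na_i"]],
               -(expected[["i_nap"]] + expected[["i_nap_native"]] +
                   expected[["i_naf"]] + 3 * expected[["i_pump"]] +
                   3 * expected[["i_pump_native"]]) / p$v_f,
               tolerance = 1e-12)
  # gating at steady state has zero gating derivatives
  expect_equal(unname(d[-(1:2)]), rep(0, 14), tolerance = 1e-9)
})

test_that("short simulations start exactly at the requested state", {
  p <- full_model_params()
  st <- full_state(-0.048, 0.0115)
  tr <- simulate_full(p, 0.002, init = st)
  expect_equal(tr$v_m_V[1], st[["v_m"]])
  expect_equal(tr$na_i_M[1], st[["na_i"]])
  expect_equal(tr$i_pump_nA[1],
               pump_current(0.0115, p$i_pump_max), tolerance = 1e-10)
})

test_that("deterministic simulations are exactly reproducible and noisy ones seeded", {
  p <- full_model_params()
  a <- simulate_full(p, 0.5)
  b <- simulate_full(p, 0.5)
  expect_identical(a$v_m_V, b$v_m_V)
  pn <- full_model_params(sigma_noise = 0.05)
  expect_error(simulate_full(pn, 0.5), "seed")
  n1 <- simulate_full(pn, 0.5, seed = 3)
  n2 <- simulate_full(pn, 0.5, seed = 3)
  n3 <- simulate_full(pn, 0.5, seed = 4)
  expect_identical(n1$v_m_V, n2$v_m_V)
  expect_false(identical(n1$v_m_V, n3$v_m_V))
})

## one high-amplitude bursting run shared by the long-horizon invariants
ha_params <- full_model_params(g_nap = 6, i_pump_max = 0.3, i_app = -0.1)
ha_trace <- simulate_full(ha_params, 60)

test_that("gating stays in [0,1] and [Na+]_i in range over a long bursting run", {
  p <- ha_params
  tr60 <- ha_trace
  expect_true(all(tr60$na_i_M > 0 & tr60$na_i_M < p$na_o))
  # re-integrate a short window keeping the full state to inspect gating
  st <- full_state()
  out <- deSolve::ode(unname(st), seq(0, 5, by = 1e-3), "hn_full_deriv",
                      hnburst:::.full_parms_vector(p), dllname = "hnburst",
                      initfunc = "hn_full_init", nout = 4,
                      outnames = c("a", "b", "c", "d"),
                      rtol = 1e-8, atol = 1e-10)
  gates <- out[, 4:17]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("steady-state bursting closes its Na+ budget cycle to cycle", {
  w <- ha_trace[ha_trace$time_s >= 30, ]
  na <- w$na_i_M
  ex <- hnburst:::.slow_extrema(na)
  troughs <- ex$troughs
  expect_gte(length(troughs), 4)
  amp <- max(na) - min(na)
  drift <- abs(diff(na[troughs]))
  expect_lt(max(drift), 0.01 * amp)
  expect_true(steady_state_reached(as_hn_trace(w), n_cycles = 4, tol = 0.1))
})

test_that("steady-state test rejects a drifting oscillation", {
  tt <- seq(0, 60, by = 0.01)
  mk <- function(grow) {
    as_hn_trace(data.frame(time_s = tt, v_m_V = -0.05,
                           i_nap_nA = 0, i_pump_nA = 0,
                           na_i_M = 0.012 +
                             0.001 * (1 + grow * tt) * sin(2 * pi * tt / 4)))
  }
  expect_true(steady_state_reached(mk(0), n_cycles = 8, tol = 0.05))
  expect_false(steady_state_reached(mk(0.05), n_cycles = 8, tol = 0.05))
})
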