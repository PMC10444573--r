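#' Parameters of the reduced two-variable HN model
#'
#' The reduced model keeps only membrane potential and intracellular Na+
#' as state variables; every gating variable is at its voltage steady
#' state (instantaneous gating).  It carries the native persistent Na+
#' current, fast Na+ current, h-current (split 3/7 Na+ and 4/7 K+),
#' persistent K+ current, Na+ and K+ leak components, plus the injected
#' persistent Na+ and pump currents with the same parameters as the hybrid
#' experiments.  Defaults are the published reduced-model constants.
#'
#' Steady-state activations are Boltzmann curves `1/(1+exp(A (V+B)))`
#' parameterised by steepness `A` (1/V) and offset `B` (V); the h-current
#' uses the double-exponential form of [h_inf()].  The half-activation
#' offsets and steepnesses of the native persistent Na+ current and of the
#' persistent K+ current are among the parameters targeted by
#' [evolve()].
#'
#' @param g_nap_native,g_nap,g_naf,g_h,g_k2 maximal conductances (nS).
#' @param g_leak_na,g_leak_k Na+ and K+ leak conductances (nS).
#' @param e_h,e_k,e_leak_k reversal potentials (V).
#' @param i_pump_max injected pump maximal current (nA).
#' @param na_ih,na_is pump half-activation and sensitivity (M).
#' @param na_o extracellular [Na+] (M).
#' @param c_m membrane capacitance (nF).
#' @param volume cytosolic Na+ reservoir volume (nl).
#' @param v_f Na+ flux-to-concentration conversion (nA s / M); by default
#'   the reciprocal of `volume` in nl, the conversion convention under which
#'   the published characteristics of this model are reproduced (see the
#'   methods vignette for the calibration).
#' @param a_mnapn,b_mnapn steepness and offset of the native persistent Na+
#'   activation.
#' @param a_mnap,b_mnap injected persistent Na+ activation.
#' @param a_mnaf,b_mnaf fast Na+ activation; `exp_mnaf` is its exponent.
#' @param a_hnaf,b_hnaf fast Na+ inactivation.
#' @param a1_mh,a2_mh,b_mh h-current activation (double-exponential form);
#'   `exp_mh` is its exponent.
#' @param a_mk2,b_mk2 persistent K+ activation; `exp_mk2` is its exponent.
#' @param exp_mnaf,exp_mh,exp_mk2 activation exponents.
#' @param ena_slope Nernst slope RT/zF (V).
#' @return an object of class `hn_reduced_params` (a named list).
#' @seealso [simulate_2d()], [currents_2d()], [v_nullcline()]
#' @export
reduced_model_params <- function(g_nap_native = 9.85, g_nap = 6,
                                 g_naf = 150, g_h = 6, g_k2 = 138,
                                 g_leak_na = 1.1, g_leak_k = 8.8,
                                 e_h = -0.021, e_k = -0.07,
                                 e_leak_k = -0.07,
                                 i_pump_max = 0.3, na_ih = 0.012,
                                 na_is = 0.0016, na_o = 0.115,
                                 c_m = 0.25, volume = 0.0038,
                                 v_f = 1 / volume,
                                 a_mnapn = -160, b_mnapn = 0.0376,
                                 a_mnap = -120, b_mnap = 0.04,
                                 a_mnaf = -210, b_mnaf = 0.032,
                                 a_hnaf = 500, b_hnaf = 0.04,
                                 a1_mh = 184.14, a2_mh = 511.5,
                                 b_mh = 0.057,
                                 a_mk2 = -83, b_mk2 = 0.0285,
                                 exp_mnaf = 3, exp_mh = 2, exp_mk2 = 2,
                                 ena_slope = 0.02526) {
  p <- mget(ls(environment()))
  conds <- c("g_nap_native", "g_nap", "g_naf", "g_h", "g_k2",
             "g_leak_na", "g_leak_k")
  if (any(unlist(p[conds]) < 0)) stop("conductances must be >= 0")
  stopifnot(p$na_is > 0, p$na_o > 0, p$v_f > 0, p$c_m > 0)
  structure(p, class = "hn_reduced_params")
}

## parameter vector in the order expected by the compiled code
.reduced_parms_vector <- function(p) {
  c(p$g_nap_native, p$g_nap, p$g_naf, p$g_h, p$g_k2, p$g_leak_na,
    p$g_leak_k, p$e_h, p$e_k, p$e_leak_k, p$i_pump_max, p$na_ih, p$na_is,
    p$na_o, p$c_m, p$v_f,
    p$a_mnapn, p$b_mnapn, p$a_mnap, p$b_mnap, p$a_mnaf, p$b_mnaf,
    p$a_hnaf, p$b_hnaf, p$a1_mh, p$a2_mh, p$b_mh, p$a_mk2, p$b_mk2,
    p$ena_slope)
}

#' Per-current breakdown of the reduced model
#'
#' Evaluates every current of the reduced model at membrane potential `V`
#' and intracellular Na+ `nai`.  Conductance currents follow
#' \eqn{I_i = \bar g_i m_\infty^{a_i} h_\infty^{b_i} (V - E_i)} with the
#' Na+ reversal from [nernst_ena()]; the h-current is computed once and
#' split 3/7 (Na+) and 4/7 (K+); the pump current from [pump_current()].
#' Vectorised over `V` and `nai`.
#'
#' @param V membrane potential (V).
#' @param nai intracellular Na+ (M).
#' @param params an [reduced_model_params()] object.
#' @return data frame with columns `i_nap_native`, `i_nap`, `i_naf`,
#'   `i_h_na`, `i_h_k`, `i_k2`, `i_leak_na`, `i_leak_k`, `i_pump` (nA).
#' @export
currents_2d <- function(V, nai, params) {
  p <- params
  ena <- nernst_ena(p$na_o, nai, p$ena_slope)
  ih <- p$g_h * h_inf(V, p$a1_mh, p$a2_mh, p$b_mh)^p$exp_mh * (V - p$e_h)
  data.frame(
    i_nap_native = p$g_nap_native * boltzmann(p$a_mnapn, p$b_mnapn, V) *
      (V - ena),
    i_nap = p$g_nap * boltzmann(p$a_mnap, p$b_mnap, V) * (V - ena),
    i_naf = p$g_naf * boltzmann(p$a_mnaf, p$b_mnaf, V)^p$exp_mnaf *
      boltzmann(p$a_hnaf, p$b_hnaf, V) * (V - ena),
    i_h_na = 3 / 7 * ih,
    i_h_k = 4 / 7 * ih,
    i_k2 = p$g_k2 * boltzmann(p$a_mk2, p$b_mk2, V)^p$exp_mk2 * (V - p$e_k),
    i_leak_na = p$g_leak_na * (V - ena),
    i_leak_k = p$g_leak_k * (V - p$e_leak_k),
    i_pump = pump_current(nai, p$i_pump_max, p$na_ih, p$na_is))
}

## total membrane current (nA) and total Na+ flux-carrying current (nA);
## vectorised -- these are the numerators of the two nullcline balances
.total_current_2d <- function(V, nai, params) {
  cur <- currents_2d(V, nai, params)
  rowSums(cur)
}

.total_na_flux_2d <- function(V, nai, params) {
  cur <- currents_2d(V, nai, params)
  cur$i_nap_native + cur$i_nap + 3 * cur$i_pump + cur$i_naf +
    cur$i_h_na + cur$i_leak_na
}

#' Right-hand side of the reduced model (reference implementation)
#'
#' dV/dt is minus the total membrane current over the capacitance; the Na+
#' balance counts every Na+-carrying current (native and injected
#' persistent Na+, fast Na+, Na+ components of h and leak) plus three
#' times the pump current, divided by the flux conversion `v_f`.
#'
#' @param state numeric `c(v_m, na_i)` (V, M).
#' @param params an [reduced_model_params()] object.
#' @return named vector `c(dv_dt, dna_dt)` (V/s, M/s).
#' @export
rhs_2d <- function(state, params) {
  V <- state[[1]]; nai <- state[[2]]
  out <- c(dv_dt = -.total_current_2d(V, nai, params) / params$c_m,
           dna_dt = -.total_na_flux_2d(V, nai, params) / params$v_f)
  if (any(!is.finite(out))) stop("rhs_2d: non-finite derivative")
  out
}

#' Simulate the reduced model
#'
#' Deterministic integration of the two-variable system with
#' `deSolve::lsoda` (compiled core).
#'
#' @param params an [reduced_model_params()] object.
#' @param duration simulated time (s), > 0.
#' @param init numeric `c(v_m, na_i)`; the default starts on the
#'   hyperpolarised branch.
#' @param sample_rate output sampling rate (Hz).
#' @param rtol,atol solver tolerances.
#' @return an `hn_trace` with `v_m_V`, `i_nap_nA`, `i_pump_nA`, `na_i_M`.
#' @export
simulate_2d <- function(params, duration, init = c(-0.055, 0.011),
                        sample_rate = 1000, rtol = 1e-8,
                        atol = c(1e-10, 1e-12)) {
  stopifnot(inherits(params, "hn_reduced_params"), duration > 0,
            length(init) == 2)
  times <- seq(0, duration, by = 1 / sample_rate)
  out <- deSolve::ode(y = unname(init), times = times,
                      func = "hn_red_deriv",
                      parms = .reduced_parms_vector(params),
                      dllname = "hnburst", initfunc = "hn_red_init",
                      nout = 2, outnames = c("i_nap", "i_pump"),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("simulate_2d: solver failure")
  nai <- out[, 3]
  if (any(nai <= 0) || any(nai >= params$na_o)) {
    stop("simulate_2d: [Na+]_i left (0, [Na+]_o)")
  }
  as_hn_trace(data.frame(time_s = out[, 1], v_m_V = out[, 2],
                         i_nap_nA = out[, "i_nap"],
                         i_pump_nA = out[, "i_pump"], na_i_M = nai),
              params = params)
}

#' Threshold-based cycle measurement for reduced-model traces
#'
#' The reduced model produces a smooth relaxation oscillation; burst
#' duration is the time the membrane potential spends above a fixed
#' threshold (default -45 mV) and the interburst interval the time below,
#' averaged over complete cycles.  Crossing times are located by linear
#' interpolation between samples.
#'
#' @param trace an `hn_trace` from [simulate_2d()].
#' @param v_threshold threshold (V).
#' @param transient initial time span (s) discarded before measuring.
#' @return list with `bd`, `ibi`, `period` (s), `v_amplitude` (V),
#'   `na_amplitude` (M), `n_cycles`, and the per-cycle values.
#' @export
measure_2d_cycle <- function(trace, v_threshold = -0.045, transient = 20) {
  tr <- trace[trace$time_s >= transient, ]
  v <- tr$v_m_V; tt <- tr$time_s
  above <- v > v_threshold
  iup <- which(diff(above) == 1)
  idn <- which(diff(above) == -1)
  if (length(iup) < 2) stop("measure_2d_cycle: no oscillation detected")
  cross <- function(i) {
    tt[i] + (v_threshold - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  }
  up <- vapply(iup, cross, 0)
  dn <- vapply(idn, cross, 0)
  dn <- dn[dn > up[1]]
  n <- min(length(up) - 1, length(dn))
  if (n < 1) stop("measure_2d_cycle: fewer than one full cycle")
  bd <- dn[seq_len(n)] - up[seq_len(n)]
  ibi <- up[seq_len(n) + 1] - dn[seq_len(n)]
  list(bd = mean(bd), ibi = mean(ibi), period = mean(bd + ibi),
       v_amplitude = max(v) - min(v),
       na_amplitude = max(tr$na_i_M) - min(tr$na_i_M),
       n_cycles = n, bd_cycles = bd, ibi_cycles = ibi)
}
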