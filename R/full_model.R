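#' Parameters of the full HN virtual hybrid neuron
#'
#' Complete parameterisation of the single-compartment HN interneuron model
#' with dynamic-clamp style injected persistent Na+ current (conductance
#' `g_nap`) and injected Na+/K+ pump current (maximum `i_pump_max`), plus the
#' native persistent Na+ and pump currents assumed endogenously present.
#' Defaults are the published dynamic-clamp model constants.
#'
#' @param g_naf fast Na+ maximal conductance (nS).
#' @param g_nap injected persistent Na+ maximal conductance (nS); the
#'   experiments vary this over 1--7 nS.
#' @param g_nap_native native persistent Na+ maximal conductance (nS).
#' @param g_k1,g_k2,g_ka delayed-rectifier, persistent and transient K+
#'   maximal conductances (nS).
#' @param g_h hyperpolarisation-activated current maximal conductance (nS).
#' @param g_caf,g_cas fast and slow Ca2+ maximal conductances (nS).
#' @param g_leak leak conductance (nS).
#' @param e_k,e_h,e_ca,e_leak reversal potentials (V).
#' @param i_pump_max injected pump maximal current (nA); experiments cover
#'   0.1--0.9 nA.
#' @param i_pump_max_native native pump maximal current (nA).
#' @param na_ih pump half-activation [Na+]_i (M).
#' @param na_is pump [Na+]_i sensitivity (M).
#' @param na_o extracellular [Na+] (M), held constant.
#' @param c_m membrane capacitance (nF).
#' @param v_f Na+ flux-to-concentration conversion (nA s / M): the net
#'   Na+-carrying current divided by `v_f` gives d[Na+]_i/dt.  The default is
#'   the reciprocal of the dynamic-clamp conversion constant 0.0024
#'   (nA to mM/ms), i.e. cytosolic volume times the Faraday constant.
#' @param i_app constant bias current (nA).  0 for pure-model runs; the
#'   hybrid experimental protocol holds -0.1 nA (see [protocol_spec()]).
#' @param sigma_noise amplitude (nA) of zero-mean piecewise-constant current
#'   noise added to the voltage equation (held for 1 ms); 0 disables noise.
#' @param ena_slope Nernst slope RT/zF (V).
#' @return an object of class `hn_full_params` (a named list).
#' @seealso [simulate_full()], [full_rhs()]
#' @export
full_model_params <- function(g_naf = 150, g_nap = 6, g_nap_native = 5,
                              g_k1 = 80, g_k2 = 80, g_ka = 100, g_h = 4,
                              g_caf = 5, g_cas = 4, g_leak = 7,
                              e_k = -0.07, e_h = -0.021, e_ca = 0.135,
                              e_leak = -0.045,
                              i_pump_max = 0.3, i_pump_max_native = 0.1,
                              na_ih = 0.012, na_is = 0.0016, na_o = 0.115,
                              c_m = 0.25, v_f = 1 / 0.0024,
                              i_app = 0, sigma_noise = 0,
                              ena_slope = 0.02526) {
  p <- list(g_naf = g_naf, g_nap = g_nap, g_nap_native = g_nap_native,
            g_k1 = g_k1, g_k2 = g_k2, g_ka = g_ka, g_h = g_h,
            g_caf = g_caf, g_cas = g_cas, g_leak = g_leak,
            e_k = e_k, e_h = e_h, e_ca = e_ca, e_leak = e_leak,
            i_pump_max = i_pump_max, i_pump_max_native = i_pump_max_native,
            na_ih = na_ih, na_is = na_is, na_o = na_o,
            c_m = c_m, v_f = v_f, i_app = i_app,
            sigma_noise = sigma_noise, ena_slope = ena_slope)
  conds <- c("g_naf", "g_nap", "g_nap_native", "g_k1", "g_k2", "g_ka",
             "g_h", "g_caf", "g_cas", "g_leak")
  if (any(unlist(p[conds]) < 0)) stop("conductances must be >= 0")
  stopifnot(na_is > 0, na_o > 0, v_f > 0, c_m > 0, sigma_noise >= 0)
  structure(p, class = "hn_full_params")
}

## gating variable bookkeeping: steady-state (A, B) pairs and time constants,
## ordered as in the compiled right-hand side
.full_gate_names <- c("m_naf", "h_naf", "m_nap", "m_nap_native",
                      "m_k1", "h_k1", "m_k2", "m_ka", "h_ka", "m_h",
                      "m_caf", "h_caf", "m_cas", "h_cas")

.full_gate_inf <- function(V) {
  c(boltzmann(-150, 0.029, V), boltzmann(500, 0.03, V),
    boltzmann(-120, 0.039, V), boltzmann(-120, 0.039, V),
    boltzmann(-143, 0.021, V), boltzmann(111, 0.028, V),
    boltzmann(-83, 0.02, V), boltzmann(-130, 0.044, V),
    boltzmann(160, 0.063, V), h_inf(V),
    boltzmann(-600, 0.0467, V), boltzmann(350, 0.055, V),
    boltzmann(-420, 0.0472, V), boltzmann(360, 0.055, V))
}

.full_gate_tau <- function(V) {
  c(0.0001, tau_hna(V),
    tau_generic(400, 0.057, 0.01, 0.2, V),
    tau_generic(400, 0.057, 0.01, 0.2, V),
    tau_generic(150, 0.016, 0.001, 0.011, V),
    tau_generic(-143, 0.013, 0.5, 0.2, V),
    tau_generic(200, 0.035, 0.057, 0.043, V),
    tau_generic(200, 0.03, 0.005, 0.011, V),
    tau_generic(-300, 0.055, 0.026, 0.0085, V),
    tau_generic(-100, 0.073, 0.7, 1.7, V),
    tau_generic(-330, 0.0467, 0.011, 0.024, V),
    tau_generic(270, 0.055, 0.06, 0.31, V),
    tau_generic(-400, 0.0487, 0.005, 0.134, V),
    tau_generic(-250, 0.043, 0.2, 5.25, V))
}

#' Full-model state with gating at voltage steady state
#'
#' @param v_m membrane potential (V).
#' @param na_i intracellular Na+ concentration (M).
#' @return named numeric state vector (16 elements) suitable for
#'   [full_rhs()] and [simulate_full()].
#' @export
full_state <- function(v_m = -0.05, na_i = 0.010) {
  stopifnot(na_i > 0)
  stats::setNames(c(v_m, na_i, .full_gate_inf(v_m)),
                  c("v_m", "na_i", .full_gate_names))
}

## parameter vector in the order expected by the compiled code
.full_parms_vector <- function(p) {
  c(p$g_naf, p$g_nap, p$g_nap_native, p$g_k1, p$g_k2, p$g_ka, p$g_h,
    p$g_caf, p$g_cas, p$g_leak, p$e_k, p$e_h, p$e_ca, p$e_leak,
    p$i_pump_max, p$i_pump_max_native, p$na_ih, p$na_is, p$na_o,
    p$c_m, p$v_f, p$i_app, p$ena_slope)
}

#' Membrane currents of the full model at a given state
#'
#' @param state named state vector as from [full_state()].
#' @param params an [full_model_params()] object.
#' @return named vector of the 12 membrane currents (nA); positive values
#'   are outward.
#' @export
full_currents <- function(state, params) {
  p <- params
  V <- state[["v_m"]]; nai <- state[["na_i"]]
  ena <- nernst_ena(p$na_o, nai, p$ena_slope)
  sp <- pump_current(nai, 1, p$na_ih, p$na_is)
  c(i_naf = p$g_naf * state[["m_naf"]]^3 * state[["h_naf"]] * (V - ena),
    i_nap = p$g_nap * state[["m_nap"]] * (V - ena),
    i_nap_native = p$g_nap_native * state[["m_nap_native"]] * (V - ena),
    i_k1 = p$g_k1 * state[["m_k1"]]^2 * state[["h_k1"]] * (V - p$e_k),
    i_k2 = p$g_k2 * state[["m_k2"]]^2 * (V - p$e_k),
    i_ka = p$g_ka * state[["m_ka"]]^2 * state[["h_ka"]] * (V - p$e_k),
    i_h = p$g_h * state[["m_h"]]^2 * (V - p$e_h),
    i_caf = p$g_caf * state[["m_caf"]]^2 * state[["h_caf"]] * (V - p$e_ca),
    i_cas = p$g_cas * state[["m_cas"]]^2 * state[["h_cas"]] * (V - p$e_ca),
    i_pump = p$i_pump_max * sp,
    i_pump_native = p$i_pump_max_native * sp,
    i_leak = p$g_leak * (V - p$e_leak))
}

#' Right-hand side of the full model (reference implementation)
#'
#' Time derivatives of the 16-dimensional state: membrane potential from the
#' total current balance, intracellular Na+ from the Na+-carrying currents
#' (fast, injected and native persistent Na+ currents, plus three times the
#' injected and native pump currents; leak and h-current Na+ fluxes are not
#' counted), and first-order gating relaxation.  This pure-R implementation
#' mirrors the compiled integrator core and serves as its reference.
#'
#' @param state named state vector, see [full_state()].
#' @param params an [full_model_params()] object.
#' @param t time (s); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @return named vector of time derivatives, same layout as `state`.
#' @export
full_rhs <- function(state, params, t = 0) {
  cur <- full_currents(state, params)
  dv <- (-sum(cur) + params$i_app) / params$c_m
  dna <- -(cur[["i_nap"]] + cur[["i_nap_native"]] + cur[["i_naf"]] +
             3 * cur[["i_pump"]] + 3 * cur[["i_pump_native"]]) / params$v_f
  V <- state[["v_m"]]
  gates <- state[.full_gate_names]
  dg <- (.full_gate_inf(V) - gates) / .full_gate_tau(V)
  out <- stats::setNames(c(dv, dna, dg), names(state))
  if (any(!is.finite(out))) stop("full_rhs: non-finite derivative")
  out
}

#' Simulate the full HN virtual hybrid neuron
#'
#' Integrates the stiff 16-dimensional system with `deSolve::lsoda` (compiled
#' core, adaptive error control) and returns a uniformly sampled trace of
#' membrane potential, injected currents and intracellular Na+.  With
#' `sigma_noise > 0` a seeded, piecewise-constant (1 ms hold) zero-mean
#' current noise is added to the voltage equation to emulate cycle-to-cycle
#' biological variability.
#'
#' @param params an [full_model_params()] object.
#' @param duration simulated time (s), > 0.
#' @param init `"default"` (V = -50 mV, [Na+]_i = 10 mM, gating at steady
#'   state) or a state vector from [full_state()].
#' @param seed integer seed for the noise stream (required reproducibility
#'   when `sigma_noise > 0`; ignored otherwise).
#' @param sample_rate output sampling rate (Hz); default 5 kHz, the
#'   acquisition rate of the emulated recordings.
#' @param rtol,atol solver tolerances (`atol` may be length 16).
#' @param keep_native also keep native-current columns in the trace.
#' @return an `hn_trace` data frame with columns `time_s`, `v_m_V`,
#'   `i_nap_nA`, `i_pump_nA`, `na_i_M` (plus native currents if requested).
#' @export
simulate_full <- function(params, duration, init = "default", seed = NULL,
                          sample_rate = 5000, rtol = 1e-8,
                          atol = c(1e-10, 1e-12, rep(1e-12, 14)),
                          keep_native = FALSE) {
  stopifnot(inherits(params, "hn_full_params"), duration > 0)
  if (identical(init, "default")) init <- full_state()
  stopifnot(length(init) == 16)
  times <- seq(0, duration, by = 1 / sample_rate)

  args <- list(y = unname(init), times = times, func = "hn_full_deriv",
               parms = .full_parms_vector(params), dllname = "hnburst",
               initfunc = "hn_full_init", nout = 4,
               outnames = c("i_nap", "i_pump", "i_nap_native",
                            "i_pump_native"),
               method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000)
  if (params$sigma_noise > 0) {
    if (is.null(seed)) stop("simulate_full: seed required when sigma_noise > 0")
    tgrid <- seq(0, duration + 0.001, by = 0.001)
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
    vals <- stats::rnorm(length(tgrid), 0, params$sigma_noise)
    args$forcings <- cbind(tgrid, vals)
    args$initforc <- "hn_full_forc"
    args$fcontrol <- list(method = "constant", rule = 2)
  }
  out <- do.call(deSolve::ode, args)
  if (attr(out, "istate")[1] < 0) stop("simulate_full: solver failure")
  nai <- out[, 3]
  if (any(nai <= 0) || any(nai >= params$na_o)) {
    stop("simulate_full: [Na+]_i left (0, [Na+]_o)")
  }
  tr <- data.frame(time_s = out[, 1], v_m_V = out[, 2],
                   i_nap_nA = out[, "i_nap"], i_pump_nA = out[, "i_pump"],
                   na_i_M = nai)
  if (keep_native) {
    tr$i_nap_native_nA <- out[, "i_nap_native"]
    tr$i_pump_native_nA <- out[, "i_pump_native"]
  }
  as_hn_trace(tr, params = params)
}

#' Has a simulated trace reached steady state?
#'
#' Steady state is declared when the per-cycle [Na+]_i oscillation amplitude
#' shows only small variability over the last `n_cycles` cycles: the
#' relative spread (max minus min over mean) must not exceed `tol`.
#'
#' @param trace an `hn_trace`.
#' @param n_cycles number of trailing cycles to examine.
#' @param tol maximal relative spread of per-cycle amplitude.
#' @return `TRUE` or `FALSE`.
#' @export
steady_state_reached <- function(trace, n_cycles = 8, tol = 0.1) {
  amps <- oscillation_stats(trace$na_i_M, time = trace$time_s)$amplitudes
  if (length(amps) < n_cycles) {
    stop("steady_state_reached: fewer than n_cycles cycles in trace")
  }
  a <- utils::tail(amps, n_cycles)
  (max(a) - min(a)) / mean(a) <= tol
}
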