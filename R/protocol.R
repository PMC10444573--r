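#' Experimental protocol specification
#'
#' The hybrid experiments follow two protocols: protocol 1 holds the
#' injected pump maximum fixed and varies the injected persistent Na+
#' conductance (1--7 nS); protocol 2 holds the conductance at 6 nS and
#' varies the pump maximum (0.1--0.9 nA).  A protocol spec is the
#' condition list plus per-condition duration and the seed; the hybrid
#' protocols hold a -0.1 nA bias current.
#'
#' @param protocol 1 or 2.
#' @param g_nap injected persistent Na+ conductances (nS): the swept values
#'   for protocol 1, a single value for protocol 2.
#' @param i_pump_max injected pump maxima (nA): a single value for
#'   protocol 1, the swept values for protocol 2.
#' @param duration per-condition simulated time (s).
#' @param seed integer seed.
#' @param i_app bias current (nA); the experimental protocol holds -0.1 nA.
#' @return an `hn_protocol` list with a `conditions` data frame.
#' @export
protocol_spec <- function(protocol = 2,
                          g_nap = if (protocol == 1) seq(1, 7) else 6,
                          i_pump_max = if (protocol == 1) 0.3 else
                            c(0.1, 0.3, 0.5, 0.7, 0.9),
                          duration = 90, seed = 1, i_app = -0.1) {
  stopifnot(protocol %in% c(1, 2),
            all(g_nap >= 0 & g_nap <= 10),
            all(i_pump_max >= 0 & i_pump_max <= 1))
  conditions <- expand.grid(g_nap = g_nap, i_pump_max = i_pump_max)
  structure(list(protocol = protocol, conditions = conditions,
                 duration = duration, seed = seed, i_app = i_app),
            class = "hn_protocol")
}

#' Run a protocol: simulate, analyse and classify every condition
#'
#' For each (conductance, pump maximum) condition, simulates the chosen
#' model, runs the burst analysis, applies the acceptance rule and the
#' two-threshold regime label, and collects everything into a tidy
#' summary table (one row per condition) suitable for regime maps and
#' normalised trend plots.  A failing condition is recorded with `NA`
#' metrics and the run continues.
#'
#' @param spec an [protocol_spec()].
#' @param model `"full"` (spiking virtual hybrid neuron, analysed with the
#'   spike/burst pipeline) or `"2d"` (reduced model, analysed with the
#'   threshold measurement).
#' @param transient initial span (s) discarded before analysis.
#' @param params base parameter object; defaults to the published set for
#'   the chosen model.
#' @return data frame with per-condition metrics, acceptance flag and
#'   regime label (1 = high-amplitude).
#' @export
run_protocol <- function(spec, model = c("full", "2d"), transient = 30,
                         params = NULL) {
  model <- match.arg(model)
  if (is.null(params)) {
    params <- if (model == "full") {
      full_model_params(i_app = spec$i_app)
    } else {
      reduced_model_params()
    }
  }
  rows <- lapply(seq_len(nrow(spec$conditions)), function(i) {
    cond <- spec$conditions[i, ]
    base <- data.frame(g_nap = cond$g_nap, i_pump_max = cond$i_pump_max)
    out <- tryCatch({
      p <- params
      p$g_nap <- cond$g_nap
      p$i_pump_max <- cond$i_pump_max
      if (model == "full") {
        tr <- simulate_full(p, spec$duration, seed = spec$seed)
        tr <- as_hn_trace(tr[tr$time_s >= transient, ])
        spikes <- detect_spikes(tr)
        seg <- segment_bursts(spikes)
        m <- cycle_metrics(tr, seg, spikes)
        cbind(base, data.frame(
          bd = m$mean_bd, ibi = m$mean_ibi, t_cycle = m$mean_t,
          spike_freq = m$spike_freq, v_amplitude = m$v_amplitude,
          na_amplitude = m$na_amplitude, na_median = m$na_median,
          pump_amplitude = m$pump_amplitude, pump_median = m$pump_median,
          cv_t = m$cv_t, accepted = accept_recording(m),
          label = two_threshold_label(m$v_amplitude, m$na_amplitude)))
      } else {
        tr <- simulate_2d(p, spec$duration)
        m <- measure_2d_cycle(tr, transient = transient)
        win <- tr[tr$time_s >= transient, ]
        na_stats <- oscillation_stats(win$na_i_M)
        pump_stats <- oscillation_stats(win$i_pump_nA)
        cbind(base, data.frame(
          bd = m$bd, ibi = m$ibi, t_cycle = m$period, spike_freq = NA,
          v_amplitude = m$v_amplitude, na_amplitude = m$na_amplitude,
          na_median = na_stats$median_value,
          pump_amplitude = pump_stats$mean_amplitude,
          pump_median = pump_stats$median_value,
          cv_t = stats::sd(m$bd_cycles + m$ibi_cycles) /
            mean(m$bd_cycles + m$ibi_cycles),
          accepted = m$n_cycles >= 5,
          label = two_threshold_label(m$v_amplitude, m$na_amplitude)))
      }
    }, error = function(e) {
      cbind(base, data.frame(
        bd = NA, ibi = NA, t_cycle = NA, spike_freq = NA,
        v_amplitude = NA, na_amplitude = NA, na_median = NA,
        pump_amplitude = NA, pump_median = NA, cv_t = NA,
        accepted = FALSE, label = NA_integer_))
    })
    out
  })
  do.call(rbind, rows)
}
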