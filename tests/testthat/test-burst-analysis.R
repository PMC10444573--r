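test_that("spike detection finds constructed spikes and nothing on flat traces", {
  flat <- make_spike_trace(numeric(0), 5)
  expect_equal(nrow(detect_spikes(flat)), 0)
  expect_error(detect_spikes(flat[0, ]), "empty")
  one <- make_spike_trace(2.5, 5)
  sp <- detect_spikes(one)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$time_s, 2.5, tolerance = 1e-3)
  # bursty train riding on a slow wave: all constructed times recovered
  times <- burst_train(n_bursts = 6)
  tr <- make_spike_trace(times, 20, height = 0.03,
                         baseline = function(t) {
                           -0.055 + 0.005 * sin(2 * pi * t / 7)
                         })
  sp2 <- detect_spikes(tr)
  expect_equal(nrow(sp2), length(times))
  expect_equal(sp2$time_s, times, tolerance = 1e-3)
  # sub-threshold spikelets are ignored in prominence mode
  small <- make_spike_trace(times, 20, height = 0.01)
  expect_equal(nrow(detect_spikes(small)), 0)
})

test_that("burst segmentation applies the interval and size rules", {
  sp <- list(time_s = c(seq(0, 0.4, by = 0.1), seq(1.4, 1.8, by = 0.1)))
  seg <- segment_bursts(sp)
  expect_equal(nrow(seg$bursts), 2)
  expect_equal(seg$bursts$bd, c(0.4, 0.4))
  expect_equal(seg$ibis$duration, 1.0)
  # an isolated undersized group is discarded; its span joins one long IBI
  sp2 <- list(time_s = sort(c(sp$time_s + c(rep(0, 5), rep(1, 5)),
                              c(0.9, 0.95, 1.0) + 0.4)))
  seg2 <- segment_bursts(sp2)
  expect_equal(nrow(seg2$bursts), 2)
  expect_equal(seg2$ibis$duration, 2.0)
})

test_that("segmentation matches a brute-force reference on 200 random trains", {
  for (seed in 1:200) {
    times <- random_spike_train(seed)
    seg <- suppressWarnings(segment_bursts(list(time_s = times)))
    ref <- oracle_segment(times)
    expect_equal(nrow(seg$bursts), length(ref))
    if (length(ref)) {
      expect_equal(seg$bursts$t_first,
                   vapply(ref, function(g) g[1], 0))
      expect_equal(seg$bursts$t_last,
                   vapply(ref, function(g) g[length(g)], 0))
      expect_equal(seg$bursts$n_spikes,
                   vapply(ref, length, 0L))
    }
  }
})

test_that("segmentation is invariant to time translation", {
  times <- random_spike_train(42)
  a <- suppressWarnings(segment_bursts(list(time_s = times)))
  b <- suppressWarnings(segment_bursts(list(time_s = times + 17.3)))
  expect_equal(b$bursts$t_first - 17.3, a$bursts$t_first)
  expect_equal(b$bursts$bd, a$bursts$bd)
})

test_that("cycle metrics reproduce constructed periods and frequencies", {
  times <- burst_train(n_bursts = 10, spikes_per_burst = 8, isi = 0.1,
                       period = 10)
  tr <- make_spike_trace(times, 95)
  sp <- detect_spikes(tr)
  seg <- segment_bursts(sp)
  m <- cycle_metrics(tr, seg, sp)
  expect_equal(m$n_bursts, 10)
  expect_equal(m$t_cycle, rep(10, 9), tolerance = 1e-3)
  expect_equal(m$spike_freq, 10, tolerance = 1e-2)  # 0.1 s ISIs
  expect_equal(m$cv_t, 0, tolerance = 1e-3)
  # bookkeeping closure: BD_i + IBI_i tile first-spike to first-spike
  expect_equal(sum(m$bd[-m$n_bursts]) + sum(m$ibi),
               seg$bursts$t_first[m$n_bursts] - seg$bursts$t_first[1],
               tolerance = 1e-6)
})

test_that("envelope flattens spikes to interval means and bounds the trace", {
  # spikeless trace: identity
  flat <- make_spike_trace(numeric(0), 5,
                           baseline = function(t) -0.05 + 0.002 * sin(t))
  sp <- detect_spikes(flat)
  seg <- suppressWarnings(segment_bursts(sp))
  env <- envelope(flat, seg, sp)
  expect_equal(env$value, flat$v_m_V)
  # adjacent symmetric triangles: each inter-minima interval is exactly one
  # triangle, whose mean is the baseline plus half the spike height
  times <- burst_train(n_bursts = 4, spikes_per_burst = 6, isi = 0.2)
  tr <- make_spike_trace(times, 12, height = 0.04, half_width = 0.1)
  sp2 <- detect_spikes(tr)
  seg2 <- segment_bursts(sp2, ibi_threshold = 0.8)
  env2 <- envelope(tr, seg2, sp2)
  i_spike <- which.min(abs(env2$time_s - times[2]))
  expect_equal(env2$value[i_spike], -0.05 + 0.02, tolerance = 2e-3)
  expect_true(all(env2$value >= min(tr$v_m_V) - 1e-12 &
                    env2$value <= max(tr$v_m_V) + 1e-12))
})

test_that("oscillation statistics match closed forms", {
  tt <- seq(0, 40, by = 0.005)
  s <- oscillation_stats(3 + 2 * sin(2 * pi * tt / 5))
  expect_equal(s$mean_amplitude, 4, tolerance = 1e-3)
  expect_equal(s$median_value, 3, tolerance = 1e-3)
  # sawtooth with instantaneous rise and linear fall: backside median 0.5
  saw <- 1 - (tt %% 4) / 4
  s2 <- oscillation_stats(saw)
  expect_equal(s2$mean_amplitude, 1, tolerance = 1e-2)
  expect_equal(s2$median_value, 0.5, tolerance = 1e-2)
  expect_error(oscillation_stats(rep(1, 100)), "no peak")
})

test_that("recording acceptance combines burst count and period regularity", {
  mk <- function(t_cycle, n) {
    structure(list(n_bursts = n, t_cycle = t_cycle,
                   cv_t = stats::sd(t_cycle) / mean(t_cycle)),
              class = "hn_cycle_metrics")
  }
  expect_true(accept_recording(mk(rep(2, 9), 10)))
  expect_false(accept_recording(mk(rep(2, 6), 7)))
  per <- c(1, 1, 1, 1, 1, 1, 1, 2)
  cv <- stats::sd(per) / mean(per)          # 0.314 >= 0.25: reject
  expect_false(accept_recording(mk(per, 8)))
  expect_true(accept_recording(mk(per, 8), cv_cutoff = cv + 0.01))
})

test_that("normalisation divides by the reference condition", {
  m <- list(mean_bd = 2, mean_ibi = 3, mean_t = 5, v_amplitude = 0.04,
            na_amplitude = 0.002, na_median = 0.012, pump_amplitude = 0.1,
            pump_median = 0.2)
  expect_equal(unname(normalize_metrics(m, m)), rep(1, 8))
  ref <- m; ref$mean_bd <- 4
  expect_equal(normalize_metrics(m, ref)[["mean_bd"]], 0.5)
  bad <- m; bad$mean_t <- 0
  expect_error(normalize_metrics(m, bad), "zero reference")
})
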