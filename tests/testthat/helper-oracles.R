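## Independent brute-force reference for burst segmentation: a plain
## spike-by-spike walk, structured differently from the package routine.
oracle_segment <- function(times, ibi_threshold = 0.8, min_spikes = 5) {
  if (!length(times)) return(list())
  groups <- list(times[1])
  for (t in times[-1]) {
    g <- groups[[length(groups)]]
    if (t - g[length(g)] > ibi_threshold) {
      groups[[length(groups) + 1]] <- t
    } else {
      groups[[length(groups)]] <- c(g, t)
    }
  }
  Filter(function(g) length(g) >= min_spikes, groups)
}

## random spike train: bursty clusters with occasional undersized groups
random_spike_train <- function(seed) {
  set.seed(seed)
  t <- 0
  times <- numeric(0)
  for (b in seq_len(sample(3:8, 1))) {
    t <- t + stats::runif(1, 0.9, 3)
    n <- sample(1:12, 1)
    isis <- stats::runif(n, 0.02, 0.3)
    times <- c(times, t + cumsum(isis))
    t <- times[length(times)]
  }
  times
}

## synthetic spiking trace: triangular spikelets of the given half-width and
## height riding on a slow baseline, sampled at `fs`
make_spike_trace <- function(spike_times, duration, fs = 2000,
                             height = 0.04, half_width = 0.005,
                             baseline = function(t) rep(-0.05, length(t))) {
  tt <- seq(0, duration, by = 1 / fs)
  v <- baseline(tt)
  for (ts in spike_times) {
    sel <- abs(tt - ts) <= half_width
    v[sel] <- v[sel] + height * (1 - abs(tt[sel] - ts) / half_width)
  }
  as_hn_trace(data.frame(time_s = tt, v_m_V = v,
                         i_nap_nA = -0.1 + 0.05 * sin(2 * pi * tt / 5),
                         i_pump_nA = 0.2 + 0.05 * sin(2 * pi * tt / 5),
                         na_i_M = 0.012 + 0.001 * sin(2 * pi * tt / 5)))
}

## spike times for a regular bursting pattern: `n_bursts` bursts of
## `spikes_per_burst` spikes at `isi` spacing, bursts `period` apart
burst_train <- function(n_bursts = 10, spikes_per_burst = 8, isi = 0.1,
                        period = 3) {
  unlist(lapply(seq_len(n_bursts) - 1, function(b) {
    b * period + isi * seq_len(spikes_per_burst)
  }))
}
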