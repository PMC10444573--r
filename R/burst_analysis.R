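## ---- spike detection -------------------------------------------------------

## indices of strict local maxima (first sample of a plateau counts)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

## topographic prominence of each peak plus its bounding minima indices:
## on each side, scan to the nearest sample higher than the peak (or the
## signal end) and record the minimum in between; prominence is the peak
## height above the higher of the two side minima.
.peak_prominence <- function(x, peaks) {
  n <- length(x)
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]; h <- x[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    j <- i + 1L; rmin <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    prom[k] <- h - max(lmin, rmin)
  }
  prom
}

#' Detect spikes in a voltage trace
#'
#' Spikes are local maxima of the membrane potential whose height exceeds
#' `min_height`.  Height is measured as topographic prominence by default,
#' which is robust to the slow-wave baseline riding under the spikes; an
#' absolute mode (peak value above a fixed potential) is also available.
#' Each spike is returned together with the two local minima bounding it,
#' which the envelope construction needs.
#'
#' @param trace an `hn_trace` (uniformly sampled).
#' @param min_height minimal spike height (V) in `"prominence"` mode.
#' @param mode `"prominence"` or `"absolute"`.
#' @param v_abs peak threshold (V) used in `"absolute"` mode.
#' @return an `hn_spikes` data frame: `time_s`, `peak_V`, `t_min_left`,
#'   `t_min_right` and the corresponding sample indices.  Zero rows when no
#'   spike is found.
#' @export
detect_spikes <- function(trace, min_height = 0.020,
                          mode = c("prominence", "absolute"),
                          v_abs = -0.02) {
  mode <- match.arg(mode)
  if (nrow(trace) == 0) stop("detect_spikes: empty trace")
  v <- trace$v_m_V; tt <- trace$time_s
  pk <- .local_maxima(v)
  keep <- if (mode == "prominence") {
    pk[.peak_prominence(v, pk) >= min_height]
  } else {
    pk[v[pk] >= v_abs]
  }
  mins <- .local_maxima(-v)
  lidx <- ridx <- integer(length(keep))
  for (k in seq_along(keep)) {
    below <- mins[mins < keep[k]]
    above <- mins[mins > keep[k]]
    lidx[k] <- if (length(below)) max(below) else 1L
    ridx[k] <- if (length(above)) min(above) else length(v)
  }
  out <- data.frame(time_s = tt[keep], peak_V = v[keep],
                    t_min_left = tt[lidx], t_min_right = tt[ridx],
                    idx = keep, idx_min_left = lidx, idx_min_right = ridx)
  class(out) <- c("hn_spikes", class(out))
  out
}

## ---- burst segmentation ----------------------------------------------------

#' Segment a spike train into bursts
#'
#' Interspike intervals longer than `ibi_threshold` delimit candidate
#' bursts.  A candidate with fewer than `min_spikes` spikes is discarded and
#' its time span, together with the two long intervals flanking it, is
#' concatenated into a single interburst interval.  Each interburst
#' interval is assigned to the burst preceding it.
#'
#' @param spikes an `hn_spikes` (or anything with sorted `time_s`).
#' @param ibi_threshold interspike-interval cutoff (s).
#' @param min_spikes minimal number of spikes per burst.
#' @return an `hn_bursts` list with `bursts` (data frame: `t_first`,
#'   `t_last`, `n_spikes`, `t_median`, `bd`) and `ibis` (data frame:
#'   `start`, `end`, `duration`, row i belonging to burst i).
#' @export
segment_bursts <- function(spikes, ibi_threshold = 0.8, min_spikes = 5) {
  st <- spikes$time_s
  stopifnot(!is.unsorted(st, strictly = TRUE))
  groups <- if (length(st)) {
    split(st, cumsum(c(1, diff(st) > ibi_threshold)))
  } else {
    list()
  }
  keep <- vapply(groups, length, 0L) >= min_spikes
  groups <- groups[keep]  # discarded spans merge into the surrounding IBI
  bursts <- data.frame(
    t_first = vapply(groups, function(g) g[1], 0),
    t_last = vapply(groups, function(g) g[length(g)], 0),
    n_spikes = vapply(groups, length, 0L),
    t_median = vapply(groups, function(g) g[ceiling(length(g) / 2)], 0))
  bursts$bd <- bursts$t_last - bursts$t_first
  row.names(bursts) <- NULL
  if (nrow(bursts) < 2) {
    warning("segment_bursts: fewer than 2 bursts survive segmentation")
    ibis <- data.frame(start = numeric(0), end = numeric(0),
                       duration = numeric(0))
  } else {
    ibis <- data.frame(start = bursts$t_last[-nrow(bursts)],
                       end = bursts$t_first[-1])
    ibis$duration <- ibis$end - ibis$start
  }
  structure(list(bursts = bursts, ibis = ibis, spike_times = st,
                 spikes_per_burst = unname(groups)),
            class = "hn_bursts")
}

## ---- envelope --------------------------------------------------------------

#' Spike-averaged envelope of the membrane potential
#'
#' Within bursts, the membrane potential is replaced, over the interval
#' between the consecutive minima bounding each spike, by its mean over
#' that interval; between bursts the potential is kept as is.  Works on any
#' trace channel via `channel`.
#'
#' @param trace an `hn_trace`.
#' @param seg an `hn_bursts` from [segment_bursts()].
#' @param spikes the `hn_spikes` used to build `seg`.
#' @param channel trace column to flatten (default the voltage).
#' @return data frame `time_s`, `value`: the envelope waveform, same time
#'   support as `trace`.
#' @export
envelope <- function(trace, seg, spikes, channel = "v_m_V") {
  val <- trace[[channel]]
  in_burst <- rep(FALSE, nrow(spikes))
  for (b in seq_len(nrow(seg$bursts))) {
    in_burst <- in_burst | (spikes$time_s >= seg$bursts$t_first[b] &
                              spikes$time_s <= seg$bursts$t_last[b])
  }
  for (k in which(in_burst)) {
    i <- spikes$idx_min_left[k]:spikes$idx_min_right[k]
    val[i] <- mean(trace[[channel]][i])
  }
  data.frame(time_s = trace$time_s, value = val)
}

## ---- oscillation amplitude / median ----------------------------------------

## local extrema of a slow waveform, keeping only swings of at least
## `min_frac` of the full signal range (guards against plateau jitter)
.slow_extrema <- function(x, min_frac = 0.25) {
  rng <- diff(range(x))
  if (rng == 0) return(list(peaks = integer(0), troughs = integer(0)))
  thr <- min_frac * rng
  pk <- .local_maxima(x); pk <- pk[.peak_prominence(x, pk) >= thr]
  tr <- .local_maxima(-x); tr <- tr[.peak_prominence(-x, tr) >= thr]
  list(peaks = pk, troughs = tr)
}

#' Per-cycle oscillation amplitudes and backside medians
#'
#' Detects the peaks and troughs of a slow oscillatory signal (an envelope
#' waveform or a [Na+]_i / pump-current trace channel) and returns the
#' pairwise peak-minus-subsequent-trough amplitudes, their mean, and the
#' median of the waveform's backside (the samples from each maximum to the
#' following minimum), averaged across cycles.
#'
#' @param x numeric signal, or a data frame with a `value` column (an
#'   envelope waveform).
#' @param time optional time base (unused in the computation, accepted for
#'   interface symmetry).
#' @param min_frac minimal swing, as a fraction of the signal range, for an
#'   extremum to count as a cycle peak or trough.
#' @return list with `amplitudes`, `mean_amplitude`, `median_value`.
#' @export
oscillation_stats <- function(x, time = NULL, min_frac = 0.25) {
  if (is.data.frame(x)) x <- x$value
  ex <- .slow_extrema(x, min_frac)
  pk <- ex$peaks; tr <- ex$troughs
  amps <- meds <- numeric(0)
  for (i in pk) {
    nxt <- tr[tr > i]
    if (!length(nxt)) break
    j <- nxt[1]
    amps <- c(amps, x[i] - x[j])
    meds <- c(meds, stats::median(x[i:j]))
  }
  if (!length(amps)) stop("oscillation_stats: no peak/trough pair found")
  list(amplitudes = amps, mean_amplitude = mean(amps),
       median_value = mean(meds))
}

## ---- cycle metrics ---------------------------------------------------------

#' Per-cycle burst metrics of a trace
#'
#' Combines the segmentation with the envelope and oscillation statistics
#' into the full set of bursting characteristics: burst durations,
#' interburst intervals, cycle periods (median spike of one burst to median
#' spike of the next, assigned to the first), intraburst spike frequencies
#' (the instantaneous frequency of a spike is 1/ISI of the interval
#' following it; the last spike of a burst has none), envelope voltage
#' amplitude, [Na+]_i amplitude and backside median, pump-current amplitude
#' and backside median, and coefficients of variation.
#'
#' @param trace an `hn_trace`.
#' @param seg an `hn_bursts`.
#' @param spikes the `hn_spikes` used to build `seg`; re-detected from
#'   `trace` when omitted.
#' @return an `hn_cycle_metrics` list.
#' @export
cycle_metrics <- function(trace, seg, spikes = NULL) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  b <- seg$bursts
  if (nrow(b) < 2) stop("cycle_metrics: need at least 2 bursts")
  t_cycle <- diff(b$t_median)
  freqs <- unlist(lapply(seg$spikes_per_burst, function(g) {
    if (length(g) >= 2) 1 / diff(g) else numeric(0)
  }))
  env <- envelope(trace, seg, spikes)
  v_stats <- oscillation_stats(env$value)
  na_stats <- oscillation_stats(trace$na_i_M)
  pump_stats <- oscillation_stats(trace$i_pump_nA)
  cv <- function(x) stats::sd(x) / mean(x)
  structure(list(
    n_bursts = nrow(b),
    bd = b$bd, ibi = seg$ibis$duration, t_cycle = t_cycle,
    mean_bd = mean(b$bd), mean_ibi = mean(seg$ibis$duration),
    mean_t = mean(t_cycle),
    spike_freq = mean(freqs), inst_freq = freqs,
    v_amplitude = v_stats$mean_amplitude,
    na_amplitude = na_stats$mean_amplitude,
    na_median = na_stats$median_value,
    pump_amplitude = pump_stats$mean_amplitude,
    pump_median = pump_stats$median_value,
    cv_t = cv(t_cycle), cv_bd = cv(b$bd),
    cv_ibi = cv(seg$ibis$duration)),
    class = "hn_cycle_metrics")
}

#' Acceptance rule for a bursting recording
#'
#' A recording enters the analysis only with at least `min_bursts`
#' consecutive bursts and a cycle-period coefficient of variation below
#' `cv_cutoff`.
#'
#' @param metrics an `hn_cycle_metrics`.
#' @param cv_cutoff CV threshold (recordings at or above it are rejected).
#' @param min_bursts minimal number of bursts.
#' @return `TRUE` or `FALSE`.
#' @export
accept_recording <- function(metrics, cv_cutoff = 0.25, min_bursts = 8) {
  metrics$n_bursts >= min_bursts && metrics$cv_t < cv_cutoff
}

#' Normalise burst metrics by a reference condition
#'
#' Element-wise division of the scalar dependent variables (mean BD, IBI,
#' period, amplitudes and medians) by the corresponding values of a
#' reference condition, as done within each experiment against the
#' reference setting (injected pump maximum 0.3 nA, injected persistent
#' Na+ conductance 6 nS).
#'
#' @param metrics,reference `hn_cycle_metrics` objects.
#' @return named vector of normalised values.
#' @export
normalize_metrics <- function(metrics, reference) {
  fields <- c("mean_bd", "mean_ibi", "mean_t", "v_amplitude",
              "na_amplitude", "na_median", "pump_amplitude", "pump_median")
  ref <- unlist(reference[fields])
  if (any(ref == 0)) stop("normalize_metrics: zero reference value")
  unlist(metrics[fields]) / ref
}
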