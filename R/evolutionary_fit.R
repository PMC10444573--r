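#' Per-condition bursting summaries of the reduced model
#'
#' Simulates the reduced model at each maximal pump current and extracts
#' the summary quantities entering the fitting cost: burst duration and
#' interburst interval at the -45 mV threshold, and the peak and trough of
#' the membrane potential and [Na+]_i waveforms at steady state.
#'
#' @param params an [reduced_model_params()] object.
#' @param imax_list maximal pump currents (nA), one condition each.
#' @param duration,transient per-condition simulation length and discarded
#'   transient (s).
#' @return data frame with one row per condition: `i_pump_max`, `bd`,
#'   `ibi`, `v_peak`, `v_trough`, `na_peak`, `na_trough`.
#' @export
summarize_bursting <- function(params, imax_list, duration = 40,
                               transient = 15) {
  do.call(rbind, lapply(imax_list, function(imax) {
    p <- params; p$i_pump_max <- imax
    tr <- simulate_2d(p, duration)
    m <- measure_2d_cycle(tr, transient = transient)
    win <- tr[tr$time_s >= transient, ]
    data.frame(i_pump_max = imax, bd = m$bd, ibi = m$ibi,
               v_peak = max(win$v_m_V), v_trough = min(win$v_m_V),
               na_peak = max(win$na_i_M), na_trough = min(win$na_i_M))
  }))
}

#' Fitting cost between simulated and target bursting summaries
#'
#' Sum over conditions of the squared burst-duration and interburst
#' interval differences plus the mean squared peak/trough differences of
#' the membrane potential and of [Na+]_i (each waveform pair averaged over
#' its two terms).  Units are summed as they stand (s^2, V^2, M^2);
#' `weights` can rescale the four term groups.
#'
#' @param sim,target data frames as from [summarize_bursting()], with
#'   identical `i_pump_max` condition sets.
#' @param weights length-4 multipliers for the BD, IBI, voltage and
#'   [Na+]_i term groups.
#' @return scalar cost (0 for a perfect match).
#' @export
fit_cost <- function(sim, target, weights = c(1, 1, 1, 1)) {
  if (!isTRUE(all.equal(sort(sim$i_pump_max), sort(target$i_pump_max)))) {
    stop("fit_cost: condition sets differ between sim and target")
  }
  s <- sim[order(sim$i_pump_max), ]
  tg <- target[order(target$i_pump_max), ]
  sum(weights[1] * (tg$bd - s$bd)^2 +
        weights[2] * (tg$ibi - s$ibi)^2 +
        weights[3] * ((tg$v_peak - s$v_peak)^2 +
                        (tg$v_trough - s$v_trough)^2) / 2 +
        weights[4] * ((tg$na_peak - s$na_peak)^2 +
                        (tg$na_trough - s$na_trough)^2) / 2)
}

## parameters the evolutionary algorithm targets (native-cell variability)
.ea_default_params <- c("g_leak_na", "g_leak_k", "g_h", "g_naf",
                        "g_nap_native", "b_mnapn", "a_mnapn",
                        "g_k2", "b_mk2")

#' Mutate a parameter vector
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `scale` times the absolute parameter value to each entry; proposals
#' that would make a conductance (`g_`-prefixed entries) non-positive are
#' resampled.
#'
#' @param values named numeric parameter vector.
#' @param scale relative noise scale (default 2.5%).
#' @return mutated vector, same names.
#' @export
mutate_params <- function(values, scale = 0.025) {
  if (scale == 0) return(values)
  out <- values
  for (nm in names(values)) {
    repeat {
      prop <- values[[nm]] + stats::rnorm(1, 0, scale * abs(values[[nm]]))
      if (!startsWith(nm, "g_") || prop > 0) break
    }
    out[[nm]] <- prop
  }
  out
}

#' Elitist evolutionary fit of the reduced model
#'
#' Fits the native-current parameters of the reduced model to a target set
#' of per-condition bursting summaries.  Each generation consists of
#' `pop` mutants of the current best individual (2.5% relative Gaussian
#' noise by default); the individual with the smallest [fit_cost()] is
#' carried over, so the best cost is non-increasing.  Individuals whose
#' simulation fails or produces no oscillation get infinite cost.
#'
#' @param target data frame as from [summarize_bursting()] (the
#'   experimental or self-generated summaries to match).
#' @param base an [reduced_model_params()] object: the starting canonical
#'   set; injected-current parameters are never touched.
#' @param pop population size per generation (>= 2).
#' @param generations number of generations (>= 1).
#' @param scale relative mutation scale.
#' @param seed integer seed (the whole run is reproducible).
#' @param param_names names of the parameters to optimise.
#' @param duration,transient per-evaluation simulation settings (s).
#' @param weights passed to [fit_cost()].
#' @param patience,min_improve stop early when the best cost improves by
#'   less than `min_improve` over `patience` generations.
#' @return list with `best_params` (full parameter object), `best_values`
#'   (named vector of the optimised entries), `best_cost`, `cost_history`
#'   (best-ever cost per generation, non-increasing) and `config`.
#' @export
evolve <- function(target, base, pop = 16, generations = 100,
                   scale = 0.025, seed = 1,
                   param_names = .ea_default_params,
                   duration = 40, transient = 15,
                   weights = c(1, 1, 1, 1),
                   patience = 15, min_improve = 1e-6) {
  stopifnot(pop >= 2, generations >= 1, scale > 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)
  conds <- target$i_pump_max
  eval_cost <- function(values) {
    p <- base
    p[names(values)] <- as.list(values)
    tryCatch(
      fit_cost(summarize_bursting(p, conds, duration, transient),
               target, weights),
      error = function(e) Inf)
  }
  best_values <- unlist(base[param_names])
  best_cost <- eval_cost(best_values)
  history <- numeric(generations)
  for (gen in seq_len(generations)) {
    for (i in seq_len(pop)) {
      cand <- mutate_params(best_values, scale)
      cost <- eval_cost(cand)
      if (cost < best_cost) {
        best_cost <- cost
        best_values <- cand
      }
    }
    history[gen] <- best_cost
    if (gen > patience &&
          history[gen - patience] - best_cost < min_improve) {
      history <- history[seq_len(gen)]
      break
    }
  }
  best_params <- base
  best_params[names(best_values)] <- as.list(best_values)
  list(best_params = best_params, best_values = best_values,
       best_cost = best_cost, cost_history = history,
       config = list(pop = pop, generations = generations, scale = scale,
                     seed = seed, param_names = param_names,
                     duration = duration, transient = transient))
}
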