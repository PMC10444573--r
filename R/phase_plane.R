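## ---- nullclines ------------------------------------------------------------

## all roots in nai of fun(V, nai) for one V: sign-change scan over a
## log-spaced grid refined by uniroot (bisection/secant) to ~1e-12 M
.roots_in_na <- function(fun, V, na_range = c(1e-4, 0.1), n_scan = 2000) {
  na <- exp(seq(log(na_range[1]), log(na_range[2]), length.out = n_scan))
  f <- fun(rep(V, n_scan), na)
  s <- which(f[-n_scan] * f[-1] <= 0 & f[-n_scan] != 0)
  vapply(s, function(i) {
    stats::uniroot(function(x) fun(V, x), c(na[i], na[i + 1]),
                   tol = 1e-12)$root
  }, 0)
}

.nullcline_build <- function(fun, params, v_grid, kind) {
  pts <- do.call(rbind, lapply(v_grid, function(V) {
    r <- .roots_in_na(function(v, n) fun(v, n, params), V)
    if (!length(r)) return(NULL)
    data.frame(v_m = V, na_i = sort(r))
  }))
  if (is.null(pts) || nrow(pts) == 0) {
    stop("nullcline: no roots found anywhere on the voltage grid ",
         "(degenerate parameters)")
  }
  pts$branch <- NA_character_
  ext <- .curve_extrema(pts$na_i)
  if (length(ext) == 2 && !anyDuplicated(pts$v_m)) {
    pts$branch <- c(rep("lower", ext[1]),
                    rep("middle", ext[2] - ext[1]),
                    rep("upper", nrow(pts) - ext[2]))
  }
  structure(list(points = pts, kind = kind, params = params),
            class = "hn_nullcline")
}

## indices of interior local extrema along a curve ordinate
.curve_extrema <- function(y) {
  idx <- which(diff(sign(diff(y))) != 0) + 1L
  idx[idx > 1 & idx < length(y)]
}

#' V-nullcline of the reduced model
#'
#' The set of states at which the inward and outward membrane currents
#' balance exactly (total current zero).  For each voltage on `v_grid`,
#' every root in [Na+]_i of the total-current balance is located by a
#' sign-change scan over a log-spaced concentration grid and refined by
#' bisection; for the published parameters the curve is single-valued in
#' [Na+]_i per voltage and z-shaped along the curve, with its branches
#' tagged `lower` (hyperpolarised, stable), `middle` (unstable) and
#' `upper` (depolarised, stable).
#'
#' @param params an [reduced_model_params()] object.
#' @param v_grid voltages (V) to scan; spans the physiological range by
#'   default.
#' @return an `hn_nullcline`: list with `points` (data frame `v_m`,
#'   `na_i`, `branch`) and metadata.
#' @export
v_nullcline <- function(params,
                        v_grid = seq(-0.075, 0.005, length.out = 1601)) {
  .nullcline_build(.total_current_2d, params, v_grid, kind = "v")
}

#' [Na+]_i-nullcline of the reduced model
#'
#' The set of states at which the inward and outward Na+ fluxes balance
#' (total Na+-carrying current, with the pump counted three times, zero).
#'
#' @inheritParams v_nullcline
#' @return an `hn_nullcline`.
#' @export
na_nullcline <- function(params,
                         v_grid = seq(-0.075, 0.005, length.out = 1601)) {
  .nullcline_build(.total_na_flux_2d, params, v_grid, kind = "na")
}

## ---- knees and fixed points ------------------------------------------------

#' Knee (fold) points of the V-nullcline
#'
#' The two local extrema of [Na+]_i along the z-shaped curve, refined by a
#' parabolic fit through each extremal point and its two neighbours.  The
#' knees bound the [Na+]_i range of the relaxation oscillation.
#'
#' @param curve an `hn_nullcline` from [v_nullcline()].
#' @return list with `lower` and `upper`, each `c(v_m, na_i)`: the lower
#'   (hyperpolarised, minimal [Na+]_i) and upper (depolarised, maximal
#'   [Na+]_i) knees.
#' @export
knee_points <- function(curve) {
  pts <- curve$points
  ext <- .curve_extrema(pts$na_i)
  if (length(ext) != 2) {
    stop("knee_points: expected a z-shaped curve with exactly 2 folds, ",
         "found ", length(ext))
  }
  refine <- function(i) {
    ## closed-form parabola through the extremal point and its neighbours,
    ## in coordinates centred on the extremal point (well conditioned)
    v <- pts$v_m[(i - 1):(i + 1)]; y <- pts$na_i[(i - 1):(i + 1)]
    d1 <- v[1] - v[2]; d3 <- v[3] - v[2]
    cc <- (d3 * (y[1] - y[2]) - d1 * (y[3] - y[2])) /
      (d1^2 * d3 - d3^2 * d1)
    bb <- ((y[1] - y[2]) - cc * d1^2) / d1
    if (!is.finite(cc) || cc == 0) {
      return(c(v_m = v[2], na_i = y[2]))
    }
    c(v_m = v[2] - bb / (2 * cc), na_i = y[2] - bb^2 / (4 * cc))
  }
  k1 <- refine(ext[1]); k2 <- refine(ext[2])
  if (k1[["na_i"]] < k2[["na_i"]]) {
    list(lower = k1, upper = k2)
  } else {
    list(lower = k2, upper = k1)
  }
}

#' Fixed points of the reduced model
#'
#' Intersections of the V- and [Na+]_i-nullclines, located by a
#' sign-change scan of the Na+ flux balance along the V-nullcline and
#' refined by bisection in voltage.  Each fixed point is annotated with
#' the V-nullcline branch it lies on; an intersection on the middle
#' (repelling) branch is an unstable stationary state surrounded by the
#' limit cycle, the configuration that sustains bursting.
#'
#' @param params an [reduced_model_params()] object.
#' @param vnc optional precomputed [v_nullcline()].
#' @return data frame `v_m`, `na_i`, `branch` (possibly zero rows).
#' @export
fixed_points <- function(params, vnc = v_nullcline(params)) {
  pts <- vnc$points
  res <- .total_na_flux_2d(pts$v_m, pts$na_i, params)
  hits <- which(res[-length(res)] * res[-1] <= 0 & res[-length(res)] != 0)
  out <- do.call(rbind, lapply(hits, function(i) {
    v_star <- stats::uniroot(function(v) {
      na <- .roots_in_na(function(vv, nn) .total_current_2d(vv, nn, params),
                         v)[1]
      .total_na_flux_2d(v, na, params)
    }, c(pts$v_m[i], pts$v_m[i + 1]), tol = 1e-12)$root
    na_star <- .roots_in_na(function(vv, nn) {
      .total_current_2d(vv, nn, params)
    }, v_star)[1]
    data.frame(v_m = v_star, na_i = na_star, branch = pts$branch[i])
  }))
  if (is.null(out)) {
    out <- data.frame(v_m = numeric(0), na_i = numeric(0),
                      branch = character(0))
  }
  out
}

## ---- slow-branch sampling and timing estimates -----------------------------

#' Sample the stable V-nullcline branches between the knees
#'
#' Places `n` points per branch at the midpoints of `n` equal [Na+]_i
#' cells spanning the inter-knee range (strictly between the knees, since
#' the flux vanishes nowhere on the open branches but the fold points
#' themselves are degenerate).  The voltage of each point is interpolated
#' along the branch and the local [Na+]_i speed evaluated from the Na+
#' flux balance.
#'
#' @param vnc an [v_nullcline()].
#' @param knees a [knee_points()] result.
#' @param n points per branch.
#' @param params the [reduced_model_params()] object used for `vnc`.
#' @return list with data frames `depolarized` and `hyperpolarized`
#'   (`na_i`, `v_m`, `speed` in M/s) and the cell width `dna` (M).
#' @export
branch_samples <- function(vnc, knees, n = 100, params = vnc$params) {
  na_lo <- knees$lower[["na_i"]]; na_hi <- knees$upper[["na_i"]]
  amp <- na_hi - na_lo
  mids <- na_lo + (seq_len(n) - 0.5) * amp / n
  one_branch <- function(tag) {
    br <- vnc$points[!is.na(vnc$points$branch) & vnc$points$branch == tag,
                     c("v_m", "na_i")]
    if (nrow(br) < 2) stop("branch_samples: branch '", tag, "' missing")
    ## each stable branch terminates at its fold: append the refined knee
    kn <- if (tag == "upper") knees$upper else knees$lower
    br <- rbind(br, data.frame(v_m = kn[["v_m"]], na_i = kn[["na_i"]]))
    br <- br[order(br$na_i), ]
    v <- stats::approx(br$na_i, br$v_m, xout = mids, ties = "ordered")$y
    if (any(is.na(v))) {
      stop("branch_samples: branch '", tag,
           "' does not span the inter-knee range")
    }
    data.frame(na_i = mids, v_m = v,
               speed = -.total_na_flux_2d(v, mids, params) / params$v_f)
  }
  list(depolarized = one_branch("upper"),
       hyperpolarized = one_branch("lower"),
       dna = amp / n)
}

#' Nullcline-based estimate of burst duration and interburst interval
#'
#' Integrates the slow motion along the stable branches: the inter-knee
#' [Na+]_i amplitude is divided into the sampled cells and each cell
#' contributes its width over the local |d[Na+]_i/dt| (midpoint rule).
#' The depolarised branch yields the burst duration, the hyperpolarised
#' branch the interburst interval.
#'
#' @param samples a [branch_samples()] result.
#' @return list with `bd` and `ibi` (s).
#' @export
approx_bd_ibi <- function(samples) {
  if (any(samples$depolarized$speed == 0) ||
        any(samples$hyperpolarized$speed == 0)) {
    stop("approx_bd_ibi: zero [Na+]_i speed on a branch (fixed point)")
  }
  list(bd = sum(samples$dna / abs(samples$depolarized$speed)),
       ibi = sum(samples$dna / abs(samples$hyperpolarized$speed)))
}

#' Relative change of [Na+]_i amplitude and branch speeds across a pump sweep
#'
#' For each maximal pump current in `imax_list`, computes the inter-knee
#' [Na+]_i amplitude and the mean |d[Na+]_i/dt| over the sampled points of
#' the depolarised (burst) and hyperpolarised (interburst) branches, each
#' divided by its value at the first (reference) pump setting.
#'
#' @param params an [reduced_model_params()] object (the pump maximum is
#'   overridden per condition).
#' @param imax_list sorted maximal pump currents (nA); the first is the
#'   reference.
#' @param n points per branch.
#' @return data frame `i_pump_max`, `d_amplitude`, `d_burst_speed`,
#'   `d_ibi_speed` (first row all ones), plus the absolute columns
#'   `amplitude`, `burst_speed`, `ibi_speed`.
#' @export
sweep_relative_change <- function(params, imax_list, n = 100) {
  rows <- lapply(imax_list, function(imax) {
    p <- params; p$i_pump_max <- imax
    vnc <- v_nullcline(p)
    kn <- knee_points(vnc)
    bs <- branch_samples(vnc, kn, n = n, params = p)
    data.frame(i_pump_max = imax,
               amplitude = kn$upper[["na_i"]] - kn$lower[["na_i"]],
               burst_speed = mean(abs(bs$depolarized$speed)),
               ibi_speed = mean(abs(bs$hyperpolarized$speed)))
  })
  out <- do.call(rbind, rows)
  out$d_amplitude <- out$amplitude / out$amplitude[1]
  out$d_burst_speed <- out$burst_speed / out$burst_speed[1]
  out$d_ibi_speed <- out$ibi_speed / out$ibi_speed[1]
  out
}

#' Simulated and nullcline-approximated timings across a pump sweep
#'
#' For each maximal pump current, simulates the reduced model and measures
#' burst duration and interburst interval at the -45 mV threshold, and
#' computes the nullcline-based estimates of both; also reports the mean
#' relative error between the two routes across the sweep.
#'
#' @param params an [reduced_model_params()] object.
#' @param imax_list maximal pump currents (nA).
#' @param duration,transient simulation length and discarded transient (s).
#' @param n points per branch for the estimates.
#' @return list with `table` (data frame `i_pump_max`, `bd_sim`,
#'   `bd_approx`, `ibi_sim`, `ibi_approx`) and `mean_rel_error_pct`.
#' @export
timing_sweep <- function(params, imax_list, duration = 80, transient = 20,
                         n = 100) {
  rows <- lapply(imax_list, function(imax) {
    p <- params; p$i_pump_max <- imax
    m <- measure_2d_cycle(simulate_2d(p, duration), transient = transient)
    vnc <- v_nullcline(p)
    ap <- approx_bd_ibi(branch_samples(vnc, knee_points(vnc), n = n,
                                       params = p))
    data.frame(i_pump_max = imax, bd_sim = m$bd, bd_approx = ap$bd,
               ibi_sim = m$ibi, ibi_approx = ap$ibi,
               n_cycles = m$n_cycles)
  })
  tab <- do.call(rbind, rows)
  rel <- c(abs(tab$bd_sim - tab$bd_approx) / tab$bd_sim,
           abs(tab$ibi_sim - tab$ibi_approx) / tab$ibi_sim)
  list(table = tab, mean_rel_error_pct = 100 * mean(rel))
}
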