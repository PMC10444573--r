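p02 <- reduced_model_params(i_pump_max = 0.2)
p09 <- reduced_model_params(i_pump_max = 0.9)
vnc02 <- v_nullcline(p02)
vnc09 <- v_nullcline(p09)

test_that("nullcline points satisfy their defining balances", {
  res_v <- hnburst:::.total_current_2d(vnc02$points$v_m, vnc02$points$na_i,
                                       p02)
  expect_lt(max(abs(res_v)), 1e-6)
  nnc <- na_nullcline(p02)
  res_na <- hnburst:::.total_na_flux_2d(nnc$points$v_m, nnc$points$na_i, p02)
  expect_lt(max(abs(res_na)), 1e-6)
  # single-valued in [Na+]_i per voltage for the published parameters
  expect_false(anyDuplicated(nnc$points$v_m) > 0)
  expect_false(anyDuplicated(vnc02$points$v_m) > 0)
})

test_that("nullclines agree with a brute-force sign map of the balances", {
  p <- p02
  na_grid <- exp(seq(log(1e-3), log(0.05), length.out = 400))
  for (V in seq(-0.07, 0, by = 0.01)) {
    f <- hnburst:::.total_current_2d(rep(V, 400), na_grid, p)
    flips <- which(f[-400] * f[-1] < 0)
    pts <- vnc02$points$na_i[abs(vnc02$points$v_m - V) < 1e-9]
    # same number of roots, each inside its bracketing grid cell
    expect_equal(length(pts), length(flips))
    for (k in seq_along(flips)) {
      expect_gte(pts[k], na_grid[flips[k]])
      expect_lte(pts[k], na_grid[flips[k] + 1])
    }
  }
})

test_that("raising the pump maximum shifts the curve to lower [Na+]_i", {
  # compare [Na+]_i at matched voltages across the two curves
  shared <- intersect(round(vnc02$points$v_m, 10), round(vnc09$points$v_m, 10))
  na02 <- vnc02$points$na_i[match(shared, round(vnc02$points$v_m, 10))]
  na09 <- vnc09$points$na_i[match(shared, round(vnc09$points$v_m, 10))]
  expect_true(all(na09 < na02))
})

test_that("knee detection recovers analytic fold points of a synthetic curve", {
  v <- seq(-1, 1, by = 2e-4)
  # cubic with extrema at v = +/- 0.5: na = v^3/3 - 0.25 v + 0.6
  na <- v^3 / 3 - 0.25 * v + 0.6
  fake <- structure(list(points = data.frame(v_m = v, na_i = na,
                                             branch = NA),
                         kind = "v", params = NULL),
                    class = "hn_nullcline")
  kn <- knee_points(fake)
  expect_equal(kn$upper[["v_m"]], -0.5, tolerance = 1e-6)
  expect_equal(kn$lower[["v_m"]], 0.5, tolerance = 1e-6)
  expect_equal(kn$upper[["na_i"]], 0.6 + 0.25 / 3, tolerance = 1e-9)
  expect_equal(kn$lower[["na_i"]], 0.6 - 0.25 / 3, tolerance = 1e-9)
  mono <- structure(list(points = data.frame(v_m = v, na_i = exp(v),
                                             branch = NA)),
                    class = "hn_nullcline")
  expect_error(knee_points(mono), "2 folds")
})

test_that("inter-knee distance shrinks and knees are grid-converged", {
  k02 <- knee_points(vnc02)
  k09 <- knee_points(vnc09)
  d02 <- k02$upper[["na_i"]] - k02$lower[["na_i"]]
  d09 <- k09$upper[["na_i"]] - k09$lower[["na_i"]]
  expect_lt(d09, d02)
  # doubling the voltage grid density moves the knees by < 0.1%
  vnc_fine <- v_nullcline(p02, seq(-0.075, 0.005, length.out = 3201))
  kf <- knee_points(vnc_fine)
  expect_lt(abs(kf$upper[["na_i"]] - k02$upper[["na_i"]]) / d02, 1e-3)
  expect_lt(abs(kf$lower[["na_i"]] - k02$lower[["na_i"]]) / d02, 1e-3)
})

test_that("the knees bracket the simulated limit cycle's [Na+]_i excursion", {
  kn <- knee_points(vnc02)
  tr <- simulate_2d(p02, 60)
  w <- tr[tr$time_s >= 20, ]
  # the fast jumps overshoot the folds slightly (finite time-scale
  # separation): the knee concentrations match the excursion to 5%, and
  # the overshoot stays a small fraction of the inter-knee amplitude
  amp_knee <- kn$upper[["na_i"]] - kn$lower[["na_i"]]
  expect_lt(abs(min(w$na_i_M) - kn$lower[["na_i"]]) / kn$lower[["na_i"]],
            0.05)
  expect_lt(abs(max(w$na_i_M) - kn$upper[["na_i"]]) / kn$upper[["na_i"]],
            0.05)
  expect_lt(abs(min(w$na_i_M) - kn$lower[["na_i"]]), 0.10 * amp_knee)
  expect_lt(abs(max(w$na_i_M) - kn$upper[["na_i"]]), 0.10 * amp_knee)
})

test_that("the oscillatory regime has one unstable fixed point on the middle branch", {
  fp <- fixed_points(reduced_model_params(i_pump_max = 0.3))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$branch, "middle")
  p03 <- reduced_model_params(i_pump_max = 0.3)
  expect_lt(abs(hnburst:::.total_current_2d(fp$v_m, fp$na_i, p03)), 1e-6)
  expect_lt(abs(hnburst:::.total_na_flux_2d(fp$v_m, fp$na_i, p03)), 1e-6)
})

test_that("branch samples are equispaced with correctly signed speeds", {
  kn <- knee_points(vnc02)
  bs <- branch_samples(vnc02, kn, n = 100, params = p02)
  expect_equal(diff(bs$depolarized$na_i),
               rep(bs$dna, 99), tolerance = 1e-9)
  expect_true(all(bs$depolarized$speed > 0))    # Na+ builds during bursts
  expect_true(all(bs$hyperpolarized$speed < 0)) # and drains between them
  # mean branch speeds increase with the pump maximum
  kn9 <- knee_points(vnc09)
  bs9 <- branch_samples(vnc09, kn9, n = 100, params = p09)
  expect_gt(mean(abs(bs9$depolarized$speed)),
            mean(abs(bs$depolarized$speed)))
  expect_gt(mean(abs(bs9$hyperpolarized$speed)),
            mean(abs(bs$hyperpolarized$speed)))
})

test_that("timing estimate is exact for constant speed and grid-insensitive", {
  fake <- list(depolarized = data.frame(na_i = 1:100, speed = 2),
               hyperpolarized = data.frame(na_i = 1:100, speed = -0.5),
               dna = 0.003 / 100)
  est <- approx_bd_ibi(fake)
  expect_equal(est$bd, 0.003 / 2)
  expect_equal(est$ibi, 0.003 / 0.5)
  fake$depolarized$speed[50] <- 0
  expect_error(approx_bd_ibi(fake), "zero")
  # quadrupling the branch sampling changes the relative table < 0.5%
  r100 <- sweep_relative_change(p02, c(0.2, 0.9), n = 100)
  r400 <- sweep_relative_change(p02, c(0.2, 0.9), n = 400)
  for (col in c("d_amplitude", "d_burst_speed", "d_ibi_speed")) {
    expect_lt(max(abs(r400[[col]] - r100[[col]]) / r100[[col]]), 0.005)
  }
})
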