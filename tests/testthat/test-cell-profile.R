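test_that("average_profiles does pointwise means and SDs on a shared grid", {
  z <- 0:30
  p1 <- data.frame(z = z, r = rep(1.3, 31))
  p2 <- data.frame(z = z, r = rep(1.5, 31))
  avg <- average_profiles(list(p1, p2))
  expect_equal(avg$r_mean, rep(1.4, 31))
  expect_equal(avg$r_sd, rep(stats::sd(c(1.3, 1.5)), 31))
  expect_equal(avg$r_sd[1], 0.1414, tolerance = 1e-3)

  same <- average_profiles(rep(list(p1), 5))
  expect_equal(same$r_mean, p1$r)
  expect_equal(same$r_sd, rep(0, 31))
  expect_equal(attr(same, "n_cells"), 5L)

  expect_error(average_profiles(list()), "empty")
  expect_error(average_profiles(list(p1, data.frame(z = 0:29, r = rep(1, 30)))),
               "same z grid")
})

test_that("group means of generated cells track the blurred truth", {
  spec <- cell_scan_spec("control", noise_sd = 0, seed = 1)
  truth <- make_cell_zscan(spec)$truth
  cells <- lapply(1:5, function(i) profile_from_truth(truth, 0.003, seed = i))
  avg <- average_profiles(cells)
  se <- 0.003 / sqrt(5)
  expect_true(all(abs(avg$r_mean - truth$r) < 4 * se))
})

test_that("estimate_thickness finds the plateau onset", {
  spec <- cell_scan_spec("control", noise_sd = 0, seed = 1)
  truth <- make_cell_zscan(spec)$truth
  avg <- average_profiles(list(profile_from_truth(truth)))
  expect_lte(abs(estimate_thickness(avg, 1.363) - 15), 1)

  flat <- average_profiles(list(data.frame(z = 0:30, r = rep(1.363, 31))))
  expect_equal(estimate_thickness(flat, 1.363), 0)

  rising <- average_profiles(list(data.frame(z = 0:30, r = seq(1.3, 1.6, by = 0.01))))
  expect_error(estimate_thickness(rising, 1.363), "plateau")
})

test_that("per-depth t-test handles identical, separated and degenerate groups", {
  expect_equal(per_depth_ttest(c(1.3, 1.31, 1.29), c(1.3, 1.31, 1.29)),
               1, tolerance = 1e-12)
  a <- ramanion:::with_seed(1, stats::rnorm(5, 0, 1))
  b <- ramanion:::with_seed(2, stats::rnorm(5, 10 * 1, 1))  # 10 pooled SDs apart
  expect_lt(per_depth_ttest(a, b), 1e-3)
  expect_equal(per_depth_ttest(rep(1.3, 3), rep(1.3, 4)), 1)
  expect_error(per_depth_ttest(1.3, c(1.2, 1.4)), "at least 2")
})

test_that("delta_profile differences groups and inverts the calibration", {
  cal <- exact_nacl_calibration()
  spec <- cell_scan_spec("control", noise_sd = 0)
  truth <- make_cell_zscan(spec)$truth
  ctrl <- average_profiles(lapply(1:3, function(i) profile_from_truth(truth)))

  dp0 <- delta_profile(ctrl, ctrl, 15, cal)
  expect_true(all(dp0$delta_na == 0))
  expect_true(all(dp0$z > 0 & dp0$z < 15))

  # delta_r = slope * (a + b z) must invert to exactly a + b z
  shifted <- lapply(1:3, function(i) {
    p <- profile_from_truth(truth)
    p$r <- p$r + cal$slope * (2 + 0.5 * p$z)
    p
  })
  trt <- average_profiles(shifted)
  dp <- delta_profile(trt, ctrl, 15, cal)
  expect_equal(dp$delta_na, 2 + 0.5 * dp$z, tolerance = 1e-9)
  expect_true(all(is.finite(dp$p_value)))

  bad <- average_profiles(list(data.frame(z = seq(0, 30, 2), r = rep(1.363, 16))))
  expect_error(delta_profile(trt, bad, 15, cal), "share the z grid")
})

test_that("fit_gradient returns exact lines, flags constants, needs 3 points", {
  cal <- exact_nacl_calibration()
  z <- 0:30
  mk_dp <- function(delta_na) {
    structure(data.frame(z = z[z > 0 & z < 15],
                         delta_r = NA, delta_na = delta_na,
                         p_value = NA, significant = NA),
              class = c("delta_profile", "data.frame"), thickness = 15)
  }
  zin <- z[z > 0 & z < 15]
  up <- fit_gradient(mk_dp(-6.725 + 1.47 * zin))
  expect_equal(up$slope, 1.47, tolerance = 1e-12)
  expect_equal(up$pearson_r, 1, tolerance = 1e-12)
  down <- fit_gradient(mk_dp(5 - 0.8 * zin))
  expect_equal(down$pearson_r, -1, tolerance = 1e-12)

  flat <- fit_gradient(mk_dp(rep(4.3, length(zin))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$pearson_r, 0)
  expect_true(flat$degenerate)

  two <- mk_dp(zin)[1:2, ]
  attr(two, "thickness") <- 15
  expect_error(fit_gradient(two, z_range = c(0, 30)), "at least 3")
})

test_that("mean concentration change equals the analytic line average", {
  const <- list(slope = 0, intercept = 4.3)
  expect_equal(mean_concentration_change(const, 15), 4.3)
  line <- list(slope = 1.47, intercept = -6.725)  # -6.7 at z=0, 15.3 at z=15
  expect_equal(mean_concentration_change(line, 15), 4.3, tolerance = 1e-3)
  expect_error(mean_concentration_change(line, 0), "positive")
  expect_error(mean_concentration_change(line, -3), "positive")
})

test_that("analytic mean matches trapezoidal quadrature to 1e-12", {
  for (par in list(c(-6.725, 1.47, 15), c(2, -0.3, 9.5), c(0.1, 0, 22))) {
    fit <- list(intercept = par[1], slope = par[2]); t <- par[3]
    z <- seq(0, t, length.out = 4001)
    y <- fit$intercept + fit$slope * z
    quad <- sum(diff(z) * (y[-1] + y[-length(y)]) / 2) / t
    expect_equal(mean_concentration_change(fit, t), quad, tolerance = 1e-12)
  }
})

test_that("Fick flux converts the instrument gradient with the stated constants", {
  expect_equal(signif(sodium_flux(1.47, 1.33e-8), 3), 1.95e-10)
  expect_equal(sodium_flux(0), 0)
  expect_equal(sodium_flux(1.47, 2 * 1.33e-8), 2 * sodium_flux(1.47, 1.33e-8))
  expect_error(sodium_flux(NA_real_), "finite")
})

test_that("short-circuit current applies the Faraday constant in uA/cm2", {
  expect_equal(signif(short_circuit_current(1.95e-10), 3), 18.8)
  expect_equal(short_circuit_current(0), 0)
  expect_equal(short_circuit_current(1), 9.6485332e10)
  expect_error(short_circuit_current(Inf), "finite")
})

test_that("the flux chain is linear and sign-consistent in the gradient", {
  mk <- function(g) flux_result(list(slope = g, intercept = 0, pearson_r = 1),
                                t = 15)
  f1 <- mk(1.47); f2 <- mk(2.94); fneg <- mk(-1.47)
  expect_equal(f2$I_sc, 2 * f1$I_sc, tolerance = 1e-12)
  expect_equal(fneg$I_sc, -f1$I_sc, tolerance = 1e-12)
  expect_equal(f1$I_sc, f1$J * f1$F * 1e6)
  expect_equal(f1$gradient_paper_convention, -f1$gradient_instrument)
})
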