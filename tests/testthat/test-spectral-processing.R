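test_that("subtract_baseline removes a known added line", {
  s <- make_water_spectrum(1.4, synth_config(noise_sd = 0,
                                             baseline_intercept = 0,
                                             baseline_slope = 0))
  line <- 3.2 + 0.002 * s$wavenumber
  s_shifted <- raman_spectrum(s$wavenumber, s$intensity + line)
  out <- subtract_baseline(s_shifted)
  ref <- subtract_baseline(s)
  expect_equal(out$intensity, ref$intensity, tolerance = 1e-9)

  # already-zero baseline: anchor means stay ~0 and the spectrum is barely touched
  flat <- raman_spectrum(s$wavenumber, rep(0, length(s$wavenumber)) + 0)
  expect_equal(subtract_baseline(flat)$intensity, flat$intensity,
               tolerance = 1e-12)

  expect_error(subtract_baseline(s, anchors = list(c(100, 200))), "outside")
  expect_error(subtract_baseline(s, anchors = list(c(2400.0, 2400.5))),
               "at least 3")
})

test_that("normalize_total hits the target integral and is idempotent", {
  s <- make_water_spectrum(1.3, synth_config(noise_sd = 0))
  n1 <- normalize_total(s)
  expect_equal(ramanion:::spectrum_integral(n1), 100, tolerance = 1e-9)
  n2 <- normalize_total(n1)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  zero <- raman_spectrum(s$wavenumber, rep(0, length(s$wavenumber)))
  expect_error(normalize_total(zero), "non-positive")
})

test_that("free-shape deconvolution recovers centres and areas of noiseless spectra", {
  cfg <- synth_config(noise_sd = 0)
  s <- normalize_total(subtract_baseline(make_water_spectrum(1.45, cfg)))
  fit <- deconvolve(s, "solution", shape = "free")
  expect_true(fit$converged)
  expect_equal(fit$bands$center, c(3016, 3221, 3429, 3572, 3636),
               tolerance = 1 / 3016)
  truth <- ramanion:::generating_bands(1.45, "solution")
  scale <- sum(fit$bands$area) / sum(truth$area)
  expect_equal(fit$bands$area / scale, truth$area, tolerance = 0.01)
})

test_that("cell-context deconvolution recovers all twelve generating areas", {
  spec <- cell_scan_spec("control", noise_sd = 0, seed = 5)
  scan <- make_cell_zscan(spec)
  i <- which(scan$spectra$z == 1)  # substrate + cytosol + water all present
  s <- normalize_total(subtract_baseline(scan$spectra$spectrum[[i]]))
  fit <- deconvolve(s, "cell", shape = "free")
  truth <- ramanion:::generating_bands(
    scan$truth$r[i], "cell",
    w_cyto = 1, w_substrate = exp(-4 * log(2) / spec$psf_axial_fwhm^2))
  # w_cyto at z=1 is essentially 1 (blurred indicator); compare where area > 0
  scale <- sum(fit$bands$area) / sum(truth$area)
  big <- truth$area > 0.5
  expect_equal(fit$bands$area[big] / scale, truth$area[big], tolerance = 0.02)
  expect_equal(compute_r(fit)$r, scan$truth$r[i], tolerance = 1e-3)
})

test_that("deconvolve rejects spectra that do not span the band set", {
  x <- seq(2400, 3300, by = 1)
  s <- raman_spectrum(x, pseudo_voigt(x, 3016, 170, 0.25))
  expect_error(deconvolve(s, "solution"), "window")
})

test_that("zero-noise fits reproduce the generating parameter vector", {
  cfg <- synth_config(noise_sd = 0, baseline_intercept = 0,
                      baseline_slope = 0)
  truth <- ramanion:::generating_bands(1.363, "solution")
  s <- make_water_spectrum(1.363, cfg)
  fit <- deconvolve(s, "solution", shape = "free")
  expect_equal(fit$bands$area, truth$area, tolerance = 1e-6)
  expect_equal(fit$bands$center, truth$center, tolerance = 1e-6)
})

test_that("compute_r is the DA/DDAA area ratio with degenerate guards", {
  expect_equal(compute_r(fake_band_fit(68.15, 50))$r, 1.363)
  expect_equal(compute_r(fake_band_fit(10, 10))$r, 1)
  expect_error(compute_r(fake_band_fit(10, 0)), "not positive")
})

test_that("r increases with the generating DA area at fixed DDAA", {
  cfg <- synth_config(noise_sd = 0)
  rs <- vapply(c(1.1, 1.3, 1.5, 1.8), function(rt) {
    spectrum_r(make_water_spectrum(rt, cfg))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("r is invariant under positive rescaling of the spectrum", {
  s <- make_water_spectrum(1.42, synth_config(noise_sd = 0.005), seed = 9)
  r1 <- spectrum_r(s)
  for (k in c(0.01, 3, 1e4)) {
    sk <- raman_spectrum(s$wavenumber, s$intensity * k)
    expect_equal(spectrum_r(sk), r1, tolerance = 1e-9)
  }
})

test_that("replicate scatter of r shrinks with the noise level", {
  sd_at <- function(noise) {
    rs <- vapply(1:12, function(i) {
      spectrum_r(make_water_spectrum(1.5, synth_config(noise_sd = noise),
                                     seed = 100 + i))
    }, numeric(1))
    stats::sd(rs)
  }
  expect_lt(sd_at(0.002), sd_at(0.02))
})
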