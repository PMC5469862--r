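# Shared fixture builders for the test suite. Everything is generated in
# code; no stored fixtures.

# Exact NaCl calibration object matching the generator's line, for tests
# that need a calibration but not its estimation.
exact_nacl_calibration <- function() {
  tab <- solute_table()
  structure(list(solute = "NaCl", slope = tab$slope[tab$solute == "NaCl"],
                 intercept = default_r0(), slope_se = 0, intercept_se = 0,
                 r_squared = 1, n = 80L, n_concentrations = 4L,
                 axis = "cation", model = NULL),
            class = "r_calibration")
}

# Minimal hand-built band_fit for compute_r arithmetic tests.
fake_band_fit <- function(area_da, area_ddaa) {
  bands <- data.frame(label = c("DDAA", "DA"),
                      center = c(3221, 3429), fwhm = c(230, 200),
                      eta = 0.25, area = c(area_ddaa, area_da),
                      amplitude = NA_real_)
  structure(list(bands = bands, residual_norm = 0, converged = TRUE,
                 context = "solution", metadata = list()),
            class = "band_fit")
}

# Per-cell r(z) profile data.frame from a truth vector (skips refitting).
profile_from_truth <- function(truth, noise_sd = 0, seed = NULL) {
  r <- truth$r
  if (noise_sd > 0) {
    r <- r + if (is.null(seed)) stats::rnorm(length(r), 0, noise_sd) else
      ramanion:::with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
  }
  data.frame(z = truth$z, r = r)
}

# Process one synthetic group of n cells into an averaged profile.
fitted_group_profile <- function(group, n_cells, seed0, noise_sd = 0.005,
                                 ...) {
  cells <- lapply(seq_len(n_cells), function(i) {
    scan <- make_cell_zscan(cell_scan_spec(group, noise_sd = noise_sd,
                                           seed = seed0 + i, ...))
    process_zscan(scan)
  })
  average_profiles(cells, group)
}
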