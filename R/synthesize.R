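#' Synthetic-spectrum generator settings
#'
#' Conditions under which synthetic spectra are produced. Defaults emulate
#' the acquisition used throughout the package: a 2400-4200 1/cm window at
#' 1 1/cm spacing, a weak linear instrument baseline, and additive Gaussian
#' noise whose standard deviation is a fraction of the spectrum maximum.
#'
#' @param wn_min,wn_max,wn_step Wavenumber grid (1/cm).
#' @param noise_sd Noise SD as a fraction of the peak intensity (0.005 =
#'   0.5% of the maximum). Set 0 for noiseless spectra.
#' @param baseline_intercept,baseline_slope Linear baseline added to every
#'   spectrum (counts, counts per 1/cm).
#' @param area_ddaa Generating area of the DDAA reference band; the DA area
#'   is `r * area_ddaa` so the generating area ratio is exactly `r`.
#' @return A list of settings for the `make_*` generators.
#' @export
synth_config <- function(wn_min = 2400, wn_max = 4200, wn_step = 1,
                         noise_sd = 0.005,
                         baseline_intercept = 0.05, baseline_slope = 2e-5,
                         area_ddaa = 50) {
  stopifnot(wn_max > wn_min, wn_step > 0, noise_sd >= 0, area_ddaa > 0)
  list(wn_min = wn_min, wn_max = wn_max, wn_step = wn_step,
       noise_sd = noise_sd,
       baseline_intercept = baseline_intercept,
       baseline_slope = baseline_slope,
       area_ddaa = area_ddaa)
}

# Evaluate a block of code with a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shared spectrum assembly: bands + linear baseline + noise on the config grid.
synth_spectrum <- function(bands, config, seed = NULL, metadata = list()) {
  x <- seq(config$wn_min, config$wn_max, by = config$wn_step)
  if (!length(x)) stop("empty wavenumber grid")
  y <- pv_model(x, bands)
  y <- y + config$baseline_intercept + config$baseline_slope * (x - config$wn_min)
  if (config$noise_sd > 0) {
    sd <- config$noise_sd * max(y)
    noise <- if (is.null(seed)) stats::rnorm(length(x), 0, sd) else
      with_seed(seed, stats::rnorm(length(x), 0, sd))
    y <- y + noise
  }
  raman_spectrum(x, y, metadata)
}

#' Synthesise a water-solution spectrum with a known DA/DDAA ratio
#'
#' Builds the five O-H stretching sub-bands (DAA, DDAA, DA, DDA, free O-H at
#' 3016, 3221, 3429, 3572, 3636 1/cm) as pseudo-Voigt profiles whose
#' generating areas satisfy area(DA)/area(DDAA) = `r_target` exactly, adds a
#' linear baseline and optional Gaussian noise.
#'
#' @param r_target Target DA/DDAA area ratio, > 0.
#' @param config A [synth_config()].
#' @param seed Integer seed; with a fixed seed the output is bit-reproducible.
#' @param metadata Metadata list stored on the spectrum.
#' @return A [raman_spectrum()].
#' @export
make_water_spectrum <- function(r_target, config = synth_config(),
                                seed = NULL, metadata = list()) {
  if (!is.numeric(r_target) || length(r_target) != 1L || r_target <= 0) {
    stop("r_target must be a single positive number")
  }
  bands <- generating_bands(r_target, "solution", area_ddaa = config$area_ddaa)
  synth_spectrum(bands, config, seed,
                 c(metadata, list(r_true = r_target)))
}

#' Per-solute calibration settings of the generated world
#'
#' Concentration series and generating slopes for the eight solute series
#' used to calibrate the ionic-activity index r. Concentrations (mM; protein
#' in mg/mL) follow the standard series design; the slopes are generator
#' conventions ordered so that NaCl and KCl share a slope, MgCl2 and CaCl2
#' share a slope equal to NaCl's per cation (hence half per chloride),
#' NaHCO3 is weakest, and Hepes/glucose/protein are strongest.
#'
#' All series share the pure-water intercept [default_r0()] so that mixture
#' additivity holds exactly in the generated world.
#'
#' @return A data.frame with columns `solute`, `slope` (delta-r per mM, or
#'   per mg/mL for protein) and a list-column `concentrations`.
#' @export
solute_table <- function() {
  data.frame(
    solute = c("NaCl", "KCl", "MgCl2", "CaCl2", "NaHCO3",
               "Hepes", "glucose", "protein"),
    slope  = c(1.0e-3, 1.0e-3, 1.0e-3, 1.0e-3, 0.3e-3,
               2.0e-3, 2.0e-3, 3.0e-3),
    concentrations = I(list(
      c(24, 96, 144, 192), c(24, 96, 144, 192),
      c(24, 48, 96), c(24, 48, 96),
      c(24, 96, 144, 192), c(10, 24, 48, 96),
      c(24, 48, 96), c(10, 50, 100))),
    stringsAsFactors = FALSE
  )
}

#' Pure-water intercept of the generated calibrations
#'
#' Chosen so that the isotonic test buffer ([isotonic_buffer()]) has an
#' additive ratio of exactly 1.363, the extracellular reference value.
#' @return A single number.
#' @export
default_r0 <- function() {
  tab <- solute_table()
  buf <- isotonic_buffer()
  1.363 - sum(tab$slope[match(names(buf), tab$solute)] * buf)
}

#' Isotonic test buffer composition
#'
#' 120 mM NaCl, 3.5 mM KCl, 1 mM CaCl2, 1 mM MgCl2, 5 mM glucose and
#' 10 mM Hepes (pH 7.4), the bathing solution used for the cell scans.
#' @return Named numeric vector of concentrations (mM).
#' @export
isotonic_buffer <- function() {
  c(NaCl = 120, KCl = 3.5, CaCl2 = 1, MgCl2 = 1, glucose = 5, Hepes = 10)
}

#' Generate a calibration series of spectra for one solute
#'
#' For each concentration c in the solute's series, generates `replicates`
#' spectra with target ratio r0 + slope * c.
#'
#' @param solute Solute name from [solute_table()], or a one-row data.frame
#'   with `solute`, `slope` and `concentrations` fields.
#' @param r0 Intercept of the generating line (shared across solutes).
#' @param replicates Spectra per concentration (default 20, the replicate
#'   count used for every solution series).
#' @param config A [synth_config()].
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return A list with `solute`, `slope`, `r0`, and `spectra`: a data.frame
#'   with columns `concentration`, `replicate`, `r_true` and a list-column
#'   `spectrum` of [raman_spectrum()] objects.
#' @export
make_calibration_series <- function(solute, r0 = default_r0(),
                                    replicates = 20L,
                                    config = synth_config(), seed = 1L) {
  if (is.character(solute)) {
    tab <- solute_table()
    row <- tab[tab$solute == solute, ]
    if (!nrow(row)) stop("unknown solute: ", solute)
  } else {
    row <- as.data.frame(solute)
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  conc <- row$concentrations[[1]]
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE)) {
    stop("concentrations must be strictly positive and increasing")
  }
  grid <- expand.grid(replicate = seq_len(replicates), concentration = conc)
  grid <- grid[, c("concentration", "replicate")]
  grid$r_true <- r0 + row$slope * grid$concentration
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(grid)))
  grid$spectrum <- I(lapply(seq_len(nrow(grid)), function(i) {
    make_water_spectrum(grid$r_true[i], config, seed = seeds[i],
                        metadata = list(solute = row$solute,
                                        concentration = grid$concentration[i],
                                        replicate = grid$replicate[i]))
  }))
  list(solute = row$solute, slope = row$slope, r0 = r0, spectra = grid)
}

#' Describe a synthetic confocal z-scan through an epithelial cell
#'
#' @param group "control" or "treated".
#' @param thickness Cell thickness t (micrometres); the apical membrane sits
#'   at z = t above the permeable support (z = 0).
#' @param z Acquisition grid (micrometres), default 0-30 in 1 um steps.
#' @param r_basolateral,r_apical Untreated intracellular r at the basolateral
#'   and apical ends; the control cytosol profile interpolates linearly
#'   between them (r is highest near the basolateral membrane).
#' @param r_extracellular r of the bathing buffer above the apical membrane.
#' @param delta_na_intercept,delta_na_slope Treated-only imposed sodium
#'   concentration change, delta[Na+](z) = intercept + slope * z (mM, with z
#'   in instrument coordinates increasing basolateral -> apical). Defaults
#'   give depletion (-6.725 mM) at the basolateral side rising to +15.3 mM
#'   at a 15 um apical membrane, i.e. a +1.47 mM/um gradient.
#' @param slope_nacl Calibration slope translating delta[Na+] into delta-r.
#' @param psf_axial_fwhm Axial Gaussian PSF FWHM (um) blurring every ideal
#'   z-profile before spectra are synthesised.
#' @param noise_sd,config Noise fraction and spectrum settings ([synth_config()]).
#' @param seed Integer seed.
#' @return A list of class `cell_scan_spec`.
#' @export
cell_scan_spec <- function(group = c("control", "treated"),
                           thickness = 15,
                           z = seq(0, 30, by = 1),
                           r_basolateral = 1.45, r_apical = 1.38,
                           r_extracellular = 1.363,
                           delta_na_intercept = -6.725,
                           delta_na_slope = 1.47,
                           slope_nacl = solute_table()$slope[1],
                           psf_axial_fwhm = 1.14,
                           noise_sd = 0.005,
                           config = synth_config(noise_sd = noise_sd),
                           seed = 1L) {
  group <- match.arg(group)
  if (thickness <= 0 || thickness >= max(z)) {
    stop("thickness must lie inside the z grid")
  }
  if (psf_axial_fwhm <= 0) stop("psf_axial_fwhm must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  config$noise_sd <- noise_sd
  structure(list(group = group, thickness = thickness, z = z,
                 r_basolateral = r_basolateral, r_apical = r_apical,
                 r_extracellular = r_extracellular,
                 delta_na_intercept = delta_na_intercept,
                 delta_na_slope = delta_na_slope,
                 slope_nacl = slope_nacl,
                 psf_axial_fwhm = psf_axial_fwhm,
                 noise_sd = noise_sd, config = config, seed = seed),
            class = "cell_scan_spec")
}

# Gaussian blur of f(z) sampled on a fine grid, constant-extended at the
# edges so plateaus are preserved exactly away from transitions.
blur_profile <- function(z_out, f, fwhm, step = 0.05) {
  if (fwhm < 4 * step) return(f(z_out))  # delta-kernel limit
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  pad <- 5 * sigma
  zf <- seq(min(z_out) - pad, max(z_out) + pad, by = step)
  vals <- f(pmin(pmax(zf, min(z_out)), max(z_out) + pad))
  half <- ceiling(4 * sigma / step)
  kern <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  kern <- kern / sum(kern)
  sm <- stats::filter(vals, kern, sides = 2)
  idx <- !is.na(sm)
  stats::approx(zf[idx], sm[idx], xout = z_out, rule = 2)$y
}

# Ideal (unblurred) r(z) and delta_na(z) for a scan spec.
ideal_profiles <- function(spec) {
  t <- spec$thickness
  r_cyto <- function(z) {
    spec$r_basolateral +
      (spec$r_apical - spec$r_basolateral) * pmin(z, t) / t
  }
  delta_na <- function(z) {
    ifelse(z < t, spec$delta_na_intercept + spec$delta_na_slope * z, 0)
  }
  r_ideal <- function(z) {
    base <- ifelse(z < t, r_cyto(z), spec$r_extracellular)
    if (spec$group == "treated") {
      base <- base + spec$slope_nacl * delta_na(z)
    }
    base
  }
  list(r = r_ideal, delta_na = delta_na)
}

#' Generate a synthetic confocal z-scan of a cell with known ground truth
#'
#' Produces one spectrum per z position. The ideal r(z) profile (cytosolic
#' ramp inside the cell, constant extracellular value above the apical
#' membrane, plus the imposed sodium change for treated cells) is convolved
#' along z with the axial Gaussian PSF before spectrum synthesis. Spectra
#' near z = 0 contain the polycarbonate substrate bands and intracellular
#' spectra contain the lipid/protein C-H bands, both weighted by
#' PSF-consistent depth profiles.
#'
#' @param spec A [cell_scan_spec()].
#' @return A list with `spectra` (data.frame: `z` and list-column
#'   `spectrum`) and `truth` (list: `z`, `r` blurred generating profile,
#'   `r_ideal`, `delta_na` mM, `slope` mM/um, `thickness` um, `group`).
#' @export
make_cell_zscan <- function(spec) {
  stopifnot(inherits(spec, "cell_scan_spec"))
  z <- spec$z
  prof <- ideal_profiles(spec)
  r_blur <- blur_profile(z, prof$r, spec$psf_axial_fwhm)
  t <- spec$thickness
  # substrate visibility: axial PSF amplitude centred on the support surface
  w_pc <- exp(-4 * log(2) * z^2 / spec$psf_axial_fwhm^2)
  # cytosol visibility: blurred indicator of 0 < z < t
  w_cy <- blur_profile(z, function(zz) as.numeric(zz < t), spec$psf_axial_fwhm)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, length(z)))
  spectra <- lapply(seq_along(z), function(i) {
    bands <- generating_bands(r_blur[i], "cell",
                              w_cyto = w_cy[i], w_substrate = w_pc[i],
                              area_ddaa = spec$config$area_ddaa)
    synth_spectrum(bands, spec$config, seeds[i],
                   metadata = list(z = z[i], group = spec$group))
  })
  truth <- list(z = z, r = r_blur, r_ideal = prof$r(z),
                delta_na = prof$delta_na(z),
                slope = if (spec$group == "treated") spec$delta_na_slope else 0,
                intercept = if (spec$group == "treated") spec$delta_na_intercept else 0,
                thickness = t, group = spec$group)
  list(spectra = data.frame(z = z, spectrum = I(spectra)), truth = truth)
}
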