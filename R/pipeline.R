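#' Pipeline configuration
#'
#' Central collection of every tunable parameter of the analysis chain,
#' serialisable to YAML so a run can be reproduced from its config file.
#'
#' @param fit_window Wavenumber window (1/cm) the spectra must span.
#' @param baseline_anchors Anchor windows for [subtract_baseline()].
#' @param normalize_target Total integrated intensity after normalisation.
#' @param r_extracellular Reference buffer ratio for thickness estimation.
#' @param plateau_tol Relative tolerance of the plateau criterion.
#' @param ttest_var_equal Student (TRUE) vs Welch t-test per depth.
#' @param p_adjust Per-depth p-value adjustment method ("none" = raw).
#' @param gradient_margin Distance (um) from both membranes excluded from
#'   the gradient fit.
#' @param D_Na,Faraday Physical constants, see [transport_constants()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fit_window = c(2400, 4200),
                            baseline_anchors = list(c(2400, 2500), c(4100, 4200)),
                            normalize_target = 100,
                            r_extracellular = 1.363,
                            plateau_tol = 0.01,
                            ttest_var_equal = TRUE,
                            p_adjust = "none",
                            gradient_margin = 1,
                            D_Na = transport_constants()$D_Na,
                            Faraday = transport_constants()$F,
                            seed = 1L) {
  stopifnot(diff(fit_window) > 0, normalize_target > 0, plateau_tol > 0,
            gradient_margin >= 0, D_Na > 0, Faraday > 0)
  structure(list(fit_window = fit_window,
                 baseline_anchors = baseline_anchors,
                 normalize_target = normalize_target,
                 r_extracellular = r_extracellular,
                 plateau_tol = plateau_tol,
                 ttest_var_equal = ttest_var_equal,
                 p_adjust = p_adjust,
                 gradient_margin = gradient_margin,
                 D_Na = D_Na, Faraday = Faraday,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$baseline_anchors <- lapply(raw$baseline_anchors, as.numeric)
  raw$fit_window <- as.numeric(raw$fit_window)
  do.call(pipeline_config, raw)
}

#' Write a z-scan to disk as spectra plus a manifest
#'
#' Each spectrum is written as a two-column CSV; the YAML manifest lists
#' file, z (um), group, cell (replicate id) and seed for every entry.
#'
#' @param scan A [make_cell_zscan()] result.
#' @param dir Output directory (created if needed).
#' @param cell Replicate identifier recorded in the manifest.
#' @param manifest Manifest file name within `dir`.
#' @return Manifest path, invisibly.
#' @export
write_zscan <- function(scan, dir, cell = 1L, manifest = "manifest.yaml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- scan$spectra
  group <- scan$truth$group
  entries <- lapply(seq_len(nrow(df)), function(i) {
    fn <- sprintf("%s_cell%02d_z%05.1f.csv", group, cell, df$z[i])
    write_spectrum(df$spectrum[[i]], file.path(dir, fn))
    list(file = fn, z = df$z[i], group = group, cell = as.integer(cell))
  })
  path <- file.path(dir, manifest)
  existing <- if (file.exists(path)) yaml::read_yaml(path)$entries else list()
  yaml::write_yaml(list(entries = c(existing, entries)), path)
  invisible(path)
}

#' Read a scan manifest and its spectra
#'
#' @param path Manifest YAML path (entries with `file`, `z`, `group`,
#'   `cell`); files are resolved relative to the manifest directory.
#' @return data.frame with columns `z`, `group`, `cell` and list-column
#'   `spectrum`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)$entries
  if (!length(man)) stop("manifest has no entries: ", path)
  base <- dirname(path)
  df <- data.frame(
    z = vapply(man, function(e) as.numeric(e$z), numeric(1)),
    group = vapply(man, function(e) as.character(e$group), character(1)),
    cell = vapply(man, function(e) as.integer(e$cell), integer(1))
  )
  if (any(df$z < 0)) stop("manifest contains negative z positions")
  df$spectrum <- I(lapply(man, function(e) {
    read_spectrum(file.path(base, e$file),
                  metadata = list(z = e$z, group = e$group, cell = e$cell))
  }))
  df
}

#' Write calibrations as a CSV table
#'
#' @param calibrations Named list of [fit_series()] results.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(calibrations, path) {
  rows <- lapply(calibrations, function(cal) {
    data.frame(solute = cal$solute, slope = cal$slope,
               intercept = cal$intercept, slope_se = cal$slope_se,
               intercept_se = cal$intercept_se, r_squared = cal$r_squared,
               n = cal$n, axis = cal$axis)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration table written by [write_calibration_table()]
#'
#' @param path CSV path.
#' @return Named list of `r_calibration` objects (without `model`).
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cals <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(solute = df$solute[i], slope = df$slope[i],
                   intercept = df$intercept[i], slope_se = df$slope_se[i],
                   intercept_se = df$intercept_se[i],
                   r_squared = df$r_squared[i], n = df$n[i],
                   n_concentrations = NA_integer_, axis = df$axis[i],
                   model = NULL),
              class = "r_calibration")
  })
  names(cals) <- df$solute
  cals
}

# group a manifest data.frame into per-cell r(z) profiles
profiles_from_manifest <- function(df, config) {
  lapply(split(df, df$cell), function(d) {
    d <- d[order(d$z), ]
    process_zscan(d, anchors = config$baseline_anchors)
  })
}

#' Run the full treated-vs-control analysis
#'
#' Orchestrates the whole chain: per-spectrum baseline subtraction,
#' normalisation and deconvolution; per-cell r(z) profiles; group averages;
#' apical-membrane (thickness) location from the control plateau; cytosolic
#' treated-minus-control differencing with per-depth t-tests; gradient fit;
#' mean concentration change, Fick flux and short-circuit current.
#'
#' @param treated,control Either manifest YAML paths or data.frames as
#'   returned by [read_manifest()].
#' @param cal_nacl NaCl calibration ([fit_series()] result) or the path of
#'   a calibration CSV containing a NaCl row.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for result tables (profiles and delta
#'   profile CSV, flux JSON).
#' @return List with `profile_treated`, `profile_control`, `thickness`
#'   (list: control, treated, used), `delta`, `gradient`, `flux`.
#' @export
run_pipeline <- function(treated, control, cal_nacl,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(cal_nacl)) {
    if (!file.exists(cal_nacl)) stop("calibration file not found: ", cal_nacl)
    tab <- read_calibration_table(cal_nacl)
    if (!"NaCl" %in% names(tab)) stop("calibration table lacks a NaCl row")
    cal_nacl <- tab$NaCl
  }
  if (is.character(treated)) treated <- read_manifest(treated)
  if (is.character(control)) control <- read_manifest(control)

  message("fitting control group (", length(unique(control$cell)), " cells)")
  prof_c <- average_profiles(profiles_from_manifest(control, config), "control")
  message("fitting treated group (", length(unique(treated$cell)), " cells)")
  prof_t <- average_profiles(profiles_from_manifest(treated, config), "treated")

  t_c <- estimate_thickness(prof_c, config$r_extracellular, config$plateau_tol)
  t_t <- estimate_thickness(prof_t, config$r_extracellular, config$plateau_tol)
  # the control crossing is the cleaner thickness estimate: the treated
  # apical ion rise, blurred by the axial PSF, delays the apparent plateau
  t_used <- t_c

  dp <- delta_profile(prof_t, prof_c, t_used, cal_nacl,
                      p_adjust = config$p_adjust,
                      var_equal = config$ttest_var_equal)
  grad <- fit_gradient(dp, z_range = c(config$gradient_margin,
                                       t_used - config$gradient_margin))
  fx <- flux_result(grad, t_used, D = config$D_Na, F = config$Faraday)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(prof_c),
                     file.path(out_dir, "profile_control.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(prof_t),
                     file.path(out_dir, "profile_treated.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(dp),
                     file.path(out_dir, "delta_profile.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(thickness_control = t_c, thickness_treated = t_t,
           thickness_used = t_used,
           gradient_instrument = fx$gradient_instrument,
           gradient_paper_convention = fx$gradient_paper_convention,
           pearson_r = fx$pearson_r,
           mean_delta_conc_mM = fx$mean_delta_conc,
           D_Na = fx$D, Faraday = fx$F,
           J_mol_s_cm2 = fx$J, I_sc_uA_cm2 = fx$I_sc),
      file.path(out_dir, "flux_result.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(profile_treated = prof_t, profile_control = prof_c,
       thickness = list(control = t_c, treated = t_t, used = t_used),
       delta = dp, gradient = grad, flux = fx)
}
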