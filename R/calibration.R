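#' Fit a linear calibration of r against concentration
#'
#' Ordinary least squares of all replicate r values on concentration,
#' r = r0 + s*c. The regression is run on individual replicates rather
#' than concentration means so that the slope standard error reflects the
#' full replicate design.
#'
#' @param data A data.frame with columns `concentration` (mM; mg/mL for
#'   protein) and `r`, one row per replicate measurement.
#' @param solute Optional solute name stored on the result.
#' @param axis For divalent chlorides, which concentration axis the input
#'   uses: "cation" (default) or "chloride". Stored as bookkeeping.
#' @return Object of class `r_calibration`: list with `solute`, `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `r_squared`, `n`,
#'   `n_concentrations`, `axis`, and the underlying `lm` fit as `model`.
#' @export
fit_series <- function(data, solute = NA_character_,
                       axis = c("cation", "chloride")) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(data), all(c("concentration", "r") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("concentration", "r")]), ]
  if (!nrow(data)) stop("no usable (concentration, r) rows")
  if (length(unique(data$concentration)) < 2L) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(r ~ concentration, data = data)
  sm <- suppressWarnings(summary(fit))  # exact lines trip the perfect-fit warning
  structure(list(solute = solute,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 n = nrow(data),
                 n_concentrations = length(unique(data$concentration)),
                 axis = axis,
                 model = fit),
            class = "r_calibration")
}

#' @export
print.r_calibration <- function(x, ...) {
  cat(sprintf("Calibration %s: r = %.4f + %.3e * c  (slope SE %.1e, R2 %.4f, n %d)\n",
              if (is.na(x$solute)) "" else x$solute,
              x$intercept, x$slope, x$slope_se, x$r_squared, x$n))
  invisible(x)
}

#' Compare calibration slopes of two solute series
#'
#' Pools the replicate-level data of two series and fits
#' r ~ c + group + c:group; the interaction coefficient estimates the slope
#' difference and its two-sided p-value tests slope equality (the classical
#' ANCOVA interaction test).
#'
#' @param a,b data.frames with columns `concentration`, `r`.
#' @param labels Length-2 character vector naming the two series.
#' @return Object of class `slope_comparison`: `solutes`, `delta_slope`
#'   (slope b minus slope a), `se`, `p_value`, `model`.
#' @export
compare_slopes <- function(a, b, labels = c("a", "b")) {
  for (d in list(a, b)) {
    if (length(unique(d$concentration)) < 2L) {
      stop("both series need at least 2 distinct concentrations")
    }
  }
  pooled <- rbind(
    data.frame(concentration = a$concentration, r = a$r, group = labels[1]),
    data.frame(concentration = b$concentration, r = b$r, group = labels[2])
  )
  pooled$group <- factor(pooled$group, levels = labels)
  fit <- stats::lm(r ~ concentration * group, data = pooled)
  sm <- summary(fit)$coefficients
  term <- paste0("concentration:group", labels[2])
  if (!term %in% rownames(sm)) stop("degenerate design: interaction not estimable")
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  p <- sm[term, "Pr(>|t|)"]
  if (!is.finite(p) && est == 0) p <- 1  # identical series: t = 0/0
  structure(list(solutes = labels, delta_slope = unname(est),
                 se = unname(se), p_value = unname(p), model = fit),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope comparison %s vs %s: delta = %.3e (SE %.1e), p = %.3g\n",
              x$solutes[1], x$solutes[2], x$delta_slope, x$se, x$p_value))
  invisible(x)
}

#' Predict the r of a multi-solute mixture by slope additivity
#'
#' Additivity of the per-solute calibrations: the predicted mixture ratio is
#' the shared pure-water intercept plus the sum of slope * concentration
#' contributions, r_hat = mean(r0_i) + sum_i s_i * c_i. Summing full
#' per-component r values would count the pure-water term once per solute,
#' so the intercept enters once, averaged across the calibrations used.
#'
#' @param calibrations Named list of [fit_series()] results (names are
#'   solute names).
#' @param buffer Named numeric vector of concentrations (mM; mg/mL for
#'   protein), e.g. [isotonic_buffer()].
#' @return Predicted r (single number).
#' @export
predict_mixture_r <- function(calibrations, buffer) {
  if (!length(buffer)) {
    return(mean(vapply(calibrations, `[[`, numeric(1), "intercept")))
  }
  if (any(buffer < 0)) stop("concentrations must be >= 0")
  missing <- setdiff(names(buffer), names(calibrations))
  if (length(missing)) {
    stop("no calibration for solute(s): ", paste(missing, collapse = ", "))
  }
  used <- calibrations[names(buffer)]
  r0 <- mean(vapply(used, `[[`, numeric(1), "intercept"))
  slopes <- vapply(used, `[[`, numeric(1), "slope")
  r0 + sum(slopes * buffer)
}

#' Convert an r difference to a concentration change
#'
#' Inverts the calibration line for differences: delta_c = delta_r / slope
#' (the intercept cancels). Under electroneutrality a sodium change inferred
#' with the NaCl calibration is balanced by an equal chloride change.
#'
#' @param delta_r r difference (treated minus control).
#' @param cal An [fit_series()] calibration (typically NaCl).
#' @return Concentration change in the calibration's units (mM).
#' @export
delta_r_to_concentration <- function(delta_r, cal) {
  stopifnot(inherits(cal, "r_calibration"))
  if (!is.finite(cal$slope) || cal$slope == 0) {
    stop("calibration slope is zero; cannot invert")
  }
  delta_r / cal$slope
}

#' Estimate r for every spectrum of a generated calibration series
#'
#' Runs the spectral pipeline ([spectrum_r()]) on each replicate spectrum of
#' a [make_calibration_series()] result.
#'
#' @param series Result of [make_calibration_series()].
#' @param anchors Baseline anchors, see [subtract_baseline()].
#' @return data.frame with columns `concentration`, `replicate`, `r_true`, `r`.
#' @export
series_r_values <- function(series,
                            anchors = list(c(2400, 2500), c(4100, 4200))) {
  df <- series$spectra
  df$r <- vapply(df$spectrum, spectrum_r, numeric(1),
                 context = "solution", anchors = anchors)
  df[, c("concentration", "replicate", "r_true", "r")]
}
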