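#' Estimate r at every depth of a z-scan
#'
#' Runs baseline subtraction, normalisation and cell-context deconvolution
#' on every spectrum of a scan, warm-starting each fit from the previous
#' depth's converged parameters (scans are processed from the top of the
#' scan, where the spectrum is nearly pure buffer, down to the substrate).
#'
#' @param scan Either the result of [make_cell_zscan()] or a data.frame
#'   with columns `z` and list-column `spectrum`.
#' @param anchors Baseline anchor windows.
#' @param shape Deconvolution mode, see [deconvolve()]; quantitative r
#'   profiling uses the calibrated fixed-shape area fit by default.
#' @return data.frame with columns `z`, `r`, `converged`.
#' @export
process_zscan <- function(scan, anchors = list(c(2400, 2500), c(4100, 4200)),
                          shape = "fixed") {
  df <- if (is.data.frame(scan)) scan else scan$spectra
  stopifnot(all(c("z", "spectrum") %in% names(df)))
  ord <- order(df$z, decreasing = TRUE)
  r <- numeric(nrow(df)); conv <- logical(nrow(df))
  init <- NULL
  for (i in ord) {
    s <- normalize_total(subtract_baseline(df$spectrum[[i]], anchors))
    fit <- deconvolve(s, context = "cell", init = init, shape = shape)
    init <- fit$bands
    r[i] <- compute_r(fit)$r
    conv[i] <- fit$converged
  }
  data.frame(z = df$z, r = r, converged = conv)
}

#' Average per-cell r(z) profiles into a group depth profile
#'
#' @param cells List of per-cell data.frames with columns `z` and `r`, all
#'   sharing the same z grid.
#' @param group Optional group label.
#' @return Object of class `z_profile`: data.frame fields `z`, `r_mean`,
#'   `r_sd` plus attributes `n_cells`, `cells` (z x cell matrix of r),
#'   `group`.
#' @export
average_profiles <- function(cells, group = NA_character_) {
  if (!length(cells)) stop("empty list of cell profiles")
  z <- cells[[1]]$z
  for (p in cells) {
    if (length(p$z) != length(z) || any(p$z != z)) {
      stop("all cells must share the same z grid")
    }
  }
  if (any(diff(z) <= 0)) stop("z must be strictly increasing")
  mat <- vapply(cells, function(p) p$r, numeric(length(z)))
  mat <- matrix(mat, nrow = length(z))
  out <- data.frame(z = z,
                    r_mean = rowMeans(mat),
                    r_sd = apply(mat, 1, stats::sd))
  structure(out, class = c("z_profile", "data.frame"),
            n_cells = ncol(mat), cells = mat, group = group)
}

#' Locate the apical membrane from the extracellular r plateau
#'
#' The apical membrane position (cell thickness) is the smallest grid depth
#' z* from which the mean profile stays within `tol * r_extracellular` of
#' the extracellular reference value for all larger depths.
#'
#' @param profile A [average_profiles()] result (or data.frame with `z`,
#'   `r_mean`).
#' @param r_extracellular Reference ratio of the bathing buffer.
#' @param tol Relative tolerance defining the plateau (default 1%).
#' @return Estimated thickness (micrometres).
#' @export
estimate_thickness <- function(profile, r_extracellular = 1.363, tol = 0.01) {
  dev <- abs(profile$r_mean - r_extracellular) <= tol * r_extracellular
  if (!dev[length(dev)]) {
    stop("profile never reaches the extracellular plateau within the scan")
  }
  # last index (from the top) at which the profile is still off-plateau
  off <- which(!dev)
  if (!length(off)) return(profile$z[1])
  idx <- max(off) + 1L
  if (idx > length(dev)) stop("profile never reaches the extracellular plateau within the scan")
  profile$z[idx]
}

#' Unpaired t-test between two groups of per-cell r values at one depth
#'
#' Two-sided Student's t-test (equal variances) by default; Welch via
#' `var_equal = FALSE`. Degenerate groups with zero pooled variance return
#' p = 1 when the means are equal.
#'
#' @param group_a,group_b Numeric vectors of per-cell r values (>= 2 each).
#' @param var_equal Use the pooled-variance Student test (default TRUE).
#' @return Two-sided p-value.
#' @export
per_depth_ttest <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 observations per group")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = var_equal)$p.value
}

#' Difference treated and control profiles inside the cytosol
#'
#' Restricts to cytosolic depths (0 < z < t), differences the mean profiles
#' (treated minus control), converts delta-r to a sodium concentration
#' change with the NaCl calibration slope, and attaches per-depth unpaired
#' t-test p-values with a significance mask at p <= 0.05. Electroneutrality
#' implies an equal chloride change.
#'
#' @param treated,control [average_profiles()] results on a shared z grid.
#' @param t Cell thickness (micrometres) on the grid.
#' @param cal_nacl NaCl [fit_series()] calibration.
#' @param alpha Significance level for the mask.
#' @param p_adjust Multiple-testing correction across depths passed to
#'   [stats::p.adjust()]; default "none" (raw per-depth significance).
#' @param var_equal Student (TRUE) or Welch t-test.
#' @return Object of class `delta_profile`: data.frame with `z`, `delta_r`,
#'   `delta_na` (mM), `p_value`, `significant`; attribute `thickness`.
#' @export
delta_profile <- function(treated, control, t, cal_nacl, alpha = 0.05,
                          p_adjust = "none", var_equal = TRUE) {
  if (length(treated$z) != length(control$z) ||
      any(treated$z != control$z)) {
    stop("treated and control profiles must share the z grid")
  }
  keep <- treated$z > 0 & treated$z < t
  if (!any(keep)) stop("no cytosolic depths between 0 and t")
  z <- treated$z[keep]
  dr <- treated$r_mean[keep] - control$r_mean[keep]
  dna <- delta_r_to_concentration(dr, cal_nacl)
  mt <- attr(treated, "cells"); mc <- attr(control, "cells")
  p <- rep(NA_real_, length(z))
  if (!is.null(mt) && !is.null(mc) && ncol(mt) >= 2 && ncol(mc) >= 2) {
    rows <- which(keep)
    p <- vapply(seq_along(rows), function(i) {
      per_depth_ttest(mt[rows[i], ], mc[rows[i], ], var_equal = var_equal)
    }, numeric(1))
  }
  p_adj <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(z = z, delta_r = dr, delta_na = dna,
                    p_value = p_adj, significant = !is.na(p_adj) & p_adj <= alpha)
  structure(out, class = c("delta_profile", "data.frame"), thickness = t)
}

#' Fit the intracellular sodium-change gradient
#'
#' Least-squares line of mean delta[Na+] against depth over the cytosolic
#' fit range (by default 1 um away from both membranes, where substrate
#' contamination and PSF edge effects are strongest), plus the Pearson
#' correlation of the fitted points. Slopes are in instrument coordinates
#' (z increasing basolateral to apical).
#'
#' @param dp A [delta_profile()].
#' @param z_range Fit range in micrometres; default c(1, t - 1).
#' @return Object of class `gradient_fit`: `slope` (mM/um), `intercept`
#'   (mM), `pearson_r`, `n`, `z_range`, `degenerate` (TRUE when the profile
#'   is constant and the correlation undefined, reported as 0).
#' @export
fit_gradient <- function(dp, z_range = NULL) {
  t <- attr(dp, "thickness")
  if (is.null(z_range)) z_range <- c(1, (if (is.null(t)) max(dp$z) else t) - 1)
  keep <- dp$z >= z_range[1] & dp$z <= z_range[2]
  z <- dp$z[keep]; y <- dp$delta_na[keep]
  if (length(z) < 3L) stop("need at least 3 cytosolic points to fit a gradient")
  fit <- stats::lm(y ~ z)
  degenerate <- stats::sd(y) == 0
  pr <- if (degenerate) 0 else stats::cor(z, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = pr, n = length(z), z_range = z_range,
                 degenerate = degenerate),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "Gradient fit: d[Na+]/dz = %.3f mM/um, intercept %.2f mM, Pearson %.3f (n=%d)\n",
    x$slope, x$intercept, x$pearson_r, x$n))
  invisible(x)
}
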