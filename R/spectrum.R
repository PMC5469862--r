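#' Construct a Raman spectrum
#'
#' @param wavenumbers Strictly increasing numeric vector (1/cm).
#' @param intensities Numeric vector, same length (detector counts).
#' @param metadata Optional named list (z, group, solute, concentration, ...).
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `metadata`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, metadata = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) < 50L) {
    stop("a spectrum needs at least 50 points spanning the fit window")
  }
  if (anyNA(wavenumbers) || anyNA(intensities)) {
    stop("spectrum contains missing values")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing")
  }
  structure(list(wavenumber = wavenumbers, intensity = intensities,
                 metadata = metadata),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d points, %.0f-%.0f 1/cm\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (length(x$metadata)) {
    meta <- paste(names(x$metadata),
                  vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                         character(1)),
                  sep = "=", collapse = ", ")
    cat(" metadata:", meta, "\n")
  }
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (counts)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Reads plain-text/CSV spectra with columns (wavenumber, intensity) and an
#' optional header line. Descending wavenumber order is tolerated and
#' re-sorted with a warning; duplicate wavenumbers or non-numeric rows are
#' errors.
#'
#' @param path File path.
#' @param metadata Optional named list attached to the result.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*-?[0-9.]+\\s*[,;\\t ]", first)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = has_header, sep = sep,
                          comment.char = "#",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns (wavenumber, intensity) in ", path)
  wn <- suppressWarnings(as.numeric(df[[1]]))
  it <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(wn) | is.na(it))
  if (length(bad)) {
    stop(sprintf("non-numeric spectrum data in %s at data line %d", path, bad[1]))
  }
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in ", path)
  if (is.unsorted(wn)) {
    warning("wavenumbers not in ascending order in ", path, "; re-sorting")
    o <- order(wn)
    wn <- wn[o]; it <- it[o]
  }
  raman_spectrum(wn, it, metadata)
}

#' Write a spectrum as two-column CSV
#'
#' @param s A [raman_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  df <- data.frame(wavenumber = s$wavenumber, intensity = s$intensity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Trapezoidal integral of a spectrum over its full window.
spectrum_integral <- function(s) {
  x <- s$wavenumber; y <- s$intensity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
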