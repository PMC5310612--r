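# Reflectance spectra: containers, CSV I/O, regridding.
#
# A `spectrum` is a wavelength-indexed curve (reflectance, receptor
# sensitivity, or illuminant irradiance); a `spectrum_set` is an ordered
# collection sharing one wavelength grid. Reflectance is stored as a
# proportion in [0, 1.05] (small calibration overshoot tolerated).

#' Canonical working wavelength grid
#'
#' The avian-visible range, 300--700 nm at 1 nm steps. All visual-model
#' computations regrid their inputs onto this grid (or any other common grid
#' supplied by the caller).
#'
#' @return Integer-valued numeric vector of wavelengths in nm.
#' @export
canonical_grid <- function() seq(300, 700, by = 1)

#' Construct a spectrum
#'
#' @param wavelengths_nm Strictly increasing, finite wavelengths (nm).
#' @param values Finite values at each wavelength. For reflectance these are
#'   proportions; negatives are clipped to 0 with a warning (a common
#'   spectrometer noise artifact) and values above 1.05 are rejected when
#'   `check_reflectance = TRUE`.
#' @param label Sample identifier.
#' @param check_reflectance Apply the reflectance range checks? Set `FALSE`
#'   for sensitivities and illuminants, which are not proportions.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values, label = "spectrum",
                     check_reflectance = TRUE) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values differ in length")
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least two wavelengths")
  if (any(!is.finite(wavelengths_nm)))
    stop("non-finite wavelengths")
  if (any(diff(wavelengths_nm) <= 0))
    stop("non-monotonic wavelengths")
  if (any(!is.finite(values)))
    stop(sprintf("non-finite values in spectrum '%s'", label))
  if (isTRUE(check_reflectance)) {
    if (any(values < 0)) {
      warning(sprintf("negative reflectance in '%s' clipped to 0", label))
      values[values < 0] <- 0
    }
    if (any(values > 1.05))
      stop(sprintf(
        "reflectance > 1.05 in '%s'; use units = \"percent\" if values are percentages",
        label))
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %g-%g nm, values [%.4g, %.4g]>\n",
              x$label, length(x$values), min(x$wavelengths_nm),
              max(x$wavelengths_nm), min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a spectrum set
#'
#' @param spectra List of [spectrum()] objects sharing an identical grid.
#' @param source Provenance string (file path or "synthetic").
#' @param units Original units flag, `"proportion"` or `"percent"`.
#' @return An object of class `spectrum_set`: list with elements `grid`,
#'   `spectra` (named list), `source`, `units`.
#' @export
spectrum_set <- function(spectra, source = NA_character_, units = "proportion") {
  if (length(spectra) == 0L) stop("empty spectrum set")
  labels <- vapply(spectra, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate spectrum labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  grid <- spectra[[1L]]$wavelengths_nm
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelengths_nm, grid, tolerance = 0)))
      stop("member spectra do not share an identical wavelength grid")
  names(spectra) <- labels
  structure(list(grid = grid, spectra = spectra, source = source,
                 units = units),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra on %g-%g nm (%d points)>\n",
              length(x$spectra), min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Read reflectance spectra from CSV
#'
#' Expects a header row, first column `wl` (wavelength, nm), remaining
#' columns one sample each (decimal point, comma separator, UTF-8).
#'
#' @param path CSV file path.
#' @param units `"proportion"` (default) or `"percent"`; percent values are
#'   divided by 100 on read.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, units = c("proportion", "percent")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("need a wavelength column plus >= 1 sample column")
  nm <- names(raw)
  if (anyDuplicated(nm))
    stop("duplicate column names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s'", bad[1L], nm[j]))
      raw[[j]] <- num
    }
  }
  wl <- raw[[1L]]
  if (any(is.na(wl)) || any(diff(wl) <= 0))
    stop("non-monotonic wavelengths")
  scale <- if (units == "percent") 1 / 100 else 1
  spectra <- lapply(seq.int(2L, ncol(raw)), function(j)
    spectrum(wl, raw[[j]] * scale, label = nm[j]))
  spectrum_set(spectra, source = path, units = units)
}

#' Write a spectrum set to CSV
#'
#' Inverse of [read_spectra()]; always writes proportions.
#'
#' @param x A [spectrum_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  df <- data.frame(wl = x$grid, check.names = FALSE)
  for (s in x$spectra) df[[s$label]] <- s$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; exact at shared nodes. The spectrum must cover the
#' requested grid (no extrapolation).
#'
#' @param s A [spectrum()].
#' @param grid Target wavelength vector (strictly increasing).
#' @return A [spectrum()] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("non-monotonic target grid")
  if (min(grid) < min(s$wavelengths_nm) || max(grid) > max(s$wavelengths_nm))
    stop(sprintf(
      "insufficient spectral coverage: '%s' spans %g-%g nm, grid needs %g-%g nm",
      s$label, min(s$wavelengths_nm), max(s$wavelengths_nm),
      min(grid), max(grid)))
  v <- stats::approx(s$wavelengths_nm, s$values, xout = grid,
                     method = "linear", ties = "ordered")$y
  spectrum(grid, v, label = s$label, check_reflectance = FALSE)
}

#' Resample every member of a spectrum set
#'
#' @param x A [spectrum_set()].
#' @param grid Target wavelength vector; defaults to [canonical_grid()].
#' @return A [spectrum_set()] on `grid`.
#' @export
resample_set <- function(x, grid = canonical_grid()) {
  stopifnot(inherits(x, "spectrum_set"))
  spectrum_set(lapply(x$spectra, resample_to_grid, grid = grid),
               source = x$source, units = x$units)
}

# trapezoidal quadrature on a shared grid (internal)
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
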