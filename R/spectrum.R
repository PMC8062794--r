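#' Spectrum objects on a wavelength grid
#'
#' A `spectrum` is the package's universal currency: a strictly increasing
#' wavelength grid (nm) with one non-negative intensity per sample, a role
#' tag, and free-form metadata (phantom id, probe, channel, ...).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavelength`. Must be finite.
#' @param role One of `"reflectance"`, `"fluorescence"`, `"standard"`.
#' @param meta Named list of metadata carried with the spectrum.
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(400:900, rep(1, 501), role = "reflectance")
#' value_at(s, 550.5)
#' @export
spectrum <- function(wavelength, intensity, role = "fluorescence", meta = list()) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) < 2L)
    stop("spectrum needs at least 2 wavelength samples", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelength grid must be finite and strictly increasing", call. = FALSE)
  if (length(intensity) != length(wavelength))
    stop("intensity length (", length(intensity), ") != grid length (",
         length(wavelength), ")", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  role <- match.arg(role, c("reflectance", "fluorescence", "standard"))
  structure(list(wavelength = wavelength, intensity = intensity,
                 role = role, meta = meta),
            class = "spectrum")
}

#' Default working wavelength grid
#'
#' 400 to 900 nm at 1 nm (501 samples): the broadband reflectance range of a
#' visible spectroscopy system, fine enough to resolve a 5 nm filter band.
#'
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric wavelength vector.
#' @export
default_grid <- function(from = 400, to = 900, by = 1) seq(from, to, by = by)

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum role=%s: %d samples, %.6g-%.6g nm>\n",
              x$role, length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a spectrum at a wavelength
#'
#' Linear interpolation between bracketing grid samples; exact stored value
#' when `lambda` lies on the grid.
#'
#' @param s A [spectrum].
#' @param lambda Wavelength in nm; must lie within the grid span.
#' @return Interpolated intensity (scalar, or vector if `lambda` is).
#' @export
value_at <- function(s, lambda) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$wavelength)
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop(sprintf("wavelength %g nm outside grid span [%g, %g] nm",
                 lambda[which(lambda < rng[1] | lambda > rng[2])[1]],
                 rng[1], rng[2]), call. = FALSE)
  stats::approx(s$wavelength, s$intensity, xout = lambda, method = "linear",
                ties = "ordered")$y
}

#' Wavelength band
#'
#' A central wavelength and full bandwidth describing an optical filter or
#' evaluation band. `bw = 0` denotes single-wavelength evaluation.
#'
#' @param cwl Central wavelength, nm.
#' @param bw Full bandwidth, nm, >= 0.
#' @return An object of class `band`.
#' @export
band <- function(cwl, bw = 0) {
  stopifnot(is.numeric(cwl), is.numeric(bw), length(cwl) == 1L, length(bw) == 1L)
  if (!is.finite(cwl) || !is.finite(bw) || bw < 0)
    stop("band requires finite cwl and bw >= 0", call. = FALSE)
  structure(list(cwl = cwl, bw = bw), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band cwl=%g nm, bw=%g nm>\n", x$cwl, x$bw)); invisible(x)
}

#' Summed intensity over a band
#'
#' Sums the stored intensities at every grid sample inside the closed
#' interval `[cwl - bw/2, cwl + bw/2]` (no fractional-sample interpolation).
#' With `bw = 0` it degenerates to [value_at] at `cwl`.
#'
#' @param s A [spectrum].
#' @param b A [band] intersecting the grid.
#' @return Summed intensity.
#' @export
band_sum <- function(s, b) {
  stopifnot(inherits(s, "spectrum"), inherits(b, "band"))
  if (b$bw == 0) return(value_at(s, b$cwl))
  lo <- b$cwl - b$bw / 2
  hi <- b$cwl + b$bw / 2
  idx <- s$wavelength >= lo & s$wavelength <= hi
  if (!any(idx))
    stop(sprintf("band [%g, %g] nm contains no grid samples (grid %g-%g nm)",
                 lo, hi, min(s$wavelength), max(s$wavelength)), call. = FALSE)
  sum(s$intensity[idx])
}

# Columns of the spectra CSV dialect; meta columns come after the first two.
.spectra_cols <- c("wavelength_nm", "intensity", "role", "phantom_id",
                   "probe", "channel")

#' Read spectra from CSV
#'
#' The CSV dialect has header
#' `wavelength_nm,intensity,role,phantom_id,probe,channel`, one row per
#' (sample, spectrum); a file may hold many spectra distinguished by the
#' (phantom_id, probe, channel, role) tuple.
#'
#' @param path Path to a CSV file.
#' @return List of [spectrum] objects; each carries `phantom_id`, `probe`,
#'   `channel` in its `meta`.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.spectra_cols, names(df))
  if (length(missing))
    stop("spectra file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$wavelength_nm)) || any(is.na(df$intensity)))
    stop("spectra file ", path, ": non-finite wavelength or NA intensity at line ",
         which(!is.finite(df$wavelength_nm) | is.na(df$intensity))[1] + 1L,
         call. = FALSE)
  key <- interaction(df$phantom_id, df$probe, df$channel, df$role, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    if (any(diff(d$wavelength_nm) <= 0))
      stop("spectra file ", path, ": wavelengths not strictly increasing for spectrum ",
           d$phantom_id[1], "/", d$role[1], call. = FALSE)
    spectrum(d$wavelength_nm, d$intensity, role = d$role[1],
             meta = list(phantom_id = d$phantom_id[1], probe = d$probe[1],
                         channel = d$channel[1]))
  })
  unname(out)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra]; lossless round-trip at full double precision.
#'
#' @param spectra A [spectrum] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    meta_or <- function(k, d) if (!is.null(s$meta[[k]])) as.character(s$meta[[k]]) else d
    data.frame(wavelength_nm = s$wavelength, intensity = s$intensity,
               role = s$role,
               phantom_id = meta_or("phantom_id", paste0("s", i)),
               probe = meta_or("probe", "none"),
               channel = meta_or("channel", "default"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
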