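#' Standard-puck measurements for instrument calibration
#'
#' Bundles the measurement of the diffuse-reflectance standard (a puck of
#' known reflectivity, 20 % by default) and a per-channel excitation-power
#' factor derived from the fluorescence standard.
#'
#' @param refl_standard_meas [spectrum]: measurement of the reflectance
#'   standard; must be strictly positive over the working range.
#' @param refl_standard_value Known reflectivity of the standard, in (0, 1).
#' @param fluor_standard_factor Positive scalar excitation-power proxy.
#' @return Object of class `standards_set`.
#' @export
standards_set <- function(refl_standard_meas, refl_standard_value = 0.20,
                          fluor_standard_factor = 1.0) {
  stopifnot(inherits(refl_standard_meas, "spectrum"))
  if (refl_standard_value <= 0 || refl_standard_value >= 1)
    stop("refl_standard_value must lie in (0, 1)", call. = FALSE)
  if (fluor_standard_factor <= 0)
    stop("fluor_standard_factor must be > 0", call. = FALSE)
  structure(list(refl_standard_meas = refl_standard_meas,
                 refl_standard_value = refl_standard_value,
                 fluor_standard_factor = fluor_standard_factor),
            class = "standards_set")
}

#' Calibrate a raw diffuse-reflectance spectrum
#'
#' Removes the wavelength-dependent source/detector response by normalizing
#' to the standard-puck measurement:
#' `R_cal(lambda) = raw(lambda) / standard(lambda) * reflectivity`.
#'
#' @param raw [spectrum] of raw reflectance counts.
#' @param std [standards_set]; its standard measurement must share the grid.
#' @return Calibrated [spectrum] with role `reflectance`.
#' @export
calibrate_reflectance <- function(raw, std) {
  stopifnot(inherits(raw, "spectrum"), inherits(std, "standards_set"))
  ref <- std$refl_standard_meas
  if (!isTRUE(all.equal(raw$wavelength, ref$wavelength)))
    stop("raw spectrum and standard measurement must share a grid", call. = FALSE)
  bad <- which(ref$intensity <= 0)
  if (length(bad))
    stop(sprintf("standard measurement non-positive at %g nm: cannot calibrate",
                 ref$wavelength[bad[1]]), call. = FALSE)
  r <- raw$intensity / ref$intensity * std$refl_standard_value
  r <- clip_negatives(r, "calibrated reflectance")
  spectrum(raw$wavelength, r, role = "reflectance", meta = raw$meta)
}

#' Calibrate a raw fluorescence spectrum
#'
#' Normalizes intensities to the channel's excitation power:
#' `F_cal(lambda) = raw(lambda) / fluor_standard_factor`.
#'
#' @param raw [spectrum] of raw fluorescence counts.
#' @param std [standards_set] with a positive `fluor_standard_factor`.
#' @return Calibrated [spectrum], role preserved.
#' @export
calibrate_fluorescence <- function(raw, std) {
  stopifnot(inherits(raw, "spectrum"), inherits(std, "standards_set"))
  if (std$fluor_standard_factor <= 0)
    stop("fluor_standard_factor must be > 0", call. = FALSE)
  f <- clip_negatives(raw$intensity / std$fluor_standard_factor,
                      "calibrated fluorescence")
  spectrum(raw$wavelength, f, role = raw$role, meta = raw$meta)
}

clip_negatives <- function(x, what) {
  n <- sum(x < 0)
  if (n > 0) {
    warning(sprintf("%s: clipped %d negative value(s) to 0", what, n),
            call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' Calibrate every spectrum in a phantom dataset
#'
#' Applies [calibrate_reflectance] and [calibrate_fluorescence] to all
#' phantom and control spectra using the dataset's standards.
#'
#' @param ds A `phantom_dataset` from [generate_design] (or assembled from
#'   files).
#' @return The dataset with calibrated spectra and `calibrated = TRUE`.
#' @export
calibrate_dataset <- function(ds) {
  stopifnot(inherits(ds, "phantom_dataset"))
  if (isTRUE(ds$calibrated)) return(ds)
  std <- ds$standards
  ds$phantoms <- lapply(ds$phantoms, function(p) {
    p$reflectance <- calibrate_reflectance(p$reflectance, std)
    p$fluorescence <- calibrate_fluorescence(p$fluorescence, std)
    p
  })
  ds$controls <- lapply(ds$controls, function(ctl) {
    ctl$spectrum <- calibrate_fluorescence(ctl$spectrum, std)
    ctl
  })
  ds$calibrated <- TRUE
  ds
}
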