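#' Correction configuration
#'
#' Wavelength bands at which diffuse reflectance is read for the
#' ratiometric correction, the model variant, and the box constraints used
#' when fitting the powers. Defaults follow the probes' excitation-source
#' and emission peaks with single-wavelength (zero-bandwidth) evaluation:
#' 450/550 nm for the glucose probe, 550/580 nm for the
#' membrane-potential probe.
#'
#' @param ex_band,em_band [band] objects for the excitation and emission
#'   reflectance terms.
#' @param mode `"two_power"` (independent exponents alpha, beta) or
#'   `"single_power"` (beta constrained to -alpha).
#' @param power_bounds Length-2 interval bounding each exponent during
#'   fitting (the correction itself accepts any finite value).
#' @return Object of class `correction_config`.
#' @export
correction_config <- function(ex_band, em_band,
                              mode = c("two_power", "single_power"),
                              power_bounds = c(-25, 25)) {
  stopifnot(inherits(ex_band, "band"), inherits(em_band, "band"),
            length(power_bounds) == 2L, power_bounds[1] < power_bounds[2])
  mode <- match.arg(mode)
  if (ex_band$cwl >= em_band$cwl)
    warning("excitation band CWL is not below emission band CWL; ",
            "unusual for a Stokes-shifted probe", call. = FALSE)
  structure(list(ex_band = ex_band, em_band = em_band, mode = mode,
                 power_bounds = as.numeric(power_bounds)),
            class = "correction_config")
}

#' Default correction configuration for a probe
#'
#' @param probe Probe name, see [fluorophore_model].
#' @param mode Model variant, passed to [correction_config].
#' @param bw Bandwidth (nm) for both reflectance bands; 0 = single
#'   wavelength.
#' @return A `correction_config`.
#' @export
default_correction_config <- function(probe = "2nbdg",
                                      mode = c("two_power", "single_power"),
                                      bw = 0) {
  probe <- normalize_probe(probe)
  if (probe == "2nbdg")
    correction_config(band(450, bw), band(550, bw), mode = mode)
  else
    correction_config(band(550, bw), band(580, bw), mode = mode)
}

#' @export
print.correction_config <- function(x, ...) {
  cat(sprintf("<correction_config %s: Rex @ %g nm (bw %g), Rem @ %g nm (bw %g), bounds [%g, %g]>\n",
              x$mode, x$ex_band$cwl, x$ex_band$bw, x$em_band$cwl, x$em_band$bw,
              x$power_bounds[1], x$power_bounds[2]))
  invisible(x)
}

#' Reflectance terms for the correction
#'
#' Reads the calibrated diffuse reflectance at the configured excitation
#' and emission bands: single-wavelength values at zero bandwidth, summed
#' sample intensities otherwise. Both must be strictly positive for the
#' power correction to be defined.
#'
#' @param R Calibrated reflectance [spectrum].
#' @param cfg [correction_config].
#' @return Named numeric vector `c(Rex = ..., Rem = ...)`.
#' @export
reflectance_terms <- function(R, cfg) {
  stopifnot(inherits(R, "spectrum"), inherits(cfg, "correction_config"))
  rex <- band_sum(R, cfg$ex_band)
  rem <- band_sum(R, cfg$em_band)
  if (rex <= 0 || rem <= 0)
    stop(sprintf("degenerate reflectance: Rex = %g, Rem = %g (both must be > 0)",
                 rex, rem), call. = FALSE)
  c(Rex = rex, Rem = rem)
}

#' Ratiometric two-power correction
#'
#' The core model: `Fcorr(lambda) = Fraw(lambda) / (Rex^alpha * Rem^beta)`.
#' `Rex` and `Rem` are the diffuse-reflectance intensities of the *same*
#' phantom or tissue site at the excitation and emission bands; the powers
#' express how strongly absorption and scattering modulate the measured
#' fluorescence.
#'
#' @param Fraw Raw fluorescence [spectrum].
#' @param Rex,Rem Positive reflectance terms, see [reflectance_terms].
#' @param alpha,beta Correction powers (finite).
#' @return Corrected [spectrum]; `meta` records `Rex`, `Rem`, `alpha`,
#'   `beta`.
#' @export
correct_spectrum <- function(Fraw, Rex, Rem, alpha, beta) {
  stopifnot(inherits(Fraw, "spectrum"))
  if (!is.finite(Rex) || !is.finite(Rem) || Rex <= 0 || Rem <= 0)
    stop(sprintf("degenerate reflectance: Rex = %g, Rem = %g (both must be > 0)",
                 Rex, Rem), call. = FALSE)
  if (!is.finite(alpha) || !is.finite(beta))
    stop("powers must be finite", call. = FALSE)
  denom <- Rex^alpha * Rem^beta
  if (!is.finite(denom) || denom == 0)
    stop(sprintf("Rex^%g * Rem^%g overflowed or underflowed", alpha, beta),
         call. = FALSE)
  meta <- Fraw$meta
  meta$Rex <- unname(Rex); meta$Rem <- unname(Rem)
  meta$alpha <- alpha; meta$beta <- beta
  spectrum(Fraw$wavelength, Fraw$intensity / denom, role = "fluorescence",
           meta = meta)
}

#' Single-power simplified correction
#'
#' The one-parameter variant
#' `Fcorr(lambda) = Fraw(lambda) / (Rex / Rem)^alpha`, exactly equivalent
#' to [correct_spectrum] with powers `(alpha, -alpha)`. It trades a little
#' accuracy for insensitivity to common-mode reflectance calibration error.
#'
#' @inheritParams correct_spectrum
#' @param alpha The single correction power.
#' @return Corrected [spectrum].
#' @export
correct_single <- function(Fraw, Rex, Rem, alpha) {
  correct_spectrum(Fraw, Rex, Rem, alpha, -alpha)
}
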