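#' Mean percent error of corrected spectra against references
#'
#' Compares a set of corrected fluorescence spectra with the
#' fluorophore-only reference spectra of matching concentration. A single
#' global scale factor `s` (least squares over all phantoms and evaluation
#' wavelengths) converts corrected units to reference units; a per-phantom
#' scale would erase exactly the concentration information the correction
#' is meant to preserve. The per-phantom error is the mean over evaluation
#' wavelengths of `|s*Fcorr - Fref| / Fref * 100`; evaluation wavelengths
#' are the samples where the reference exceeds `rel_threshold` of its peak
#' (pointwise relative error diverges in spectral tails).
#'
#' @param corrected List of corrected [spectrum] objects; each `meta` must
#'   carry `concentration` (and, for subgroup summaries, `mua_mean` and
#'   `musp_mean`).
#' @param references List of reference spectra: either [spectrum] objects
#'   with `concentration` in `meta`, or `list(concentration=, spectrum=)`
#'   records as stored in a `phantom_dataset`.
#' @param rel_threshold Fraction of the reference peak defining the
#'   evaluation band (default 0.10).
#' @param em_cwl Optional emission central wavelength recorded for
#'   reporting.
#' @return Object of class `error_report`: `per_phantom_pct`, `mean_pct`,
#'   `group_means` (mean error over the varying-absorption and
#'   varying-scattering subgroups, when design metadata is present),
#'   `scale_factor`, `n`.
#' @export
percent_error <- function(corrected, references, rel_threshold = 0.10,
                          em_cwl = NULL) {
  refs <- lapply(references, function(r) {
    if (inherits(r, "spectrum")) list(concentration = r$meta$concentration, spectrum = r)
    else r
  })
  ref_conc <- vapply(refs, function(r) as.numeric(r$concentration), numeric(1))
  if (any(!is.finite(ref_conc)))
    stop("every reference needs a concentration", call. = FALSE)
  ref_eval <- lapply(refs, function(r) {
    y <- r$spectrum$intensity
    pk <- max(y)
    if (pk <= 0) stop("all-zero reference spectrum", call. = FALSE)
    which(y >= rel_threshold * pk)
  })

  num <- 0; den <- 0
  matched <- lapply(corrected, function(s) {
    conc <- s$meta$concentration
    j <- which(abs(ref_conc - conc) < 1e-9)
    if (length(j) != 1L)
      stop("no unique reference for concentration ", conc, call. = FALSE)
    idx <- ref_eval[[j]]
    list(fc = s$intensity[idx], fr = refs[[j]]$spectrum$intensity[idx], s = s)
  })
  for (m in matched) { num <- num + sum(m$fc * m$fr); den <- den + sum(m$fc^2) }
  if (den <= 0) stop("corrected spectra are all zero on the evaluation band",
                     call. = FALSE)
  sf <- num / den

  pct <- vapply(matched, function(m)
    mean(abs(sf * m$fc - m$fr) / m$fr) * 100, numeric(1))
  ids <- vapply(seq_along(corrected), function(i) {
    id <- corrected[[i]]$meta$phantom_id
    if (is.null(id)) paste0("phantom", i) else id
  }, character(1))
  names(pct) <- ids

  group_means <- NULL
  mua <- vapply(corrected, function(s)
    if (is.null(s$meta$mua_mean)) NA_real_ else s$meta$mua_mean, numeric(1))
  musp <- vapply(corrected, function(s)
    if (is.null(s$meta$musp_mean)) NA_real_ else s$meta$musp_mean, numeric(1))
  if (!anyNA(mua) && !anyNA(musp) &&
      length(unique(mua)) >= 3 && length(unique(musp)) >= 3) {
    mid_mua <- sort(unique(mua))[2]
    mid_musp <- sort(unique(musp))[2]
    group_means <- c(absorption = mean(pct[musp == mid_musp]),
                     scattering = mean(pct[mua == mid_mua]))
  }

  structure(list(per_phantom_pct = pct, mean_pct = mean(pct),
                 group_means = group_means, scale_factor = sf,
                 n = length(pct), rel_threshold = rel_threshold,
                 em_cwl = em_cwl),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Percent error vs references: mean %.2f%% over %d phantoms (global scale %.4g)\n",
              x$mean_pct, x$n, x$scale_factor))
  if (!is.null(x$group_means))
    cat(sprintf("  varying-absorption group: %.2f%%; varying-scattering group: %.2f%%\n",
                x$group_means["absorption"], x$group_means["scattering"]))
  invisible(x)
}

#' Linear concentration calibration curve
#'
#' Ordinary least-squares line through corrected emission-peak intensity
#' versus true concentration, with Pearson correlation and its exact
#' t-based two-sided p-value.
#'
#' @param peak_intensities Numeric vector of corrected peak intensities.
#' @param concentrations Matching true concentrations (not all equal,
#'   n >= 3).
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `p_value`, `n`.
#' @export
fit_calibration_curve <- function(peak_intensities, concentrations) {
  n <- length(peak_intensities)
  if (n != length(concentrations)) stop("length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(concentrations) == 0)
    stop("degenerate fit: concentrations are all equal", call. = FALSE)
  fit <- stats::lm(peak_intensities ~ concentrations)
  ct <- stats::cor.test(peak_intensities, concentrations, method = "pearson")
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = n),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration line: intensity = %.4g * conc + %.4g  (n = %d)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("  R^2 = %.4f, Pearson r = %.4f, p = %.3g\n",
              x$r_squared, x$pearson_r, x$p_value))
  invisible(x)
}

#' Invert the calibration curve
#'
#' @param peak_intensity Corrected peak intensity (vectorized).
#' @param curve A [fit_calibration_curve] result with nonzero slope.
#' @return Estimated concentration(s); negative estimates are returned
#'   as-is with a warning.
#' @export
estimate_concentration <- function(peak_intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("cannot invert a zero-slope curve", call. = FALSE)
  est <- (peak_intensity - curve$intercept) / curve$slope
  if (any(est < 0))
    warning(sum(est < 0), " negative concentration estimate(s)", call. = FALSE)
  est
}

#' Bland-Altman agreement statistics
#'
#' @param estimates,truths Equal-length numeric vectors (n >= 2).
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, with the limits of agreement at
#'   mean difference +/- 1.96 SD of the differences.
#' @export
bland_altman <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths differ in length", call. = FALSE)
  if (length(estimates) < 2L) stop("need n >= 2", call. = FALSE)
  d <- estimates - truths
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, SD %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Evaluate a fitted correction on a phantom dataset
#'
#' Corrects every turbid phantom with the fitted powers, scores the
#' corrected spectra against the fluorophore-only references
#' ([percent_error]), fits the concentration calibration line through the
#' corrected emission-peak intensities, estimates concentrations by
#' inverting it, and summarizes agreement with Bland-Altman statistics.
#'
#' @param fit A `ratiometric_fit` (or a list with `powers` and `config`).
#' @param dataset A `phantom_dataset` (calibrated automatically if raw).
#' @param ids Optional phantom ids to score; default all turbid phantoms.
#' @return Object of class `correction_report`: `error` ([percent_error]
#'   report), `curve` ([fit_calibration_curve]), `estimates` (data.frame
#'   with truth and estimate per phantom), `agreement` ([bland_altman] of
#'   estimates vs truths), `powers`.
#' @export
evaluate_correction <- function(fit, dataset, ids = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  cfg <- fit$config
  corrected <- correct_dataset(dataset, cfg,
                               alpha = fit$powers[["alpha"]],
                               beta = fit$powers[["beta"]], ids = ids)
  err <- percent_error(corrected, dataset$controls, em_cwl = cfg$em_band$cwl)
  peaks <- vapply(corrected, value_at, numeric(1), lambda = cfg$em_band$cwl)
  concs <- vapply(corrected, function(s) s$meta$concentration, numeric(1))
  curve <- fit_calibration_curve(peaks, concs)
  est <- estimate_concentration(peaks, curve)
  structure(list(
    error = err, curve = curve,
    estimates = data.frame(
      phantom_id = names(err$per_phantom_pct),
      concentration = concs, estimate = est,
      pct_error = unname(err$per_phantom_pct),
      stringsAsFactors = FALSE),
    agreement = bland_altman(est, concs),
    powers = fit$powers),
    class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("Correction report (alpha = %.3f, beta = %.3f)\n",
              x$powers[["alpha"]], x$powers[["beta"]]))
  print(x$error); print(x$curve); print(x$agreement)
  invisible(x)
}
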