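#' Deterministic stratified train/validation split
#'
#' Partitions the 27 turbid phantoms (9 optical combinations x 3 nonzero
#' concentrations) into 15 training and 12 validation phantoms. The split
#' is a fixed function of the design: every optical combination and every
#' concentration appears in training at least once. Baseline
#' (concentration-0) phantoms are never part of either side.
#'
#' @param ds A `phantom_dataset` holding the complete design.
#' @return List with character vectors `train` (15 ids) and `validation`
#'   (12 ids).
#' @export
split_train_validation <- function(ds) {
  stopifnot(inherits(ds, "phantom_dataset"))
  meta <- as.data.frame(ds)
  meta <- meta[meta$concentration > 0, ]
  mua_lv <- sort(unique(meta$mua_mean))
  musp_lv <- sort(unique(meta$musp_mean))
  conc_lv <- sort(unique(meta$concentration))
  cells <- expand.grid(mua = mua_lv, musp = musp_lv, conc = conc_lv)
  have <- paste(meta$mua_mean, meta$musp_mean, meta$concentration)
  want <- paste(cells$mua, cells$musp, cells$conc)
  if (length(mua_lv) != 3L || length(musp_lv) != 3L || length(conc_lv) != 3L ||
      !all(want %in% have)) {
    stop("incomplete 3x3x3 design; missing cells: ",
         paste(setdiff(want, have), collapse = "; "), call. = FALSE)
  }
  in_train <- function(i0, j0, k0) {
    k0 == (i0 + j0) %% 3 ||
      ((i0 == j0 || (i0 - j0) %% 3 == 1) && k0 == (i0 + j0 + 1) %% 3)
  }
  train <- character(0); validation <- character(0)
  for (r in seq_len(nrow(meta))) {
    i0 <- match(meta$mua_mean[r], mua_lv) - 1L
    j0 <- match(meta$musp_mean[r], musp_lv) - 1L
    k0 <- match(meta$concentration[r], conc_lv) - 1L
    if (in_train(i0, j0, k0)) train <- c(train, meta$phantom_id[r])
    else validation <- c(validation, meta$phantom_id[r])
  }
  list(train = train, validation = validation)
}

# Per-phantom quantities the objective needs: raw emission-peak intensity
# and the two reflectance terms, plus the true concentration for grouping.
fit_data <- function(ds, cfg, ids = NULL) {
  stopifnot(inherits(ds, "phantom_dataset"), inherits(cfg, "correction_config"))
  if (!isTRUE(ds$calibrated))
    stop("dataset must be calibrated first (see calibrate_dataset)", call. = FALSE)
  ph <- ds$phantoms
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(ph))
    if (length(missing))
      stop("unknown phantom id(s): ", paste(missing, collapse = ", "), call. = FALSE)
    ph <- ph[ids]
  }
  ph <- Filter(function(p) p$concentration > 0, ph)
  rows <- lapply(ph, function(p) {
    terms <- reflectance_terms(p$reflectance, cfg)
    data.frame(phantom_id = p$phantom_id, concentration = p$concentration,
               peak_raw = value_at(p$fluorescence, cfg$em_band$cwl),
               Rex = terms[["Rex"]], Rem = terms[["Rem"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Relative-variation objective for the power fit
#'
#' For each group of phantoms sharing a true fluorophore concentration,
#' computes the coefficient of variation (sample SD / mean) of the
#' corrected emission-peak intensities, then averages the group CVs. The
#' optimal powers make corrected intensities depend on concentration only,
#' driving this to 0.
#'
#' @param powers Numeric `c(alpha, beta)`.
#' @param data data.frame with columns `concentration`, `peak_raw`, `Rex`,
#'   `Rem` (one row per phantom; concentrations > 0).
#' @return Non-negative scalar: the mean group CV.
#' @export
cv_objective <- function(powers, data) {
  stopifnot(length(powers) == 2L, all(is.finite(powers)))
  if (any(data$concentration <= 0))
    stop("objective requires concentrations > 0", call. = FALSE)
  corrected <- data$peak_raw / (data$Rex^powers[1] * data$Rem^powers[2])
  groups <- split(corrected, data$concentration)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every concentration group needs >= 2 phantoms (got sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  cvs <- vapply(groups, function(g) {
    m <- mean(g)
    if (!is.finite(m) || m == 0)
      stop("degenerate group: zero or non-finite mean corrected intensity",
           call. = FALSE)
    stats::sd(g) / m
  }, numeric(1))
  mean(abs(cvs))
}

#' Fit the correction powers by multi-start bounded optimization
#'
#' Minimizes [cv_objective] over `(alpha, beta)` (or over `alpha` alone
#' with `beta = -alpha` in single-power mode) with L-BFGS-B inside
#' `power_bounds`, restarted from a fixed deterministic grid of starting
#' points spanning the bounds. Ties within 1e-9 of the best objective are
#' broken toward the smallest `|alpha| + |beta|`.
#'
#' @param data Training rows as produced internally from a calibrated
#'   dataset (columns `concentration`, `peak_raw`, `Rex`, `Rem`).
#' @param cfg [correction_config].
#' @return List with `powers` (named c(alpha, beta)), `objective_value`,
#'   `n_restarts_used`, `converged`.
#' @export
fit_powers <- function(data, cfg) {
  stopifnot(inherits(cfg, "correction_config"))
  lo <- cfg$power_bounds[1]; hi <- cfg$power_bounds[2]
  single <- cfg$mode == "single_power"
  obj2 <- function(p) cv_objective(p, data)
  if (single) {
    starts <- as.matrix(seq(lo, hi, length.out = 9))
    fn <- function(a) obj2(c(a, -a))
    lower <- lo; upper <- hi
  } else {
    s <- seq(lo, hi, length.out = 5)
    starts <- as.matrix(expand.grid(s, s))
    fn <- obj2
    lower <- rep(lo, 2); upper <- rep(hi, 2)
  }
  start_vals <- vapply(seq_len(nrow(starts)), function(i)
    tryCatch(fn(starts[i, ]), error = function(e) NA_real_), numeric(1))
  if (all(!is.finite(start_vals)))
    stop("objective non-finite at every starting point: degenerate data",
         call. = FALSE)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))[is.finite(start_vals)]) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    cand <- list(par = res$par, value = res$value, conv = res$convergence == 0)
    if (is.null(best)) { best <- cand; next }
    if (cand$value < best$value - 1e-9) best <- cand
    else if (abs(cand$value - best$value) <= 1e-9) {
      size <- function(p) if (single) 2 * abs(p[1]) else sum(abs(p))
      if (size(cand$par) < size(best$par)) best <- cand
    }
  }
  if (is.null(best))
    stop("power fit failed: no restart converged to a finite objective",
         call. = FALSE)
  powers <- if (single) c(alpha = unname(best$par[1]), beta = -unname(best$par[1]))
            else c(alpha = unname(best$par[1]), beta = unname(best$par[2]))
  list(powers = powers, objective_value = best$value,
       n_restarts_used = n_ok, converged = best$conv)
}

#' Fit the ratiometric attenuation-correction model
#'
#' The central estimator. Given a calibrated phantom dataset with paired
#' diffuse-reflectance and fluorescence spectra across a grid of optical
#' properties and fluorophore concentrations, finds the pair of
#' system-dependent powers `(alpha, beta)` such that
#' `Fcorr = Fraw / (Rex^alpha * Rem^beta)` converges phantoms of equal
#' concentration onto a common corrected intensity. Fitting minimizes the
#' mean within-concentration coefficient of variation of corrected
#' emission-peak intensities over the training phantoms.
#'
#' @param dataset A `phantom_dataset`; calibrated automatically if raw.
#' @param config A [correction_config]; defaults to the probe's standard
#'   single-wavelength configuration.
#' @param training Character vector of training phantom ids; defaults to
#'   the deterministic 15-phantom stratified split of
#'   [split_train_validation].
#' @return Object of class `ratiometric_fit` with components `powers`,
#'   `objective_value`, `objective_uncorrected`, `n_restarts_used`,
#'   `converged`, `training_ids`, `validation_ids`, `config`, `probe`.
#' @seealso [predict.ratiometric_fit], [evaluate_correction]
#' @examples
#' ds <- generate_design("2nbdg", forward_params(seed = 1))
#' fit <- fit_ratiometric(ds)
#' coef(fit)
#' @export
fit_ratiometric <- function(dataset, config = NULL, training = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  if (is.null(config)) config <- default_correction_config(dataset$probe$name)
  validation_ids <- NULL
  if (is.null(training)) {
    split <- split_train_validation(dataset)
    training <- split$train
    validation_ids <- split$validation
  }
  data <- fit_data(dataset, config, training)
  res <- fit_powers(data, config)
  structure(list(
    powers = res$powers,
    objective_value = res$objective_value,
    objective_uncorrected = cv_objective(c(0, 0), data),
    n_restarts_used = res$n_restarts_used,
    converged = res$converged,
    training_ids = training,
    validation_ids = validation_ids,
    config = config,
    probe = dataset$probe$name,
    call = match.call()),
    class = "ratiometric_fit")
}

#' @export
coef.ratiometric_fit <- function(object, ...) object$powers

#' @export
print.ratiometric_fit <- function(x, ...) {
  cat("Ratiometric attenuation-correction fit (", x$config$mode, ")\n", sep = "")
  cat(sprintf("  probe: %s;  Rex @ %g nm (bw %g), Rem @ %g nm (bw %g)\n",
              x$probe, x$config$ex_band$cwl, x$config$ex_band$bw,
              x$config$em_band$cwl, x$config$em_band$bw))
  cat(sprintf("  powers: alpha = %.4f, beta = %.4f\n",
              x$powers["alpha"], x$powers["beta"]))
  cat(sprintf("  mean within-concentration CV: %.4g (uncorrected %.4g)\n",
              x$objective_value, x$objective_uncorrected))
  invisible(x)
}

#' @export
summary.ratiometric_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ratiometric_fit")
}

#' @export
print.summary.ratiometric_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  training phantoms: %d; validation phantoms: %d\n",
              length(f$training_ids),
              if (is.null(f$validation_ids)) 0L else length(f$validation_ids)))
  cat(sprintf("  restarts used: %d; converged: %s\n",
              f$n_restarts_used, f$converged))
  invisible(x)
}

#' Apply a fitted correction to phantom spectra
#'
#' Corrects the fluorescence spectrum of each (by default, each turbid)
#' phantom in a dataset with the fitted powers and that phantom's own
#' reflectance terms.
#'
#' @param object A `ratiometric_fit`.
#' @param dataset A calibrated `phantom_dataset` (calibrated automatically
#'   if raw).
#' @param ids Optional character vector of phantom ids; default all
#'   phantoms with concentration > 0.
#' @param ... Unused.
#' @return List of corrected [spectrum] objects; each `meta` carries
#'   `concentration`, `mua_mean`, `musp_mean`, `Rex`, `Rem` and the powers.
#' @export
predict.ratiometric_fit <- function(object, dataset, ids = NULL, ...) {
  correct_dataset(dataset, object$config,
                  alpha = object$powers[["alpha"]],
                  beta = object$powers[["beta"]], ids = ids)
}

#' Correct every phantom in a dataset with given powers
#'
#' @param dataset A `phantom_dataset`; calibrated automatically if raw.
#' @param config [correction_config] giving the reflectance bands.
#' @param alpha,beta Correction powers; `alpha = beta = 0` returns the
#'   calibrated fluorescence unchanged (useful for scoring the uncorrected
#'   data with the same machinery).
#' @param ids Optional phantom ids; default all with concentration > 0.
#' @return List of corrected [spectrum] objects with design metadata.
#' @export
correct_dataset <- function(dataset, config, alpha, beta, ids = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  ph <- dataset$phantoms
  if (!is.null(ids)) ph <- ph[ids]
  ph <- Filter(function(p) p$concentration > 0, ph)
  lapply(unname(ph), function(p) {
    terms <- reflectance_terms(p$reflectance, config)
    s <- correct_spectrum(p$fluorescence, terms[["Rex"]], terms[["Rem"]],
                          alpha, beta)
    s$meta$mua_mean <- p$mua_mean
    s$meta$musp_mean <- p$musp_mean
    s
  })
}

#' Plot corrected spectra against the fluorophore-only references
#'
#' @param x A `ratiometric_fit`.
#' @param dataset The `phantom_dataset` to correct and display.
#' @param ... Passed to [graphics::matplot].
#' @return Invisibly, the corrected spectra.
#' @export
plot.ratiometric_fit <- function(x, dataset, ...) {
  corrected <- predict(x, dataset)
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  err <- percent_error(corrected, dataset$controls, em_cwl = x$config$em_band$cwl)
  wl <- corrected[[1]]$wavelength
  mat <- vapply(corrected, function(s) s$intensity * err$scale_factor,
                numeric(length(wl)))
  graphics::matplot(wl, mat, type = "l", lty = 2, col = "grey40",
                    xlab = "wavelength (nm)", ylab = "intensity (a.u.)", ...)
  for (ctl in dataset$controls)
    graphics::lines(ctl$spectrum$wavelength, ctl$spectrum$intensity,
                    lwd = 2, col = "firebrick")
  graphics::legend("topright", bty = "n", lty = c(2, 1), lwd = c(1, 2),
                   col = c("grey40", "firebrick"),
                   legend = c("corrected (scaled)", "reference"))
  invisible(corrected)
}
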