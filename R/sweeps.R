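# Filter-design studies: how the bandwidth and central wavelength of the
# reflectance terms affect correction accuracy and the fitted powers.

sweep_cell <- function(ds, ex_band, em_band, mode, training) {
  cfg <- suppressWarnings(correction_config(ex_band, em_band, mode = mode))
  fit <- fit_ratiometric(ds, config = cfg, training = training)
  rep <- evaluate_correction(fit, ds)
  c(error = rep$error$mean_pct,
    alpha = fit$powers[["alpha"]], beta = fit$powers[["beta"]])
}

sweep_result <- function(kind, axis1, axis2, cells) {
  err <- matrix(cells["error", ], length(axis1), length(axis2), byrow = FALSE)
  al <- matrix(cells["alpha", ], length(axis1), length(axis2), byrow = FALSE)
  be <- matrix(cells["beta", ], length(axis1), length(axis2), byrow = FALSE)
  dimnames(err) <- dimnames(al) <- dimnames(be) <- list(axis1, axis2)
  amin <- arrayInd(which.min(err), dim(err))
  structure(list(kind = kind, axis1 = axis1, axis2 = axis2,
                 error_matrix = err, alpha_matrix = al, beta_matrix = be,
                 argmin = c(row = amin[1], col = amin[2])),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<%s sweep: %d x %d cells, min error %.2f%% at (%s, %s)>\n",
              x$kind, length(x$axis1), length(x$axis2), min(x$error_matrix),
              x$axis1[x$argmin["row"]], x$axis2[x$argmin["col"]]))
  invisible(x)
}

#' Bandwidth sweep of the reflectance correction bands
#'
#' For every pair of excitation/emission bandwidths, rebuilds the
#' correction configuration with band-summed reflectance terms at fixed
#' central wavelengths, refits the powers on the training split from
#' scratch, and scores the mean percent error over the full phantom set.
#' Cells are independent: each equals a standalone fit+evaluate run at
#' that configuration.
#'
#' @param dataset A `phantom_dataset`.
#' @param cwl_ex,cwl_em Fixed central wavelengths, nm; default the probe's
#'   standard correction wavelengths.
#' @param bandwidths Bandwidths (nm) swept on both axes; default
#'   `c(5, 10, 20, 30, 40)`.
#' @param mode Correction model variant.
#' @return Object of class `sweep_result` with `error_matrix` (%),
#'   `alpha_matrix`, `beta_matrix` indexed `[bw_ex, bw_em]`.
#' @export
bandwidth_sweep <- function(dataset, cwl_ex = NULL, cwl_em = NULL,
                            bandwidths = c(5, 10, 20, 30, 40),
                            mode = "two_power") {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  base <- default_correction_config(dataset$probe$name)
  if (is.null(cwl_ex)) cwl_ex <- base$ex_band$cwl
  if (is.null(cwl_em)) cwl_em <- base$em_band$cwl
  training <- split_train_validation(dataset)$train
  grid <- expand.grid(bw_ex = bandwidths, bw_em = bandwidths)
  cells <- vapply(seq_len(nrow(grid)), function(i)
    sweep_cell(dataset, band(cwl_ex, grid$bw_ex[i]), band(cwl_em, grid$bw_em[i]),
               mode, training),
    numeric(3))
  sweep_result("bandwidth", bandwidths, bandwidths, cells)
}

#' Central-wavelength sweep of the reflectance correction bands
#'
#' Analogous to [bandwidth_sweep] but over pairs of excitation/emission
#' central wavelengths at a fixed bandwidth (default 10 nm). Default CWL
#' lists cover the neighbourhood of each probe's excitation source and
#' emission peak.
#'
#' @param dataset A `phantom_dataset`.
#' @param cwls_ex,cwls_em Central wavelength lists, nm.
#' @param bw Fixed bandwidth, nm.
#' @param mode Correction model variant.
#' @return `sweep_result` indexed `[cwl_ex, cwl_em]`.
#' @export
cwl_sweep <- function(dataset, cwls_ex = NULL, cwls_em = NULL, bw = 10,
                      mode = "two_power") {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!isTRUE(dataset$calibrated)) dataset <- calibrate_dataset(dataset)
  probe <- dataset$probe$name
  if (is.null(cwls_ex))
    cwls_ex <- if (probe == "2nbdg") c(440, 450, 470, 490) else c(530, 550, 570)
  if (is.null(cwls_em))
    cwls_em <- if (probe == "2nbdg") c(530, 550, 570, 590) else c(570, 580, 600)
  training <- split_train_validation(dataset)$train
  grid <- expand.grid(ex = cwls_ex, em = cwls_em)
  cells <- vapply(seq_len(nrow(grid)), function(i)
    sweep_cell(dataset, band(grid$ex[i], bw), band(grid$em[i], bw),
               mode, training),
    numeric(3))
  sweep_result("cwl", cwls_ex, cwls_em, cells)
}
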