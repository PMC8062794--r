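#' Write a phantom dataset to disk
#'
#' Exports every phantom's reflectance and fluorescence spectrum, the
#' control spectra and the standard measurement as spectra CSV files, plus
#' a `manifest.json` binding them to the ground-truth design metadata.
#'
#' @param ds A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  for (p in ds$phantoms)
    write_spectra(list(p$reflectance, p$fluorescence),
                  file.path(dir, "spectra", paste0(p$phantom_id, ".csv")))
  write_spectra(lapply(ds$controls, `[[`, "spectrum"),
                file.path(dir, "spectra", "controls.csv"))
  write_spectra(list(ds$standards$refl_standard_meas),
                file.path(dir, "spectra", "standards.csv"))
  manifest <- list(
    probe = ds$probe$name,
    forward = unclass(ds$params),
    mua_levels = ds$mua_levels, musp_levels = ds$musp_levels,
    concentrations = ds$concentrations,
    refl_standard_value = ds$standards$refl_standard_value,
    fluor_standard_factor = ds$standards$fluor_standard_factor,
    calibrated = isTRUE(ds$calibrated),
    phantoms = as.data.frame(ds),
    controls = data.frame(
      phantom_id = vapply(ds$controls, function(x) x$spectrum$meta$phantom_id,
                          character(1)),
      concentration = vapply(ds$controls, `[[`, numeric(1), "concentration")))
  path <- file.path(dir, "manifest.json")
  write_json_out(manifest, path)
  invisible(path)
}

#' Read a phantom dataset from a manifest
#'
#' Inverse of [write_dataset]: reassembles the `phantom_dataset` from the
#' spectra CSV files listed by a `manifest.json`.
#'
#' @param manifest_path Path to the manifest file.
#' @return A `phantom_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  grid <- NULL
  phantoms <- list()
  for (r in seq_len(nrow(m$phantoms))) {
    id <- m$phantoms$phantom_id[r]
    sp <- read_spectra(file.path(dir, "spectra", paste0(id, ".csv")))
    roles <- vapply(sp, `[[`, character(1), "role")
    refl <- sp[[match("reflectance", roles)]]
    fl <- sp[[match("fluorescence", roles)]]
    fl$meta$concentration <- m$phantoms$concentration[r]
    phantoms[[id]] <- list(
      phantom_id = id,
      mua_mean = m$phantoms$mua_mean[r], musp_mean = m$phantoms$musp_mean[r],
      concentration = m$phantoms$concentration[r],
      reflectance = refl, fluorescence = fl)
    grid <- refl$wavelength
  }
  ctl_sp <- read_spectra(file.path(dir, "spectra", "controls.csv"))
  ctl_ids <- vapply(ctl_sp, function(s) as.character(s$meta$phantom_id),
                    character(1))
  controls <- lapply(seq_len(nrow(m$controls)), function(r) {
    s <- ctl_sp[[match(m$controls$phantom_id[r], ctl_ids)]]
    s$meta$concentration <- m$controls$concentration[r]
    list(concentration = m$controls$concentration[r], spectrum = s)
  })
  std_meas <- read_spectra(file.path(dir, "spectra", "standards.csv"))[[1]]
  params <- do.call(forward_params, as.list(m$forward))
  structure(list(
    probe = fluorophore_model(m$probe),
    instrument = instrument_model(m$probe, grid),
    params = params,
    mua_levels = m$mua_levels, musp_levels = m$musp_levels,
    concentrations = m$concentrations,
    phantoms = phantoms, controls = controls,
    standards = standards_set(std_meas, m$refl_standard_value,
                              m$fluor_standard_factor),
    calibrated = isTRUE(m$calibrated)),
    class = "phantom_dataset")
}

#' Build a pipeline run configuration
#'
#' A fully serializable description of one end-to-end run: probe, forward
#' model, correction configuration, and seed. A stored config re-runs to
#' identical outputs.
#'
#' @param probe `"2nbdg"` or `"tmre"`.
#' @param mode Forward-model mode, `"diffusion"` or `"powerlaw"`.
#' @param correction_mode `"two_power"` or `"single_power"`.
#' @param bw Bandwidth (nm) of the correction bands; 0 = single wavelength.
#' @param seed Integer seed for the generator.
#' @param noise_rel Relative noise SD of the generator.
#' @param out_dir Output directory.
#' @param run_sweeps Logical: also run the bandwidth and CWL sweeps
#'   (slower).
#' @param forward Optional [forward_params] overriding `mode`, `seed`,
#'   `noise_rel`.
#' @return List of class `run_config`.
#' @export
run_config <- function(probe = "2nbdg", mode = "diffusion",
                       correction_mode = "two_power", bw = 0,
                       seed = 20210423L, noise_rel = 0.01,
                       out_dir = tempfile("fluorcorr_run"),
                       run_sweeps = FALSE, forward = NULL) {
  probe <- normalize_probe(probe)
  if (is.null(forward))
    forward <- forward_params(mode = mode, noise_rel = noise_rel, seed = seed)
  structure(list(probe = probe, forward = forward,
                 correction_mode = correction_mode, bw = bw,
                 seed = as.integer(seed), out_dir = out_dir,
                 run_sweeps = isTRUE(run_sweeps)),
            class = "run_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}

fit_to_list <- function(fit) {
  list(mode = fit$config$mode,
       ex_band = unclass(fit$config$ex_band), em_band = unclass(fit$config$em_band),
       alpha = fit$powers[["alpha"]], beta = fit$powers[["beta"]],
       objective_value = fit$objective_value,
       objective_uncorrected = fit$objective_uncorrected,
       n_restarts_used = fit$n_restarts_used, converged = fit$converged,
       training_ids = fit$training_ids)
}

report_to_list <- function(report, uncorr = NULL) {
  list(mean_pct = report$error$mean_pct,
       uncorrected_mean_pct = if (is.null(uncorr)) NULL else uncorr$mean_pct,
       group_means = as.list(report$error$group_means),
       scale_factor = report$error$scale_factor,
       per_phantom = report$estimates,
       calibration_curve = unclass(report$curve),
       bland_altman = unclass(report$agreement))
}

#' Run the full pipeline: simulate, calibrate, fit, evaluate (and sweep)
#'
#' Executes the stages in order against a synthetic phantom dataset,
#' writing machine-readable outputs under `config$out_dir`: the spectra
#' CSV files and `manifest.json` with ground truth ([write_dataset]),
#' `fit.json` with the fitted powers, `report.json` with the percent-error
#' report, calibration curve and Bland-Altman agreement, and (optionally)
#' sweep matrices. A `run.log` records stage timings and the effective
#' configuration. Equal configs and seeds reproduce byte-identical JSON
#' outputs.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the dataset, fit, report, sweeps and the
#'   output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-10s %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    val
  }

  ds <- stage("simulate", generate_design(config$probe, config$forward))
  stage("export", write_dataset(ds, out))
  ds <- stage("calibrate", calibrate_dataset(ds))
  cfg <- default_correction_config(config$probe, mode = config$correction_mode,
                                   bw = config$bw)
  fit <- stage("fit", fit_ratiometric(ds, config = cfg))
  stage("write_fit",
        write_json_out(c(list(probe = config$probe), fit_to_list(fit)),
                       file.path(out, "fit.json")))
  report <- stage("evaluate", evaluate_correction(fit, ds))
  uncorr <- stage("evaluate0", {
    raw0 <- correct_dataset(ds, cfg, 0, 0)
    percent_error(raw0, ds$controls, em_cwl = cfg$em_band$cwl)
  })
  stage("write_report",
        write_json_out(report_to_list(report, uncorr),
                       file.path(out, "report.json")))

  sweeps <- NULL
  if (config$run_sweeps) {
    sweeps <- stage("sweep", list(bandwidth = bandwidth_sweep(ds),
                                  cwl = cwl_sweep(ds)))
    stage("write_sweeps", for (k in names(sweeps)) {
      sw <- sweeps[[k]]
      write_json_out(list(kind = sw$kind, axis1 = sw$axis1, axis2 = sw$axis2,
                          error_matrix = sw$error_matrix,
                          alpha_matrix = sw$alpha_matrix,
                          beta_matrix = sw$beta_matrix),
                     file.path(out, paste0("sweep_", k, ".json")))
      utils::write.csv(sw$error_matrix,
                       file.path(out, paste0("sweep_", k, "_error.csv")))
    })
  }

  writeLines(c(sprintf("fluorcorr run: probe=%s forward=%s correction=%s bw=%g seed=%d",
                       config$probe, config$forward$mode, config$correction_mode,
                       config$bw, config$seed),
               sprintf("effective forward params: %s",
                       paste(names(unclass(config$forward)),
                             unlist(config$forward), sep = "=", collapse = " ")),
               log_lines), file.path(out, "run.log"))
  invisible(list(dataset = ds, fit = fit, report = report,
                 uncorrected = uncorr, sweeps = sweeps, out_dir = out))
}
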