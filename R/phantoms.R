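#' Fluorophore models for the metabolic probes
#'
#' Spectral parameters of the two probe families the package targets: a
#' glucose-analog probe (2-NBDG-like, excitation peak 470 nm, emission peak
#' 550 nm, concentrations in micromolar) and a mitochondrial
#' membrane-potential probe (TMRE-like, excitation peak 550 nm, emission
#' peak 580 nm, concentrations in nanomolar).
#'
#' @param name `"2nbdg"` or `"tmre"` (aliases `"2-NBDG"`, `"TMRE"` accepted).
#' @return List with fields `name`, `ex_peak`, `em_peak`, `em_fwhm` (nm),
#'   `brightness` (intensity per concentration unit), `conc_units`.
#' @export
fluorophore_model <- function(name = c("2nbdg", "tmre")) {
  name <- normalize_probe(name)
  switch(name,
    "2nbdg" = list(name = "2nbdg", ex_peak = 470, em_peak = 550, em_fwhm = 60,
                   brightness = 100, conc_units = "uM"),
    "tmre"  = list(name = "tmre", ex_peak = 550, em_peak = 580, em_fwhm = 40,
                   brightness = 3, conc_units = "nM"))
}

normalize_probe <- function(name) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(name[1])))
  if (key %in% c("2nbdg", "nbdg")) return("2nbdg")
  if (key == "tmre") return("tmre")
  stop("unknown probe '", name[1], "' (expected '2nbdg' or 'tmre')", call. = FALSE)
}

#' Synthetic instrument model
#'
#' Excitation bandpass filter, collection long-pass cut-on, a smooth
#' source+detector wavelength response, and the reflectivity of the
#' calibration standard puck. Defaults follow a typical LED + compact
#' spectrometer platform: 450/25 nm bandpass and 515 nm long-pass for the
#' glucose probe channel, 549/25 nm bandpass and 575 nm long-pass for the
#' membrane-potential probe channel, and a 20 % reflectance standard.
#'
#' @param probe Probe name, see [fluorophore_model].
#' @param grid Wavelength grid for the response spectrum.
#' @return List with `ex_filter` ([band]), `longpass_cut` (nm), `response`
#'   ([spectrum], strictly positive), `standard_reflectivity`.
#' @export
instrument_model <- function(probe = "2nbdg", grid = default_grid()) {
  probe <- normalize_probe(probe)
  resp <- 0.55 + 0.45 * exp(-((grid - 620) / 170)^2)  # broad, strictly positive
  list(
    ex_filter = if (probe == "2nbdg") band(450, 25) else band(549, 25),
    longpass_cut = if (probe == "2nbdg") 515 else 575,
    response = spectrum(grid, resp, role = "standard",
                        meta = list(channel = "response")),
    standard_reflectivity = 0.20
  )
}

#' Forward-model parameters for the synthetic phantoms
#'
#' Parameterizes the in-silico stand-in for liquid tissue-mimicking
#' phantoms. In `diffusion` mode the diffuse reflectance follows the
#' semi-infinite diffusion-theory total-reflectance formula (a strictly
#' increasing function of the transport albedo) and the fluorescence of
#' each propagation leg attenuates like that reflectance raised to the
#' ratio of the leg's effective path to the reflectance sampling path; in
#' `powerlaw` mode the fluorescence distortion is injected exactly in the
#' ratiometric form `Rex^p * Rem^q`, which makes the whole pipeline
#' exactly invertible and serves as a self-consistency oracle.
#'
#' @param mode `"diffusion"` or `"powerlaw"`.
#' @param d_refl Effective reflectance sampling path, cm; it normalizes
#'   the fluorescence path ratios `d_ex/d_refl` and `d_em/d_refl`.
#' @param d_ex Excitation penetration path, cm (diffusion mode).
#' @param d_em Emission escape path, cm (diffusion mode).
#' @param scatter_gain_exp Scales both fluorescence leg exponents relative
#'   to the reflectance path ratios (diffusion mode); 1 means each leg
#'   attenuates exactly like `R^(d/d_refl)`.
#' @param powerlaw_p,powerlaw_q Injected exponents (powerlaw mode).
#' @param noise_rel Relative (multiplicative Gaussian) noise SD of the
#'   fluorescence channel.
#' @param refl_noise_frac Reflectance-channel noise as a fraction of
#'   `noise_rel`. The broadband reflectance channel runs near detector
#'   full scale (it needs a strong neutral-density attenuator and tens of
#'   milliseconds of integration, against seconds for the photon-starved
#'   fluorescence channel), so its relative noise sits well over an order
#'   of magnitude lower; default 0.02.
#' @param seed Integer seed used by [generate_design].
#' @return List of class `forward_params`.
#' @export
forward_params <- function(mode = c("diffusion", "powerlaw"),
                           d_refl = 0.10, d_ex = 0.65, d_em = 0.01,
                           scatter_gain_exp = 1.0,
                           powerlaw_p = 5.96, powerlaw_q = -6.44,
                           noise_rel = 0.01, refl_noise_frac = 0.02,
                           seed = 20210423L) {
  mode <- match.arg(mode)
  stopifnot(d_refl >= 0, d_ex >= 0, d_em >= 0, noise_rel >= 0,
            refl_noise_frac >= 0)
  structure(list(mode = mode, d_refl = d_refl, d_ex = d_ex, d_em = d_em,
                 scatter_gain_exp = scatter_gain_exp,
                 powerlaw_p = powerlaw_p, powerlaw_q = powerlaw_q,
                 noise_rel = noise_rel, refl_noise_frac = refl_noise_frac,
                 seed = as.integer(seed)),
            class = "forward_params")
}

# mean of a spectrum's intensities over the 400-600 nm design band
band_mean_400_600 <- function(wavelength, values) {
  idx <- wavelength >= 400 & wavelength <= 600
  mean(values[idx])
}

#' Hemoglobin-like absorption spectrum
#'
#' Synthetic absorber shape: Gaussian Soret band at 415 nm plus Q bands at
#' 542 and 577 nm (FWHM 35/25/25 nm, relative amplitudes 10:1:1.2) on a flat
#' baseline of 5 % of the Soret amplitude, rescaled so its mean over
#' 400-600 nm equals `mua_mean` exactly.
#'
#' @param grid Wavelength grid, nm.
#' @param mua_mean Target band-average absorption coefficient, cm^-1 (> 0).
#' @return [spectrum] of absorption coefficients (cm^-1).
#' @export
absorber_mu_a <- function(grid = default_grid(), mua_mean) {
  if (!is.numeric(mua_mean) || mua_mean <= 0)
    stop("mua_mean must be > 0", call. = FALSE)
  g <- function(center, fwhm) exp(-(grid - center)^2 / (2 * (fwhm / 2.3548200450309493)^2))
  shape <- 10 * g(415, 35) + 1 * g(542, 25) + 1.2 * g(577, 25) + 0.5
  shape <- shape / band_mean_400_600(grid, shape)
  spectrum(grid, shape * mua_mean, role = "standard",
           meta = list(channel = "mu_a", mua_mean = mua_mean))
}

#' Intralipid-like reduced scattering spectrum
#'
#' Power law `mu_s'(lambda) = A * (lambda / 500 nm)^-2.4`, with `A` chosen so
#' the mean over 400-600 nm equals `musp_mean`.
#'
#' @param grid Wavelength grid, nm.
#' @param musp_mean Target band-average reduced scattering coefficient,
#'   cm^-1 (> 0).
#' @return [spectrum] of reduced scattering coefficients (cm^-1).
#' @export
scatterer_mu_sp <- function(grid = default_grid(), musp_mean) {
  if (!is.numeric(musp_mean) || musp_mean <= 0)
    stop("musp_mean must be > 0", call. = FALSE)
  shape <- (grid / 500)^(-2.4)
  shape <- shape / band_mean_400_600(grid, shape)
  spectrum(grid, shape * musp_mean, role = "standard",
           meta = list(channel = "mu_sp", musp_mean = musp_mean))
}

# transport albedo on raw numeric vectors
albedo <- function(mua, musp) musp / (mua + musp)

# internal-reflection parameter of the diffusion-theory reflectance;
# k = (1 + r_d)/(1 - r_d) ~ 2.5 for an aqueous medium probed through glass
.refl_internal_k <- 2.5

# semi-infinite diffusion-theory total reflectance as a function of the
# transport albedo (Flock-style): strictly increasing, R(0) = 0, R(1) = 1
diffusion_reflectance_of_albedo <- function(ap, k = .refl_internal_k) {
  ap / (1 + 2 * k * (1 - ap) + (1 + 2 * k / 3) * sqrt(3 * (1 - ap)))
}

#' Physics-level diffuse reflectance of a phantom
#'
#' Semi-infinite diffusion approximation: with transport albedo
#' `a' = mu_s' / (mu_a + mu_s')` and internal-reflection parameter
#' `k = 2.5`,
#' `R = a' / (1 + 2k(1 - a') + (1 + 2k/3) * sqrt(3 (1 - a')))`.
#' R is a strictly increasing function of the albedo, so it lies in
#' (0, 1), decreases with absorption and increases with reduced scattering
#' at every wavelength, and reaches 1 in the absorption-free limit.
#'
#' @param mua,musp [spectrum] objects on a shared grid (cm^-1).
#' @param params [forward_params].
#' @return [spectrum] with role `reflectance`.
#' @export
diffuse_reflectance <- function(mua, musp, params = forward_params()) {
  stopifnot(inherits(mua, "spectrum"), inherits(musp, "spectrum"))
  if (!isTRUE(all.equal(mua$wavelength, musp$wavelength)))
    stop("mu_a and mu_s' spectra must share a wavelength grid", call. = FALSE)
  r <- diffusion_reflectance_of_albedo(albedo(mua$intensity, musp$intensity))
  spectrum(mua$wavelength, r, role = "reflectance",
           meta = c(mua$meta["mua_mean"], musp$meta["musp_mean"]))
}

# intrinsic emission as seen by the instrument (no turbidity distortion)
intrinsic_emission <- function(probe, concentration, instrument,
                               grid = instrument$response$wavelength) {
  sigma <- probe$em_fwhm / 2.3548200450309493
  g <- exp(-(grid - probe$em_peak)^2 / (2 * sigma^2))
  g[grid < instrument$longpass_cut] <- 0
  f <- probe$brightness * concentration * g * instrument$response$intensity
  spectrum(grid, f, role = "fluorescence",
           meta = list(probe = probe$name, concentration = concentration))
}

#' Raw (distorted) fluorescence of a turbid phantom
#'
#' Builds the intrinsic emission line shape (Gaussian at the probe's
#' emission peak, truncated below the collection long-pass cut, scaled by
#' brightness, concentration and the instrument response), then applies the
#' turbidity distortion. In `diffusion` mode each propagation leg
#' attenuates like the phantom's diffuse reflectance raised to the leg's
#' path ratio,
#' `R(ex)^(s * d_ex/d_refl) * R(lambda)^(s * d_em/d_refl)` with
#' `s = scatter_gain_exp`; the excitation leg is collapsed to the
#' excitation-filter central wavelength while the escape leg is resolved
#' per emission wavelength — so the distortion is carried by measurable
#' reflectance (the operating regime of the ratiometric correction) but
#' its wavelength dependence across the emission band still defeats any
#' single-wavelength correction exactly.
#' In `powerlaw` mode it is `Rex^p * Rem^q` with `Rex`, `Rem`
#' this phantom's diffuse reflectance at the probe's default correction
#' wavelengths. Multiplicative Gaussian noise of relative SD
#' `params$noise_rel` is drawn from the current RNG stream (seed it, or use
#' [generate_design] which seeds once per dataset) and the result clipped
#' at 0.
#'
#' @param phantom_spec List with `concentration` (>= 0) and optionally
#'   `phantom_id`.
#' @param mua,musp [spectrum] optical-property spectra of the phantom.
#' @param probe [fluorophore_model].
#' @param instrument [instrument_model].
#' @param params [forward_params].
#' @return [spectrum] with role `fluorescence`.
#' @export
raw_fluorescence <- function(phantom_spec, mua, musp, probe,
                             instrument = instrument_model(probe$name),
                             params = forward_params()) {
  conc <- phantom_spec$concentration
  if (!is.numeric(conc) || conc < 0)
    stop("concentration must be >= 0", call. = FALSE)
  grid <- mua$wavelength
  f_intr <- intrinsic_emission(probe, conc, instrument, grid)
  if (params$mode == "diffusion") {
    lam_ex <- instrument$ex_filter$cwl
    r_ex <- diffusion_reflectance_of_albedo(
      albedo(value_at(mua, lam_ex), value_at(musp, lam_ex)))
    r_em <- diffusion_reflectance_of_albedo(
      albedo(mua$intensity, musp$intensity))
    dist <- r_ex^(params$scatter_gain_exp * params$d_ex / params$d_refl) *
      r_em^(params$scatter_gain_exp * params$d_em / params$d_refl)
  } else {
    cfg <- default_correction_config(probe$name)
    r <- diffuse_reflectance(mua, musp, params)
    dist <- value_at(r, cfg$ex_band$cwl)^params$powerlaw_p *
      value_at(r, cfg$em_band$cwl)^params$powerlaw_q
  }
  f <- f_intr$intensity * dist
  if (params$noise_rel > 0)
    f <- f * (1 + stats::rnorm(length(f), sd = params$noise_rel))
  f <- pmax(f, 0)
  spectrum(grid, f, role = "fluorescence",
           meta = list(probe = probe$name, concentration = conc,
                       phantom_id = phantom_spec$phantom_id))
}

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate the full phantom study design for one probe
#'
#' Emulates the wet-lab design: a 3 x 3 grid of band-average optical
#' properties (mu_a in {1.5, 3.0, 4.5} cm^-1, mu_s' in {4.5, 9.0, 13.5}
#' cm^-1 over 400-600 nm) crossed with a concentration series (0-9 uM by
#' 3 uM for the glucose probe; 0-300 nM by 100 nM for the
#' membrane-potential probe). This yields 27 turbid fluorescence phantoms
#' (9 optical combinations x 3 nonzero concentrations), each carrying one
#' raw reflectance and one raw fluorescence spectrum, plus 9 baseline
#' (concentration-0) phantoms and 3 fluorophore-only control spectra with
#' no absorber or scatterer. Standard-puck measurements for calibration are
#' included. The RNG is seeded once from `params$seed`, so equal seeds give
#' bit-identical datasets.
#'
#' @param probe Probe name or [fluorophore_model].
#' @param params [forward_params].
#' @param mua_levels,musp_levels Band-average optical-property grids, cm^-1.
#' @param concentrations Concentration series including 0; defaults to the
#'   probe's design series.
#' @param grid Wavelength grid.
#' @return Object of class `phantom_dataset`.
#' @export
generate_design <- function(probe = "2nbdg", params = forward_params(),
                            mua_levels = c(1.5, 3.0, 4.5),
                            musp_levels = c(4.5, 9.0, 13.5),
                            concentrations = NULL,
                            grid = default_grid()) {
  if (is.character(probe)) probe <- fluorophore_model(probe)
  instrument <- instrument_model(probe$name, grid)
  if (is.null(concentrations))
    concentrations <- if (probe$name == "2nbdg") c(0, 3, 6, 9) else c(0, 100, 200, 300)
  stopifnot(all(concentrations >= 0), any(concentrations > 0))

  run_with_seed(params$seed, {
    phantoms <- list()
    for (a in mua_levels) for (s in musp_levels) {
      mua <- absorber_mu_a(grid, a)
      musp <- scatterer_mu_sp(grid, s)
      r_phys <- diffuse_reflectance(mua, musp, params)
      for (conc in concentrations) {
        id <- sprintf("%s_a%.1f_s%.1f_c%g", probe$name, a, s, conc)
        refl_raw <- r_phys$intensity * instrument$response$intensity
        refl_sd <- params$noise_rel * params$refl_noise_frac
        if (refl_sd > 0)
          refl_raw <- pmax(refl_raw * (1 + stats::rnorm(length(refl_raw),
                                                        sd = refl_sd)), 0)
        fl <- raw_fluorescence(list(concentration = conc, phantom_id = id),
                               mua, musp, probe, instrument, params)
        phantoms[[id]] <- list(
          phantom_id = id, mua_mean = a, musp_mean = s, concentration = conc,
          reflectance = spectrum(grid, refl_raw, role = "reflectance",
                                 meta = list(phantom_id = id, probe = probe$name,
                                             channel = "reflectance")),
          fluorescence = fl)
      }
    }
    controls <- lapply(concentrations[concentrations > 0], function(conc) {
      f <- intrinsic_emission(probe, conc, instrument, grid)
      y <- f$intensity
      if (params$noise_rel > 0)
        y <- pmax(y * (1 + stats::rnorm(length(y), sd = params$noise_rel)), 0)
      list(concentration = conc,
           spectrum = spectrum(grid, y, role = "fluorescence",
                               meta = list(phantom_id = sprintf("control_c%g", conc),
                                           probe = probe$name, channel = "control",
                                           concentration = conc)))
    })
    std_meas <- spectrum(grid,
                         instrument$standard_reflectivity * instrument$response$intensity,
                         role = "standard", meta = list(channel = "refl_standard"))
    structure(list(
      probe = probe, instrument = instrument, params = params,
      mua_levels = mua_levels, musp_levels = musp_levels,
      concentrations = concentrations,
      phantoms = phantoms, controls = controls,
      standards = standards_set(refl_standard_meas = std_meas,
                                refl_standard_value = instrument$standard_reflectivity,
                                fluor_standard_factor = 1.0),
      calibrated = FALSE),
      class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  n_turbid <- sum(vapply(x$phantoms, function(p) p$concentration > 0, logical(1)))
  cat(sprintf("<phantom_dataset probe=%s mode=%s: %d turbid + %d baseline phantoms, %d controls%s>\n",
              x$probe$name, x$params$mode, n_turbid,
              length(x$phantoms) - n_turbid, length(x$controls),
              if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Phantom metadata table
#'
#' @param x A `phantom_dataset`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return data.frame with one row per phantom: id, band-average optical
#'   properties, concentration.
#' @export
as.data.frame.phantom_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(unname(x$phantoms), function(p)
    data.frame(phantom_id = p$phantom_id, mua_mean = p$mua_mean,
               musp_mean = p$musp_mean, concentration = p$concentration,
               stringsAsFactors = FALSE)))
}
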