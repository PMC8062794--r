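# fluorcorr

Rapid ratiometric attenuation correction for fluorescence spectra
measured on turbid media, with a synthetic tissue-mimicking phantom
study to fit and validate the correction without instrument data.

Fluorescence measured on tissue or liquid phantoms is distorted by
hemoglobin absorption and scattering: optically different samples with
the same fluorophore concentration can differ in measured intensity by
an order of magnitude. For metabolic probes — 2-NBDG (glucose uptake,
excitation ~450 nm / emission peak 550 nm) and TMRE (mitochondrial
membrane potential, ~550 / 580 nm) — this blocks real-time *in vivo*
quantification, and model-based inversion (inverse Monte Carlo) is too
slow. The ratiometric correction divides the raw spectrum by the same
site's diffuse reflectance at the excitation and emission wavelengths,
raised to a pair of system-dependent powers:

    Fcorr(lambda) = Fraw(lambda) / (Rex^alpha * Rem^beta)

with the one-parameter simplification
`Fcorr = Fraw / (Rex/Rem)^alpha` also supported. The powers are fitted
once on reference phantoms by minimizing the relative variation
(mean within-concentration CV) of corrected emission-peak intensities
across phantoms that share a true concentration, using a deterministic
15/12 train/validation split of the 27-phantom design; after that the
correction is a single arithmetic operation per spectrum.

The package provides:

- `spectrum()`, `band()`, `value_at()`, `band_sum()`,
  `read_spectra()` / `write_spectra()` — wavelength-grid spectra, band
  operations, and the spectra CSV dialect;
- `generate_design()` — the synthetic phantom study (3 × 3 optical grid
  × concentration series, fluorophore-only controls, standards), with a
  diffusion-theory forward model and an exactly invertible `powerlaw`
  oracle mode;
- `calibrate_dataset()` — reflectance-standard and excitation-power
  calibration;
- `fit_ratiometric()` — the estimator; returns a classed fit with
  `print`, `summary`, `coef`, `predict`, `plot` methods;
- `evaluate_correction()` — percent error versus the fluorophore-only
  references (one global scale), concentration calibration curve,
  Bland–Altman agreement;
- `bandwidth_sweep()`, `cwl_sweep()` — filter-design studies;
- `run_pipeline()` and a thin CLI (`inst/cli/fluorcorr`) for
  simulate → calibrate → fit → evaluate runs with JSON/CSV outputs.

## Worked example

```r
library(fluorcorr)

ds  <- calibrate_dataset(generate_design("2nbdg", forward_params(seed = 42)))
fit <- fit_ratiometric(ds)
fit
#> Ratiometric attenuation-correction fit (two_power)
#>   probe: 2nbdg;  Rex @ 450 nm (bw 0), Rem @ 550 nm (bw 0)
#>   powers: alpha = 6.7225, beta = -0.0862
#>   mean within-concentration CV: 0.009688 (uncorrected 1.744)

evaluate_correction(fit, ds)
#> Correction report (alpha = 6.723, beta = -0.086)
#> Percent error vs references: mean 2.10% over 27 phantoms (global scale 1.015)
#>   varying-absorption group: 2.01%; varying-scattering group: 2.15%
#> Calibration line: intensity = 91.39 * conc + 0.5271  (n = 27)
#>   R^2 = 0.9992, Pearson r = 0.9996, p = 2.65e-40
#> Bland-Altman: mean diff 5.757e-16, SD 0.07022, LoA [-0.1376, 0.1376] (n = 27)
```

Reading the numbers: before correction the phantoms' emission-peak
intensities vary by a factor of several among equal concentrations
(within-concentration CV 1.74); the fitted powers collapse that to
below 1 %. Against the fluorophore-only reference spectra the corrected
set is off by 2.1 % on average, the corrected peak intensity is linear
in true concentration (R² = 0.9992), and concentration estimates from
the inverted calibration line agree with truth to ±0.14 µM
(95 % limits of agreement).

The same pipeline runs from a shell:

```sh
Rscript inst/cli/fluorcorr run --probe 2nbdg --seed 42 --out out/
```

writing `manifest.json`, the spectra CSVs, `fit.json` and
`report.json`.

## Scope

The methods vignette (`vignettes/ratiometric-correction.Rmd`) documents
the model, the synthetic forward model and its frozen defaults, the
fitting and scoring choices, and known limitations — including why the
single-power simplification underperforms on this synthetic design. Not
in scope: photon-transport simulation, fiber-probe geometry, hemoglobin
oxidation chemistry, vendor spectrometer formats, instrument control.
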