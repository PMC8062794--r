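# simple emission-like reference shape on a coarse grid
ref_shape <- function(conc = 1) {
  g <- seq(500, 620, 2)
  spectrum(g, conc * exp(-(g - 550)^2 / (2 * 20^2)), role = "fluorescence",
           meta = list(concentration = conc, phantom_id = paste0("ref", conc)))
}

test_that("percent error is zero for perfect correction and absorbs global scale", {
  refs <- list(ref_shape(1), ref_shape(2))
  corrected <- lapply(refs, function(r) {
    r$meta$phantom_id <- paste0("c", r$meta$concentration); r
  })
  rep0 <- percent_error(corrected, refs)
  expect_equal(rep0$mean_pct, 0)
  expect_equal(rep0$scale_factor, 1)

  doubled <- lapply(corrected, function(s) { s$intensity <- 2 * s$intensity; s })
  rep2 <- percent_error(doubled, refs)
  expect_equal(rep2$scale_factor, 0.5)
  expect_equal(rep2$mean_pct, 0)
})

test_that("two-member toy set matches the closed-form least-squares scalar", {
  r <- ref_shape(1)
  hi <- r; hi$intensity <- 1.1 * hi$intensity; hi$meta$phantom_id <- "hi"
  lo <- r; lo$intensity <- 0.9 * lo$intensity; lo$meta$phantom_id <- "lo"
  rep <- percent_error(list(hi, lo), list(r))
  # s = sum(fc*fr)/sum(fc^2) = (1.1 + 0.9)/(1.1^2 + 0.9^2) = 1/1.01
  expect_equal(rep$scale_factor, 1 / 1.01)
  expect_equal(unname(rep$per_phantom_pct["hi"]), 100 * abs(1.1 / 1.01 - 1))
  expect_equal(unname(rep$per_phantom_pct["lo"]), 100 * abs(0.9 / 1.01 - 1))
})

test_that("percent error is invariant to rescaling the whole corrected set", {
  ds <- cached_dataset("2nbdg")
  cfg <- default_correction_config("2nbdg")
  corrected <- correct_dataset(ds, cfg, 2, -1)
  scaled <- lapply(corrected, function(s) { s$intensity <- 17 * s$intensity; s })
  expect_equal(percent_error(scaled, ds$controls)$per_phantom_pct,
               percent_error(corrected, ds$controls)$per_phantom_pct)
})

test_that("unmatched concentrations and degenerate references error out", {
  r <- ref_shape(1)
  odd <- r; odd$meta$concentration <- 99
  expect_error(percent_error(list(odd), list(r)), "no unique reference")
  flat0 <- r; flat0$intensity[] <- 0
  expect_error(percent_error(list(r), list(flat0)), "all-zero reference")
})

test_that("calibration curve matches the normal equations on a 4-point set", {
  x <- c(0, 3, 6, 9)
  y <- c(0.1, 3.2, 5.9, 9.3)
  # independent arithmetic straight from the normal equations
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))

  cur <- fit_calibration_curve(y, x)
  expect_equal(cur$slope, slope)
  expect_equal(cur$intercept, intercept)
  expect_equal(cur$pearson_r, r)
  expect_equal(cur$r_squared, r^2, tolerance = 1e-12)
  expect_equal(cur$n, 4L)

  perm <- sample(4)
  cur2 <- fit_calibration_curve(y[perm], x[perm])
  expect_equal(cur2$slope, cur$slope)
  expect_equal(cur2$r_squared, cur$r_squared)
})

test_that("exact lines and degenerate inputs behave as specified", {
  # an exactly collinear input makes summary.lm warn about a perfect fit
  cur <- suppressWarnings(fit_calibration_curve(c(0, 3, 6, 9), c(0, 3, 6, 9)))
  expect_equal(cur$slope, 1)
  expect_equal(cur$intercept, 0)
  expect_equal(cur$r_squared, 1)
  expect_lt(cur$p_value, 1e-4)
  expect_error(fit_calibration_curve(1:4, rep(2, 4)), "all equal")
  expect_error(fit_calibration_curve(1:2, 1:2), "at least 3")
})

test_that("concentration estimation inverts the curve exactly", {
  cur <- fit_calibration_curve(c(1.0, 4.1, 6.9, 10.2), c(0, 3, 6, 9))
  for (c0 in c(0, 2.5, 7)) {
    expect_equal(estimate_concentration(cur$slope * c0 + cur$intercept, cur), c0)
  }
  expect_equal(estimate_concentration(cur$intercept, cur), 0)
  expect_warning(estimate_concentration(cur$intercept - 1, cur), "negative")

  # batch application then Pearson against truth reproduces the curve's r
  peaks <- c(1.0, 4.1, 6.9, 10.2)
  est <- estimate_concentration(peaks, cur)
  expect_equal(cor(est, c(0, 3, 6, 9)), cur$pearson_r)
})

test_that("Bland-Altman statistics satisfy the LoA identity", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(0, 2), c(1, 1))   # diffs -1, +1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))

  set.seed(51)
  est <- rnorm(10); tru <- rnorm(10)
  a <- bland_altman(est, tru)
  b <- bland_altman(est + 3, tru)
  expect_equal(b$mean_diff, a$mean_diff + 3)
  expect_equal(b$sd_diff, a$sd_diff)
  expect_equal(b$loa_low, a$loa_low + 3)

  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("evaluate_correction ties the pieces together coherently", {
  ds <- cached_dataset("2nbdg")
  fit <- fit_ratiometric(ds)
  rep <- evaluate_correction(fit, ds)
  expect_s3_class(rep$curve, "calibration_curve")
  expect_equal(rep$agreement$mean_diff,
               mean(rep$estimates$estimate - rep$estimates$concentration))
  expect_equal(rep$error$n, 27)
  expect_named(rep$error$group_means, c("absorption", "scattering"))
})
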