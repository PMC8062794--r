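test_that("train/validation split is a stratified 15/12 partition", {
  ds <- cached_dataset("2nbdg")
  sp <- split_train_validation(ds)
  expect_length(sp$train, 15)
  expect_length(sp$validation, 12)
  expect_length(intersect(sp$train, sp$validation), 0)
  meta <- as.data.frame(ds)
  turbid <- meta$phantom_id[meta$concentration > 0]
  expect_setequal(c(sp$train, sp$validation), turbid)

  tr <- meta[meta$phantom_id %in% sp$train, ]
  combos <- unique(tr[, c("mua_mean", "musp_mean")])
  expect_equal(nrow(combos), 9)                      # every optical combination
  expect_setequal(unique(tr$concentration), c(3, 6, 9))  # every concentration

  # same by construction for a fresh dataset: the split is deterministic
  expect_identical(split_train_validation(cached_dataset("2nbdg")), sp)
})

test_that("incomplete designs are rejected with the missing cells named", {
  ds <- cached_dataset("2nbdg")
  ds$phantoms[["2nbdg_a3.0_s9.0_c6"]] <- NULL
  expect_error(split_train_validation(ds), "missing cells: 3 9 6")
})

test_that("objective is the mean within-concentration CV of corrected peaks", {
  d <- data.frame(concentration = c(1, 1), peak_raw = c(1, 3),
                  Rex = 1, Rem = 1)
  expect_equal(cv_objective(c(0, 0), d), sqrt(2) / 2)

  d2 <- data.frame(concentration = rep(c(1, 2), each = 3),
                   peak_raw = rep(c(5, 8), each = 3), Rex = 1, Rem = 1)
  expect_equal(cv_objective(c(0, 0), d2), 0)

  # scale invariance: scaling one whole group's raw intensities changes nothing
  d3 <- d2
  d3$peak_raw[d3$concentration == 2] <- 10 * d3$peak_raw[d3$concentration == 2]
  d3$peak_raw <- d3$peak_raw * c(1, 1.2, 0.8, 1.1, 0.9, 1)
  expect_equal(cv_objective(c(0.7, -0.2), d3),
               cv_objective(c(0.7, -0.2),
                            within(d3, peak_raw[concentration == 1] <-
                                     5 * peak_raw[concentration == 1])))

  expect_error(cv_objective(c(0, 0),
                            data.frame(concentration = c(1, 2, 2),
                                       peak_raw = 1, Rex = 1, Rem = 1)),
               ">= 2 phantoms")
  expect_error(cv_objective(c(0, 0),
                            data.frame(concentration = c(1, 1),
                                       peak_raw = c(1, -1), Rex = 1, Rem = 1)),
               "degenerate group")
})

test_that("noiseless powerlaw data: the fit inverts the injected exponents", {
  ds <- cached_dataset("2nbdg", noiseless_powerlaw())
  fit <- fit_ratiometric(ds)
  expect_lt(abs(coef(fit)[["alpha"]] - 5.96), 0.05)
  expect_lt(abs(coef(fit)[["beta"]] - (-6.44)), 0.05)
  expect_lt(fit$objective_value, 1e-6)
  expect_true(fit$converged)

  # brute-force cross-check: no grid point beats the optimizer
  data <- fluorcorr:::fit_data(ds, fit$config, fit$training_ids)
  pts <- seq(-25, 25, length.out = 21)
  grid_vals <- outer(pts, pts, Vectorize(function(a, b)
    cv_objective(c(a, b), data)))
  expect_gte(min(grid_vals), fit$objective_value - 1e-6)
})

test_that("with 1% noise the powerlaw distortion is still inverted", {
  # The two reflectance terms are strongly correlated across the optical
  # design, so at 1% noise the individual exponents are only identified
  # up to a drift along the (1, -1) ridge; the identifiable sum and the
  # achieved convergence are what noise leaves testable.
  fp <- forward_params(mode = "powerlaw", noise_rel = 0.01, seed = 6)
  fit <- fit_ratiometric(cached_dataset("2nbdg", fp))
  expect_lt(abs(sum(coef(fit)) - (5.96 - 6.44)), 0.5)
  expect_lt(fit$objective_value, 0.03)
})

test_that("undistorted data fit to zero powers and zero objective", {
  ds <- cached_dataset("2nbdg", noiseless_powerlaw(p = 0, q = 0, seed = 8))
  data <- fluorcorr:::fit_data(ds, default_correction_config("2nbdg"),
                               split_train_validation(ds)$train)
  expect_equal(cv_objective(c(0, 0), data), 0)
  fit <- fit_ratiometric(ds)
  expect_lt(fit$objective_value, 1e-8)
})

test_that("fit is invariant to phantom order and never worse than uncorrected", {
  ds <- cached_dataset("2nbdg")
  sp <- split_train_validation(ds)
  f1 <- fit_ratiometric(ds, training = sp$train)
  f2 <- fit_ratiometric(ds, training = rev(sp$train))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_lte(f1$objective_value, f1$objective_uncorrected)
})

test_that("the fitted model exposes the usual accessors", {
  ds <- cached_dataset("2nbdg")
  fit <- fit_ratiometric(ds)
  expect_named(coef(fit), c("alpha", "beta"))
  expect_output(print(fit), "alpha")
  expect_output(print(summary(fit)), "training phantoms: 15")
  corrected <- predict(fit, ds)
  expect_length(corrected, 27)
  expect_true(all(vapply(corrected, inherits, logical(1), "spectrum")))
})
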