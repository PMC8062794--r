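grid <- default_grid()

test_that("absorber spectrum hits its band mean and hemoglobin-like shape", {
  mua <- absorber_mu_a(grid, 3.0)
  in_band <- grid >= 400 & grid <= 600
  expect_equal(mean(mua$intensity[in_band]), 3.0)

  a1 <- absorber_mu_a(grid, 1.5)
  a3 <- absorber_mu_a(grid, 4.5)
  expect_equal(a3$intensity, 3 * a1$intensity)

  expect_gt(value_at(mua, 415), value_at(mua, 650))
  expect_error(absorber_mu_a(grid, -1), "must be > 0")
})

test_that("scatterer spectrum is a decreasing power law with exact band mean", {
  musp <- scatterer_mu_sp(grid, 9.0)
  in_band <- grid >= 400 & grid <= 600
  expect_equal(mean(musp$intensity[in_band]), 9.0)
  expect_gt(value_at(musp, 400), value_at(musp, 600))
  expect_equal(scatterer_mu_sp(grid, 18)$intensity, 2 * musp$intensity)
})

test_that("diffuse reflectance behaves like a semi-infinite turbid medium", {
  fp <- forward_params(noise_rel = 0)
  musp <- scatterer_mu_sp(grid, 9.0)

  # mu_a -> 0: R -> transport albedo -> 1
  tiny <- absorber_mu_a(grid, 1e-9)
  expect_true(all(diffuse_reflectance(tiny, musp, fp)$intensity > 0.999))

  # strictly decreasing in absorption, increasing in scattering, at every
  # wavelength, across the design levels
  for (s in c(4.5, 9, 13.5)) {
    r <- lapply(c(1.5, 3, 4.5), function(a)
      diffuse_reflectance(absorber_mu_a(grid, a), scatterer_mu_sp(grid, s), fp))
    expect_true(all(r[[1]]$intensity > r[[2]]$intensity))
    expect_true(all(r[[2]]$intensity > r[[3]]$intensity))
  }
  for (a in c(1.5, 3, 4.5)) {
    r <- lapply(c(4.5, 9, 13.5), function(s)
      diffuse_reflectance(absorber_mu_a(grid, a), scatterer_mu_sp(grid, s), fp))
    expect_true(all(r[[1]]$intensity < r[[2]]$intensity))
    expect_true(all(r[[2]]$intensity < r[[3]]$intensity))
  }
  r <- diffuse_reflectance(absorber_mu_a(grid, 3), musp, fp)
  expect_true(all(r$intensity > 0 & r$intensity < 1))

  short <- scatterer_mu_sp(seq(400, 500, 1), 9)
  expect_error(diffuse_reflectance(absorber_mu_a(grid, 3), short, fp),
               "share a wavelength grid")
})

test_that("raw fluorescence is linear in concentration with multiplicative distortion", {
  probe <- fluorophore_model("2nbdg")
  inst <- instrument_model("2nbdg", grid)
  mua <- absorber_mu_a(grid, 3)
  musp <- scatterer_mu_sp(grid, 9)
  fp0 <- forward_params(noise_rel = 0)

  zero <- raw_fluorescence(list(concentration = 0), mua, musp, probe, inst, fp0)
  expect_true(all(zero$intensity == 0))
  expect_error(raw_fluorescence(list(concentration = -1), mua, musp, probe,
                                inst, fp0), ">= 0")

  # powerlaw with p = q = 0: no distortion at all
  plain <- forward_params(mode = "powerlaw", powerlaw_p = 0, powerlaw_q = 0,
                          noise_rel = 0)
  f <- raw_fluorescence(list(concentration = 6), mua, musp, probe, inst, plain)
  f_intr <- fluorcorr:::intrinsic_emission(probe, 6, inst, grid)
  expect_equal(f$intensity, f_intr$intensity)

  # diffusion mode: Fraw / F_intr independent of concentration
  f3 <- raw_fluorescence(list(concentration = 3), mua, musp, probe, inst, fp0)
  f9 <- raw_fluorescence(list(concentration = 9), mua, musp, probe, inst, fp0)
  sup <- f3$intensity > 0
  expect_equal(f9$intensity[sup] / f3$intensity[sup],
               rep(3, sum(sup)))
})

test_that("generate_design reproduces the 27 + 9 + 3 study layout", {
  ds <- generate_design("2nbdg", forward_params(seed = 21))
  meta <- as.data.frame(ds)
  expect_equal(sum(meta$concentration > 0), 27)
  expect_equal(sum(meta$concentration == 0), 9)
  expect_length(ds$controls, 3)
  expect_equal(sort(vapply(ds$controls, `[[`, numeric(1), "concentration")),
               c(3, 6, 9))
  # conservation: every (optical level, concentration) cell appears once
  expect_equal(nrow(unique(meta[, c("mua_mean", "musp_mean", "concentration")])),
               36)
  expect_error(generate_design("unknown-probe"), "unknown probe")
})

test_that("equal seeds give bit-identical datasets", {
  a <- generate_design("tmre", forward_params(seed = 77))
  b <- generate_design("tmre", forward_params(seed = 77))
  expect_identical(a, b)
})

test_that("reflectance shows absorber dips that deepen with absorption", {
  fp <- forward_params(noise_rel = 0)
  r_at <- function(a) {
    r <- diffuse_reflectance(absorber_mu_a(grid, a), scatterer_mu_sp(grid, 9), fp)
    c(dip = value_at(r, 542), shoulder = value_at(r, 560))
  }
  lo <- r_at(1.5); hi <- r_at(4.5)
  expect_lt(lo["dip"], lo["shoulder"])
  expect_lt(hi["dip"], hi["shoulder"])
  # relative dip depth grows with absorber level
  expect_gt(1 - hi["dip"] / hi["shoulder"], 1 - lo["dip"] / lo["shoulder"])
})
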