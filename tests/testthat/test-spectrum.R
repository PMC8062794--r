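test_that("value_at interpolates linearly and is exact on grid samples", {
  flat <- spectrum(400:900, rep(2, 501))
  expect_identical(value_at(flat, 550), 2)

  two <- spectrum(c(400, 401), c(1, 3))
  expect_equal(value_at(two, 400.5), 2)

  set.seed(11)
  s <- spectrum(seq(400, 500, 10), runif(11))
  expect_identical(value_at(s, 450), s$intensity[6])
  expect_error(value_at(s, 600), "outside grid span")
})

test_that("value_at stays between its bracketing samples", {
  set.seed(12)
  s <- spectrum(seq(400, 500, 5), runif(21))
  for (lam in runif(25, 400, 500)) {
    i <- findInterval(lam, s$wavelength)
    lo <- min(s$intensity[i:(i + 1)])
    hi <- max(s$intensity[i:(i + 1)])
    v <- value_at(s, lam)
    expect_gte(v, lo - 1e-12)
    expect_lte(v, hi + 1e-12)
  }
})

test_that("band_sum sums grid samples over a closed interval", {
  ones <- spectrum(400:900, rep(1, 501))
  expect_equal(band_sum(ones, band(550, 10)), 11)  # 545..555 inclusive

  set.seed(13)
  s <- spectrum(400:900, runif(501))
  expect_identical(band_sum(s, band(550, 0)), s$intensity[151])
  expect_equal(band_sum(s, band(650, 1000)), sum(s$intensity))
  expect_error(band_sum(s, band(300, 10)), "no grid samples")
})

test_that("band_sum is additive over disjoint sample sets", {
  set.seed(14)
  s <- spectrum(400:900, runif(501))
  left <- band_sum(s, band(505, 10))      # samples 500..510
  right <- band_sum(s, band(515.5, 9))    # samples 511..520
  expect_equal(left + right, band_sum(s, band(510, 20)))  # 500..520
})

test_that("spectra CSV files round-trip losslessly with metadata", {
  set.seed(15)
  sp <- list(
    spectrum(400:410, runif(11), role = "reflectance",
             meta = list(phantom_id = "p1", probe = "2nbdg", channel = "refl")),
    spectrum(400:410, runif(11), role = "fluorescence",
             meta = list(phantom_id = "p1", probe = "2nbdg", channel = "fl")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_length(back, 2)
  chan <- vapply(back, function(s) s$meta$channel, character(1))
  for (i in 1:2) {
    b <- back[[match(sp[[i]]$meta$channel, chan)]]
    expect_equal(b$wavelength, sp[[i]]$wavelength)
    expect_equal(b$intensity, sp[[i]]$intensity)
    expect_identical(b$role, sp[[i]]$role)
    expect_identical(b$meta$phantom_id, "p1")
  }
})

test_that("malformed spectra files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("wavelength_nm,intensity,role,phantom_id,probe,channel",
               "402,1.0,reflectance,p,x,c",
               "401,1.1,reflectance,p,x,c"), path)
  expect_error(read_spectra(path), "not strictly increasing")

  writeLines(c("wavelength_nm,intensity,phantom_id,probe,channel",
               "400,1.0,p,x,c"), path)
  expect_error(read_spectra(path), "role")

  writeLines(c("wavelength_nm,intensity,role,phantom_id,probe,channel",
               "400,1.0,reflectance,p,x,c",
               "401,NA,reflectance,p,x,c"), path)
  expect_error(read_spectra(path), "NA intensity")
})
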