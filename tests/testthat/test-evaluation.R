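test_that("normalized DTW distance behaves like a distance", {
  x <- sin(1:200 / 7) + 0.1 * cos(1:200 / 3)
  expect_equal(normalized_dtw(x, x), 0)
  # forced diagonal path oracle (internal normalization disabled)
  expect_equal(normalized_dtw(c(0, 0, 0), c(1, 1, 1), normalize = FALSE), 1)
  y <- cos(1:150 / 9)
  expect_equal(normalized_dtw(x, y), normalized_dtw(y, x))
  expect_gte(normalized_dtw(x, y), 0)
})

test_that("normalized DTW is invariant to affine rescaling of either input", {
  set.seed(2)
  x <- rnorm(150); y <- rnorm(120)
  base <- normalized_dtw(x, y)
  expect_equal(normalized_dtw(5 * x + 40, y), base, tolerance = 1e-12)
  expect_equal(normalized_dtw(x, -0.2 + 0.01 * y), base, tolerance = 1e-12)
})

test_that("CWT spectrum of a constant vanishes and of a sine peaks at its frequency", {
  cst <- cwt_spectrum(rep(5, 256), n_scales = 32)
  expect_lt(max(cst$magnitudes), 1e-6 * 5)

  fs <- 4000
  for (f0 in c(200, 800)) {
    x <- sin(2 * pi * f0 * (0:2047) / fs)
    sp <- cwt_spectrum(x, n_scales = 64, sample_rate_hz = fs)
    peak <- which.max(rowMeans(sp$magnitudes))
    # within one scale step of f0
    ratio <- sp$frequencies_hz[2] / sp$frequencies_hz[1]
    fpk <- sp$frequencies_hz[peak]
    expect_lt(abs(log(fpk / f0)), abs(log(ratio)) * 1.0 + 1e-9)
  }
})

test_that("CWT spectra are deterministic with a descending frequency axis", {
  x <- rnorm(300)
  s1 <- cwt_spectrum(x); s2 <- cwt_spectrum(x)
  expect_identical(s1$magnitudes, s2$magnitudes)
  expect_true(all(diff(s1$frequencies_hz) < 0))
  expect_equal(dim(s1$magnitudes), c(64L, 300L))
  expect_true(all(s1$magnitudes >= 0))
  expect_error(cwt_spectrum(rnorm(10)), "too short")
})

test_that("spectrum PCC detects identity, affine maps and anti-correlation", {
  set.seed(8)
  s1 <- cwt_spectrum(rnorm(400) + sin(1:400 / 5))
  expect_equal(spectrum_pcc(s1, s1), list(pcc_all = 1, pcc_low = 1,
                                          pcc_high = 1))
  s2 <- s1; s2$magnitudes <- 3 * s1$magnitudes + 2
  r <- spectrum_pcc(s1, s2)
  expect_equal(r$pcc_all, 1); expect_equal(r$pcc_low, 1)
  expect_equal(r$pcc_high, 1)
  s3 <- s1; s3$magnitudes <- -s1$magnitudes + 7
  r <- spectrum_pcc(s1, s3)
  expect_equal(r$pcc_all, -1); expect_equal(r$pcc_high, -1)
})

test_that("PCC of independent noise spectra is near zero and bounded", {
  set.seed(11)
  s1 <- cwt_spectrum(rnorm(512), n_scales = 32)
  s2 <- cwt_spectrum(rnorm(512), n_scales = 32)
  r <- spectrum_pcc(s1, s2)
  for (v in unlist(r)) expect_true(v >= -1 && v <= 1)
  # magnitudes are strongly dependent within a spectrum, so allow a loose
  # bound well below perfect correlation rather than 3/sqrt(cells)
  expect_lt(abs(r$pcc_all), 0.5)
})

test_that("mismatched spectra are rejected", {
  s1 <- cwt_spectrum(rnorm(128), n_scales = 16)
  s2 <- cwt_spectrum(rnorm(256), n_scales = 16)
  expect_error(spectrum_pcc(s1, s2), "shape")
  s3 <- cwt_spectrum(rnorm(128), n_scales = 16, sample_rate_hz = 1000)
  expect_error(spectrum_pcc(s1, s3), "frequency axes")
})
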