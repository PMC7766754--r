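test_that("repeat counts stay in bounds and reproduce with the seed", {
  counts <- sample_repeat_counts(5000, seed = 3)
  expect_true(all(counts >= 1))
  expect_true(all(counts <= 40))
  expect_identical(counts, sample_repeat_counts(5000, seed = 3))
  expect_false(identical(counts, sample_repeat_counts(5000, seed = 4)))
})

test_that("default repeat model mean matches the 450 bp/s / 4 kHz dwell regime", {
  counts <- sample_repeat_counts(1e5, seed = 1)
  expect_gt(mean(counts), 8)
  expect_lt(mean(counts), 9)
})

test_that("a degenerate zero-scale component collapses to its location", {
  m <- repeat_model(components = list(
    list(weight = 1, a = 4, location = 5, scale = 0)))
  expect_true(all(sample_repeat_counts(500, m, seed = 1) == 5L))
})

test_that("invalid repeat models are rejected", {
  expect_error(repeat_model(components = list(
    list(weight = 0.5, a = 4, location = 1, scale = 28))), "sum to 1")
  expect_error(repeat_model(min_repeat = 0), ">= 1")
  expect_error(sample_repeat_counts(0), ">= 1")
})

test_that("ground truth assembly concatenates repeated levels", {
  gt <- assemble_ground_truth(c(80, 95), c(2L, 3L))
  expect_equal(as.numeric(gt), c(80, 80, 95, 95, 95))
  expect_equal(length(gt), sum(attr(gt, "repeats")))
  ev <- c(1.5, 2.5, -3)
  expect_equal(as.numeric(assemble_ground_truth(ev, c(1L, 1L, 1L))), ev)
  expect_error(assemble_ground_truth(c(80, 95), c(0L, 3L)), ">= 1")
  expect_error(assemble_ground_truth(c(80, 95), c(2L)), "length")
})

test_that("sample conservation holds across random repeat draws", {
  for (s in 1:5) {
    ev <- runif(50, 60, 120)
    reps <- sample_repeat_counts(50, seed = s)
    expect_length(assemble_ground_truth(ev, reps), sum(reps))
  }
})

test_that("gaussian noise has the configured moments and no time correlation", {
  expect_identical(add_gaussian_noise(1:10, std = 0), as.numeric(1:10))
  n <- 1e6
  e <- add_gaussian_noise(numeric(n), std = 2.0, seed = 1)
  se_sd <- 2.0 / sqrt(2 * (n - 1))   # SE of a normal sample sd
  expect_lt(abs(sd(e) - 2.0), 3 * se_sd)
  expect_lt(abs(mean(e)), 3 * 2.0 / sqrt(n))
  lag1 <- cor(e[-1], e[-n])
  expect_lt(abs(lag1), 3 / sqrt(n))
  expect_identical(e, add_gaussian_noise(numeric(n), std = 2.0, seed = 1))
  expect_false(identical(e, add_gaussian_noise(numeric(n), std = 2.0, seed = 2)))
  expect_error(add_gaussian_noise(1:5, std = -1), ">= 0")
})

test_that("z-score normalization is exact and invertible", {
  z <- zscore_normalize(c(1, 3))
  expect_equal(mean(z$values), 0)
  expect_equal(sd(z$values), 1)
  x <- rnorm(200, 90, 8)
  z <- zscore_normalize(x)
  expect_equal(zscore_denormalize(z$values, z$stats), x, tolerance = 1e-12)
  expect_error(zscore_normalize(c(5, 5, 5)), "constant")
  expect_error(zscore_normalize(7), "length >= 2")
})
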