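test_that("dtw_path solves the textbook examples", {
  a <- c(1, 2, 3)
  p <- dtw_path(a, a)
  expect_equal(p$total_cost, 0)
  expect_equal(p$steps, cbind(i = 1:3, j = 1:3))

  p <- dtw_path(c(1, 2, 3), c(1, 3))
  expect_equal(p$total_cost, 1)
  expect_equal(p$steps[1, ], c(i = 1, j = 1))
  expect_equal(p$steps[nrow(p$steps), ], c(i = 3, j = 2))

  # length-1 b forces every a sample onto b[1]
  a <- rnorm(8)
  p <- dtw_path(a, 0.5)
  expect_equal(p$total_cost, sum(abs(a - 0.5)))
})

test_that("dtw_path equals the exhaustive DP oracle on small instances", {
  set.seed(17)
  vals <- c(-2, -0.5, 0, 0.3, 1, 2.5)
  for (rep in 1:60) {
    n <- sample(1:10, 1); m <- sample(1:10, 1)
    a <- sample(vals, n, replace = TRUE)
    b <- sample(vals, m, replace = TRUE)
    p <- dtw_path(a, b)
    expect_equal(p$total_cost, oracle_dtw_cost(a, b), tolerance = 1e-12)
    # path validity: monotone unit steps from (1,1) to (n,m)
    expect_equal(p$steps[1, ], c(i = 1, j = 1))
    expect_equal(unname(p$steps[nrow(p$steps), ]), c(n, m))
    di <- diff(p$steps[, 1]); dj <- diff(p$steps[, 2])
    expect_true(all(di %in% 0:1 & dj %in% 0:1 & (di + dj) > 0))
  }
})

test_that("banded dtw matches exact dtw when the band is wide enough", {
  set.seed(3)
  a <- rnorm(120); b <- rnorm(100)
  exact <- dtw_path(a, b)
  banded <- dtw_path(a, b, band_radius = 60)
  expect_equal(banded$total_cost, exact$total_cost, tolerance = 1e-12)
  expect_error(dtw_path(a, b, band_radius = 0.5), "band_radius")
})

test_that("label_read recovers an exact repeat expansion", {
  pm <- synthetic_pore_model(2)
  sq <- random_sequence(60, seed = 1)
  ev <- expected_signal(sq, pm)
  # repeat 1 each: raw IS the expected signal
  pair <- label_read(as.numeric(ev), ev)
  expect_equal(attr(pair, "ground_truth"), as.numeric(ev))
  expect_equal(attr(pair, "expected_index"), seq_along(ev))

  reps <- sample_repeat_counts(length(ev), seed = 2)
  gt <- assemble_ground_truth(ev, reps)
  pair <- label_read(as.numeric(gt), ev)
  expect_length(pair$I, length(gt))
  expect_length(pair$R, length(gt))
  expect_gte(mean(attr(pair, "ground_truth") == as.numeric(gt)), 0.99)
  # monotone index assignment along the raw signal
  expect_true(all(diff(attr(pair, "expected_index")) >= 0))
})

test_that("label_read recovers >= 95% of positions under noise", {
  pm <- synthetic_pore_model(4)
  set.seed(1)
  rates <- vapply(1:20, function(r) {
    sq <- random_sequence(80)
    ev <- expected_signal(sq, pm)
    reps <- sample_repeat_counts(length(ev))
    gt <- as.numeric(assemble_ground_truth(ev, reps))
    zg <- zscore_normalize(gt)
    raw <- zscore_denormalize(zg$values + rnorm(length(gt), sd = 0.1),
                              zg$stats)
    pair <- label_read(raw, ev)
    mean(attr(pair, "ground_truth") == gt)
  }, numeric(1))
  expect_gte(mean(rates), 0.95)
})
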