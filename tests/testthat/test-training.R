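test_that("log-cosh loss matches its closed form and asymptote", {
  expect_equal(log_cosh_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(log_cosh_loss(1, 0), log(cosh(1)))
  expect_lt(abs(log_cosh_loss(1, 0) - 0.433781), 1e-6)
  expect_lt(abs(log_cosh_loss(100, 0) - (100 - log(2))), 1e-9)
  expect_lt(abs(log_cosh_loss(0, 1000) - (1000 - log(2))), 1e-9)
  expect_error(log_cosh_loss(1:3, 1:2), "equal lengths")
})

test_that("log-cosh loss is non-negative, symmetric and at most linear", {
  set.seed(4)
  for (rep in 1:20) {
    o <- rnorm(30, sd = 5); r <- rnorm(30, sd = 5)
    l <- log_cosh_loss(o, r)
    expect_gte(l, 0)
    expect_equal(l, log_cosh_loss(r, o))       # sign symmetry
    expect_lte(l, sum(abs(o - r)))             # linear upper bound
  }
  expect_identical(log_cosh_loss(1:5, 1:5), 0)
})

test_that("xavier draws respect the fan-in/fan-out bound", {
  W <- xavier_init(2, 4, seed = 1)
  expect_equal(dim(W), c(4L, 2L))
  expect_true(all(abs(W) <= 1))  # bound = sqrt(6/6) = 1
  draws <- xavier_init(500, 200, seed = 2)  # 1e5 entries
  bound <- sqrt(6 / 700)
  expect_true(all(abs(draws) <= bound))
  expect_lt(abs(mean(draws)), 3 * bound / sqrt(3 * length(draws)))
  # order statistics approach the edges
  expect_lt(bound - max(draws), 0.01 * bound)
  expect_lt(min(draws) + bound, 0.01 * bound)
  expect_gt(min(draws), -bound)
})

test_that("chunking follows the remainder rule and is reproducible", {
  p1024 <- training_pair(rnorm(1024), rnorm(1024))
  ch <- make_chunks(list(p1024), window_length = 512, seed = 1)
  expect_equal(ch$n_windows, 2L)
  expect_true(all(ch$mask == 1))

  p700 <- training_pair(rnorm(700), rnorm(700))
  ch <- make_chunks(list(p700), window_length = 512, seed = 1)
  expect_equal(ch$n_windows, 1L)  # 188-sample remainder < 256 is discarded

  p800 <- training_pair(rnorm(800), rnorm(800))
  ch <- make_chunks(list(p800), window_length = 512, seed = 1)
  expect_equal(ch$n_windows, 2L)  # 288 >= 256 is kept, zero-padded
  expect_equal(sum(ch$mask[, 2]), 288)
  expect_equal(ch$I[289:512, 2], rep(0, 224))

  ch1 <- make_chunks(list(p1024, p800), window_length = 512, batch_size = 2,
                     seed = 7)
  ch2 <- make_chunks(list(p1024, p800), window_length = 512, batch_size = 2,
                     seed = 7)
  expect_identical(ch1$batches, ch2$batches)
  expect_error(make_chunks(list(training_pair(rnorm(100), rnorm(100))),
                           window_length = 512), "no usable windows")
})

test_that("zero-iteration fits return the untouched initialization", {
  ds <- make_dataset(n_reads = 4, seq_length = 60, seed = 2)
  fit <- bigru_fit(ds$pairs, hidden_size = 4, iterations = 0,
                   window_length = 32, seed = 9)
  ref <- bigru_network(hidden_size = 4, seed = 9)
  expect_length(fit$loss, 0)
  expect_identical(fit$net$layers[[1]]$fwd$Wz, ref$layers[[1]]$fwd$Wz)
  expect_identical(fit$net$fc_weight, ref$fc_weight)
})

test_that("training descends and is seed-reproducible on a tiny dataset", {
  ds <- make_dataset(n_reads = 20, seq_length = 60, seed = 1)
  fit <- bigru_fit(ds$pairs, hidden_size = 8, iterations = 100,
                   window_length = 64, batch_size = 16, seed = 1)
  expect_length(fit$loss, 100)
  expect_lt(mean(tail(fit$loss, 10)), mean(head(fit$loss, 10)))
  fit2 <- bigru_fit(ds$pairs, hidden_size = 8, iterations = 100,
                    window_length = 64, batch_size = 16, seed = 1)
  expect_identical(fit$loss, fit2$loss)
  expect_identical(fit$net$fc_weight, fit2$net$fc_weight)
})

test_that("fit methods expose the model in the standard S3 vocabulary", {
  ds <- make_dataset(n_reads = 6, seq_length = 60, seed = 3)
  fit <- bigru_fit(ds$pairs, hidden_size = 4, iterations = 10,
                   window_length = 32, batch_size = 4, seed = 1)
  expect_s3_class(fit, "bigru_fit")
  expect_output(print(fit), "BiGRU")
  s <- summary(fit)
  expect_output(print(s), "last 10 steps")
  cf <- coef(fit)
  expect_true(all(c("layer1.fwd", "layer3.bwd", "fc_weight") %in% names(cf)))
  pr <- predict(fit, ds$reads[[1]]$ground_truth)
  expect_length(pr, length(ds$reads[[1]]$ground_truth))
  res <- residuals(fit)
  expect_length(res, 6)
  expect_equal(res[[2]], ds$pairs[[2]]$R - fitted(fit)[[2]])
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("identity-map scoring and network scoring agree on degenerate data", {
  # noise-free, no smoothing: target equals input, identity loss is exactly 0
  ds <- make_dataset(n_reads = 3, seq_length = 60, edge_smooth_taps = 1,
                     noise_std = 0, seed = 5)
  expect_equal(network_pair_loss(NULL, ds$pairs), 0)
})
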