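test_that("gru_step matches hand-solvable degenerate cases", {
  d <- 3
  p <- list(Wz = matrix(0, d, d + 1), Wr = matrix(0, d, d + 1),
            Wc = matrix(0, d, d + 1), bz = numeric(d), br = numeric(d))
  expect_equal(gru_step(p, numeric(d), 0), numeric(d))
  v <- c(0.4, -1.2, 2)
  # zero weights: z = 0.5, candidate = 0, so h = 0.5 * h_prev
  expect_equal(gru_step(p, v, 0), 0.5 * v)
})

test_that("gru_step matches the scalar-loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    d <- 3; m <- 2
    p <- list(Wz = matrix(rnorm(d * (d + m)), d), Wr = matrix(rnorm(d * (d + m)), d),
              Wc = matrix(rnorm(d * (d + m)), d), bz = rnorm(d), br = rnorm(d))
    h <- rnorm(d); x <- rnorm(m)
    expect_equal(gru_step(p, h, x), oracle_gru_step(p, h, x),
                 tolerance = 1e-12)
  }
})

test_that("gates stay in (0,1) and hidden states stay in [-1,1]", {
  set.seed(5)
  d <- 4
  p <- list(Wz = matrix(rnorm(d * (d + 1), sd = 3), d),
            Wr = matrix(rnorm(d * (d + 1), sd = 3), d),
            Wc = matrix(rnorm(d * (d + 1), sd = 3), d),
            bz = rnorm(d), br = rnorm(d))
  h <- runif(d, -1, 1)
  for (t in 1:50) {
    h <- gru_step(p, h, rnorm(1))
    expect_true(all(h >= -1 & h <= 1))
  }
})

test_that("bigru_layer equals forward and reversed-backward gru_step runs", {
  set.seed(12)
  d <- 3; m <- 2; Tn <- 7
  mk <- function() list(Wz = matrix(rnorm(d * (d + m)), d),
                        Wr = matrix(rnorm(d * (d + m)), d),
                        Wc = matrix(rnorm(d * (d + m)), d),
                        bz = rnorm(d), br = rnorm(d))
  fwd <- mk(); bwd <- mk()
  X <- matrix(rnorm(Tn * m), Tn, m)
  H <- bigru_layer(fwd, bwd, X)
  expect_equal(dim(H), c(Tn, 2 * d))
  expect_equal(H, oracle_bigru_layer(fwd, bwd, X), tolerance = 1e-12)
  # single-step boundary: both directions see only the one input
  H1 <- bigru_layer(fwd, bwd, X[1, , drop = FALSE])
  expect_equal(H1[1, 1:d], gru_step(fwd, numeric(d), X[1, ]))
  expect_equal(H1[1, d + 1:d], gru_step(bwd, numeric(d), X[1, ]))
})

test_that("palindromic input with shared parameters gives mirrored halves", {
  set.seed(9)
  d <- 3
  p <- list(Wz = matrix(rnorm(d * (d + 1)), d), Wr = matrix(rnorm(d * (d + 1)), d),
            Wc = matrix(rnorm(d * (d + 1)), d), bz = rnorm(d), br = rnorm(d))
  x <- c(0.3, -1, 2, -1, 0.3)  # palindrome
  H <- bigru_layer(p, p, matrix(x, ncol = 1))
  Tn <- length(x)
  for (t in 1:Tn)
    expect_equal(H[t, 1:d], H[Tn + 1 - t, d + 1:d], tolerance = 1e-12)
})

test_that("network_forward matches the composed scalar-loop oracle", {
  for (s in 1:4) {
    d <- sample(2:8, 1)
    Tn <- sample(3:32, 1)
    net <- random_net(d, seed = 100 + s)
    x <- rnorm(Tn)
    expect_equal(network_forward(net, x), oracle_network_forward(net, x),
                 tolerance = 1e-10)
  }
})

test_that("the candidate-bias variant threads its bias through the forward pass", {
  net <- random_net(3, seed = 77, candidate_bias = TRUE)
  for (l in 1:3) for (dir in c("fwd", "bwd"))
    net$layers[[l]][[dir]]$bc <- rnorm(3, sd = 0.5)
  x <- rnorm(12)
  expect_equal(network_forward(net, x), oracle_network_forward(net, x),
               tolerance = 1e-10)
})

test_that("network output length always equals input length", {
  net <- random_net(3, seed = 2)
  for (Tn in c(1, 2, 17))
    expect_length(network_forward(net, rnorm(Tn)), Tn)
})

test_that("a dead fully connected head outputs a constant", {
  net <- random_net(4, seed = 3)
  net$fc_weight <- numeric(8)
  net$fc_bias <- -2.5
  expect_equal(network_forward(net, rnorm(15)), rep(-2.5, 15))
})

test_that("forward pass is deterministic regardless of RNG state", {
  net <- random_net(4, seed = 8)
  x <- rnorm(25)
  set.seed(1); o1 <- network_forward(net, x)
  set.seed(999); o2 <- network_forward(net, x)
  expect_identical(o1, o2)
})

test_that("checkpoints round-trip the network exactly enough to reuse", {
  net <- random_net(3, seed = 21)
  f <- withr::local_tempfile(fileext = ".json")
  write_bigru(net, f)
  net2 <- read_bigru(f)
  x <- rnorm(20)
  expect_equal(network_forward(net2, x), network_forward(net, x),
               tolerance = 1e-12)
  expect_error(read_bigru(file.path(tempdir(), "nope.json")), "not found")
})

test_that("training gradients match finite differences", {
  set.seed(7)
  net <- bigru_network(hidden_size = 3, seed = 42)
  Tn <- 8; B <- 2
  I <- matrix(rnorm(Tn * B), Tn, B)
  R <- matrix(rnorm(Tn * B), Tn, B)
  M <- matrix(1, Tn, B); M[7:8, 2] <- 0
  g <- squigglesim:::cpp_network_loss_grad(
    squigglesim:::net_for_cpp(net), I, R, M, TRUE)
  loss_at <- function(n) squigglesim:::cpp_network_loss_grad(
    squigglesim:::net_for_cpp(n), I, R, M, FALSE)$loss
  eps <- 1e-6
  for (probe in list(c(2, "fwd", "Wc"), c(1, "bwd", "Wz"), c(3, "fwd", "br"))) {
    l <- as.integer(probe[1]); dir <- probe[2]; w <- probe[3]
    k <- sample(length(net$layers[[l]][[dir]][[w]]), 3)
    for (kk in k) {
      n1 <- net; n1$layers[[l]][[dir]][[w]][kk] <- n1$layers[[l]][[dir]][[w]][kk] + eps
      n2 <- net; n2$layers[[l]][[dir]][[w]][kk] <- n2$layers[[l]][[dir]][[w]][kk] - eps
      numg <- (loss_at(n1) - loss_at(n2)) / (2 * eps)
      expect_equal(g$grad$layers[[l]][[dir]][[w]][kk], numg, tolerance = 1e-5)
    }
  }
})
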