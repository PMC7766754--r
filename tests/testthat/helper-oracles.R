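# Independent scalar-loop oracles used to cross-check the vectorized /
# compiled implementations. These are deliberately written as plain
# per-element loops from the model equations, sharing no code with the
# package internals.

# one GRU step, element by element
oracle_gru_step <- function(p, h_prev, x) {
  d <- length(h_prev); m <- length(x)
  cat_v <- c(h_prev, x)
  z <- r <- hc <- h <- numeric(d)
  for (k in 1:d) {
    az <- p$bz[k]; ar <- p$br[k]
    for (j in 1:(d + m)) {
      az <- az + p$Wz[k, j] * cat_v[j]
      ar <- ar + p$Wr[k, j] * cat_v[j]
    }
    z[k] <- 1 / (1 + exp(-az))
    r[k] <- 1 / (1 + exp(-ar))
  }
  cat_c <- c(r * h_prev, x)
  for (k in 1:d) {
    ac <- if (is.null(p$bc)) 0 else p$bc[k]
    for (j in 1:(d + m)) ac <- ac + p$Wc[k, j] * cat_c[j]
    hc[k] <- tanh(ac)
    h[k] <- (1 - z[k]) * h_prev[k] + z[k] * hc[k]
  }
  h
}

# bidirectional layer from repeated oracle steps
oracle_bigru_layer <- function(fwd, bwd, X) {
  Tn <- nrow(X); d <- length(fwd$bz)
  Hf <- matrix(0, Tn, d); Hb <- matrix(0, Tn, d)
  h <- numeric(d)
  for (t in 1:Tn) { h <- oracle_gru_step(fwd, h, X[t, ]); Hf[t, ] <- h }
  h <- numeric(d)
  for (t in Tn:1) { h <- oracle_gru_step(bwd, h, X[t, ]); Hb[t, ] <- h }
  cbind(Hf, Hb)
}

# full three-layer network + head from the layer oracle
oracle_network_forward <- function(net, x) {
  A <- matrix(x, ncol = 1)
  for (l in 1:3)
    A <- oracle_bigru_layer(net$layers[[l]]$fwd, net$layers[[l]]$bwd, A)
  drop(A %*% net$fc_weight) + net$fc_bias
}

# exhaustive DTW dynamic program (no band, no traceback tricks)
oracle_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n, m)
  D[1, 1] <- abs(a[1] - b[1])
  for (i in 1:n) for (j in 1:m) {
    if (i == 1 && j == 1) next
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, D[i - 1, j - 1])
    if (i > 1) best <- min(best, D[i - 1, j])
    if (j > 1) best <- min(best, D[i, j - 1])
    D[i, j] <- abs(a[i] - b[j]) + best
  }
  D[n, m]
}

random_net <- function(d, seed, candidate_bias = FALSE) {
  bigru_network(hidden_size = d, candidate_bias = candidate_bias, seed = seed)
}
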