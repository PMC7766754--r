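#' Supervised training pairs
#'
#' A training pair couples a normalized ground-truth signal `I` (the
#' network input) with the real or target signal `R` it should be
#' mapped to, aligned sample-by-sample. Pairs come either from
#' [label_read()] applied to real raw signals or from the synthetic
#' generator [make_dataset()].
#'
#' @param I numeric input signal (normalized ground truth).
#' @param R numeric target signal, same length as `I`.
#' @param tag optional provenance string.
#' @return an object of class `"training_pair"`.
#' @export
training_pair <- function(I, R, tag = "") {
  I <- as.numeric(I); R <- as.numeric(R)
  check_numeric_vector(I, "I"); check_numeric_vector(R, "R")
  if (length(I) != length(R))
    stop_input("I and R must have the same length (", length(I), " vs ",
               length(R), ")")
  structure(list(I = I, R = R, tag = as.character(tag)),
            class = "training_pair")
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf("training pair: %d aligned samples%s\n", length(x$I),
              if (nzchar(x$tag)) paste0(" [", x$tag, "]") else ""))
  invisible(x)
}

#' Log-Cosh regression loss
#'
#' `sum(log(cosh(O - R)))`: quadratic near zero, linear in the tails
#' (asymptote `|x| - log 2`), hence robust to occasional large signal
#' excursions. Computed overflow-safely for large residuals. This is the
#' per-read sum; training minimizes its mean over valid positions.
#'
#' @param O,R numeric vectors of equal length.
#' @return the scalar loss (>= 0, zero iff `O == R`).
#' @examples
#' log_cosh_loss(1, 0)  # log(cosh(1))
#' @export
log_cosh_loss <- function(O, R) {
  O <- as.numeric(O); R <- as.numeric(R)
  if (length(O) != length(R)) stop_input("O and R must have equal lengths")
  if (!length(O)) stop_input("O and R must be non-empty")
  x <- O - R
  big <- abs(x) > 20
  out <- numeric(length(x))
  out[big] <- abs(x[big]) - log(2)
  out[!big] <- log(cosh(x[!big]))
  sum(out)
}

#' Xavier (Glorot) uniform initialization
#'
#' Draws entries i.i.d. uniform on the interval
#' `[-sqrt(6/(n_in + n_out)), +sqrt(6/(n_in + n_out))]`, keeping the
#' variance of activations stable across layers.
#'
#' @param n_in input dimension (fan-in).
#' @param n_out output dimension (fan-out).
#' @param seed optional integer seed.
#' @return an `n_out x n_in` matrix.
#' @export
xavier_init <- function(n_in, n_out, seed = NULL) {
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  if (is.na(n_in) || n_in < 1L || is.na(n_out) || n_out < 1L)
    stop_input("n_in and n_out must be >= 1")
  bound <- sqrt(6 / (n_in + n_out))
  with_seed(seed,
    matrix(runif(n_in * n_out, -bound, bound), nrow = n_out, ncol = n_in))
}

#' Slice training pairs into shuffled fixed-length windows
#'
#' Each pair is cut into non-overlapping windows of `window_length`
#' samples. A final remainder shorter than `window_length / 2` is
#' discarded; otherwise it is zero-padded and marked in the padding
#' mask (padded positions never contribute to the loss). Windows are
#' then shuffled and grouped into batches.
#'
#' @param pairs list of [training_pair()] objects.
#' @param window_length window size in samples (>= 8).
#' @param batch_size windows per batch.
#' @param seed optional integer seed for the shuffle.
#' @return an object of class `"chunk_set"`: matrices `I`, `R`, `mask`
#'   (`window_length x n_windows`), `n_windows`, and `batches`, a list
#'   of column-index vectors (one epoch).
#' @export
make_chunks <- function(pairs, window_length = 512L, batch_size = 128L,
                        seed = NULL) {
  if (inherits(pairs, "training_pair")) pairs <- list(pairs)
  if (!length(pairs)) stop_input("pairs must be non-empty")
  window_length <- as.integer(window_length)
  batch_size <- as.integer(batch_size)
  if (is.na(window_length) || window_length < 8L)
    stop_input("window_length must be >= 8")
  if (is.na(batch_size) || batch_size < 1L)
    stop_input("batch_size must be >= 1")
  Is <- list(); Rs <- list(); Ms <- list()
  for (p in pairs) {
    stopifnot(inherits(p, "training_pair"))
    n <- length(p$I)
    n_full <- n %/% window_length
    for (w in seq_len(n_full)) {
      idx <- ((w - 1L) * window_length + 1L):(w * window_length)
      Is[[length(Is) + 1L]] <- p$I[idx]
      Rs[[length(Rs) + 1L]] <- p$R[idx]
      Ms[[length(Ms) + 1L]] <- rep(1, window_length)
    }
    rem <- n - n_full * window_length
    if (rem >= window_length / 2) {
      idx <- (n_full * window_length + 1L):n
      pad <- window_length - rem
      Is[[length(Is) + 1L]] <- c(p$I[idx], rep(0, pad))
      Rs[[length(Rs) + 1L]] <- c(p$R[idx], rep(0, pad))
      Ms[[length(Ms) + 1L]] <- c(rep(1, rem), rep(0, pad))
    }
  }
  if (!length(Is))
    stop_input("no usable windows: every pair is shorter than window_length/2")
  nw <- length(Is)
  order <- with_seed(seed, sample.int(nw))
  batches <- split(order, ceiling(seq_along(order) / batch_size))
  structure(list(I = matrix(unlist(Is), ncol = nw),
                 R = matrix(unlist(Rs), ncol = nw),
                 mask = matrix(unlist(Ms), ncol = nw),
                 n_windows = nw,
                 batches = unname(batches)),
            class = "chunk_set")
}

#' @export
print.chunk_set <- function(x, ...) {
  cat(sprintf("chunk set: %d windows of %d samples in %d batches\n",
              x$n_windows, nrow(x$I), length(x$batches)))
  invisible(x)
}

#' Mean per-position log-cosh loss of a network over pairs
#'
#' Runs the network forward on each pair's input and averages the
#' log-cosh loss over all positions, weighting pairs by length. Used
#' for held-out evaluation; `net = NULL` scores the identity map
#' (`O = I`), the copy baseline a useful network must beat.
#'
#' @param net a `"bigru_net"`, a `"bigru_fit"`, or `NULL` for the
#'   identity map.
#' @param pairs list of [training_pair()] objects.
#' @return mean log-cosh loss per position.
#' @export
network_pair_loss <- function(net, pairs) {
  if (inherits(pairs, "training_pair")) pairs <- list(pairs)
  if (inherits(net, "bigru_fit")) net <- net$net
  total <- 0; npos <- 0
  for (p in pairs) {
    O <- if (is.null(net)) p$I else network_forward(net, p$I)
    total <- total + log_cosh_loss(O, p$R)
    npos <- npos + length(p$I)
  }
  total / npos
}

#' Fit the BiGRU signal-processing network
#'
#' Trains the three-layer bidirectional GRU + fully connected head to
#' map normalized ground-truth signals onto their real (or synthetic
#' target) counterparts, minimizing the mean per-position log-cosh loss
#' with the Adam optimizer. Weights are Xavier-initialized, biases start
#' at zero, and the whole run is reproducible given `seed`.
#'
#' An "iteration" is one Adam step on one mini-batch of shuffled
#' windows; windows are rebuilt from the pairs by [make_chunks()] and
#' the shuffled order is cycled for as many epochs as `iterations`
#' requires.
#'
#' @param pairs list of [training_pair()] objects (see [label_read()]
#'   and [make_dataset()]).
#' @param hidden_size hidden units per GRU direction (default 64).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size windows per Adam step (default 128).
#' @param iterations number of Adam steps (default 1000).
#' @param window_length training window size in samples (default 512).
#' @param candidate_bias add a bias to the GRU candidate state
#'   (framework-standard variant; default `FALSE`).
#' @param seed integer seed controlling initialization and batching.
#' @return an object of class `"bigru_fit"` with components `net` (the
#'   trained `"bigru_net"`), `loss` (per-step training loss), `config`,
#'   and the training `pairs`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' ds <- make_dataset(n_reads = 8, seq_length = 80, seed = 1)
#' fit <- bigru_fit(ds$pairs, hidden_size = 4, iterations = 20,
#'                  window_length = 64, batch_size = 8, seed = 1)
#' fit
#' }
#' @export
bigru_fit <- function(pairs, hidden_size = 64L, learning_rate = 1e-4,
                      batch_size = 128L, iterations = 1000L,
                      window_length = 512L, candidate_bias = FALSE,
                      seed = 1L) {
  if (inherits(pairs, "training_pair")) pairs <- list(pairs)
  if (!length(pairs)) stop_input("pairs must be non-empty")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop_input("iterations must be >= 0")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_input("learning_rate must be positive")
  config <- list(hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = iterations,
                 window_length = as.integer(window_length),
                 candidate_bias = candidate_bias, seed = as.integer(seed))
  res <- with_seed(seed, {
    net <- bigru_network(hidden_size, candidate_bias)
    chunks <- make_chunks(pairs, window_length, batch_size)
    if (iterations == 0L) {
      list(net = net, loss = numeric(0))
    } else {
      # cycle shuffled epochs until `iterations` batches are scheduled
      schedule <- chunks$batches
      while (length(schedule) < iterations) {
        order <- sample.int(chunks$n_windows)
        schedule <- c(schedule,
                      unname(split(order, ceiling(seq_along(order) /
                                                  config$batch_size))))
      }
      schedule <- schedule[seq_len(iterations)]
      out <- cpp_train_bigru(net_for_cpp(net), chunks$I, chunks$R,
                             chunks$mask, schedule, learning_rate,
                             0.9, 0.999, 1e-8)
      list(net = net_from_cpp(out$net), loss = as.numeric(out$loss))
    }
  })
  structure(list(net = res$net, loss = res$loss, config = config,
                 pairs = pairs, call = match.call()),
            class = "bigru_fit")
}

#' @export
print.bigru_fit <- function(x, ...) {
  cat("BiGRU signal-processing fit\n")
  cat(sprintf("  %d training pairs, %d Adam steps, hidden size %d\n",
              length(x$pairs), length(x$loss), x$config$hidden_size))
  if (length(x$loss))
    cat(sprintf("  training loss: %.4f (first) -> %.4f (last)\n",
                x$loss[1L], x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
summary.bigru_fit <- function(object, ...) {
  n10 <- min(10L, length(object$loss))
  s <- list(config = object$config,
            n_pairs = length(object$pairs),
            n_parameters = length(unlist(coef_list(object$net))),
            loss_initial = if (n10) mean(head(object$loss, n10)) else NA_real_,
            loss_final = if (n10) mean(tail(object$loss, n10)) else NA_real_)
  class(s) <- "summary.bigru_fit"
  s
}

#' @export
print.summary.bigru_fit <- function(x, ...) {
  cfg <- x$config
  cat("BiGRU signal-processing fit\n")
  cat(sprintf("  pairs: %d   parameters: %d\n", x$n_pairs, x$n_parameters))
  cat(sprintf("  hidden %d/direction, window %d, batch %d, lr %g, %d steps, seed %d\n",
              cfg$hidden_size, cfg$window_length, cfg$batch_size,
              cfg$learning_rate, cfg$iterations, cfg$seed))
  cat(sprintf("  mean loss, first 10 steps: %.4f; last 10 steps: %.4f\n",
              x$loss_initial, x$loss_final))
  invisible(x)
}

#' @export
coef.bigru_fit <- function(object, ...) coef_list(object$net)

#' @param object a `"bigru_fit"`.
#' @param signal numeric signal to filter. By default it is z-score
#'   normalized before the network and the output is mapped back to the
#'   input's pA scale; `normalized = TRUE` skips both steps.
#' @param normalized treat `signal` as already normalized.
#' @rdname bigru_fit
#' @export
predict.bigru_fit <- function(object, signal, normalized = FALSE, ...) {
  if (normalized) return(network_forward(object$net, signal))
  z <- zscore_normalize(signal)
  zscore_denormalize(network_forward(object$net, z$values), z$stats)
}

#' @export
fitted.bigru_fit <- function(object, ...) {
  lapply(object$pairs, function(p) network_forward(object$net, p$I))
}

#' @export
residuals.bigru_fit <- function(object, ...) {
  lapply(object$pairs, function(p) p$R - network_forward(object$net, p$I))
}

#' @param x a `"bigru_fit"`.
#' @rdname bigru_fit
#' @export
plot.bigru_fit <- function(x, ...) {
  if (!length(x$loss)) stop_input("no loss history to plot (0 iterations)")
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "training iteration step", ylab = "log-cosh loss",
                 main = "BiGRU training loss", ...)
  invisible(x)
}

#' @param nsim number of squiggles to simulate.
#' @param sequence,pore_model passed to [simulate_squiggle()]; `sequence`
#'   may be a vector, recycled across `nsim`.
#' @param ... further arguments to [simulate_squiggle()].
#' @rdname bigru_fit
#' @export
simulate.bigru_fit <- function(object, nsim = 1, seed = NULL, sequence,
                               pore_model, ...) {
  with_seed(seed, {
    seqs <- rep_len(sequence, nsim)
    lapply(seqs, function(s)
      simulate_squiggle(s, pore_model, filter = "bigru", fit = object, ...))
  })
}
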