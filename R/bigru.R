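#' Gated recurrent unit primitives
#'
#' The GRU cell used by the signal-processing network. With hidden state
#' `h` and input `x` (concatenation order `[hidden, input]`):
#' \deqn{z = \sigma(W_z [h, x] + b_z)}
#' \deqn{r = \sigma(W_r [h, x] + b_r)}
#' \deqn{h' = \tanh(W [r \circ h, x])}
#' \deqn{h_{new} = (1 - z) \circ h + z \circ h'}
#' Note the update-gate convention: here `z` weights the candidate
#' state. The candidate path has no bias term by default; setting
#' `candidate_bias = TRUE` when building a network adds one (the
#' framework-standard variant).
#'
#' @param params a list with matrices `Wz`, `Wr`, `Wc` of shape
#'   `d x (d + m)`, bias vectors `bz`, `br` of length `d`, and optionally
#'   `bc` (used only when present and non-NULL).
#' @param h_prev hidden state vector of length `d`.
#' @param input input vector of length `m`.
#' @return `gru_step()` returns the new hidden state (length `d`).
#' @examples
#' p <- list(Wz = matrix(0, 2, 3), Wr = matrix(0, 2, 3),
#'           Wc = matrix(0, 2, 3), bz = c(0, 0), br = c(0, 0))
#' gru_step(p, h_prev = c(1, -1), input = 0)  # 0.5 * h_prev
#' @export
gru_step <- function(params, h_prev, input) {
  h_prev <- as.numeric(h_prev); input <- as.numeric(input)
  d <- length(h_prev); m <- length(input)
  for (nm in c("Wz", "Wr", "Wc"))
    if (!all(dim(params[[nm]]) == c(d, d + m)))
      stop_input(nm, " must be a ", d, " x ", d + m, " matrix")
  if (length(params$bz) != d || length(params$br) != d)
    stop_input("bz and br must have length ", d)
  concat <- c(h_prev, input)
  z <- plogis(drop(params$Wz %*% concat) + params$bz)
  r <- plogis(drop(params$Wr %*% concat) + params$br)
  pre <- drop(params$Wc %*% c(r * h_prev, input))
  if (!is.null(params$bc)) pre <- pre + params$bc
  hc <- tanh(pre)
  (1 - z) * h_prev + z * hc
}

#' @rdname gru_step
#' @param fwd,bwd GRU parameter lists for the forward (left-to-right) and
#'   backward (right-to-left) passes; both start from a zero hidden state.
#' @param inputs a `T x m` matrix of per-time-step inputs (a numeric
#'   vector is treated as `T x 1`).
#' @return `bigru_layer()` returns a `T x 2d` matrix: at each time step
#'   the forward hidden state concatenated with the backward one.
#' @export
bigru_layer <- function(fwd, bwd, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(as.numeric(inputs), ncol = 1L)
  T_len <- nrow(inputs)
  if (T_len < 1L) stop_input("inputs must contain at least one time step")
  d <- length(fwd$bz)
  Hf <- matrix(0, T_len, d); Hb <- matrix(0, T_len, d)
  h <- numeric(d)
  for (t in seq_len(T_len)) {
    h <- gru_step(fwd, h, inputs[t, ])
    Hf[t, ] <- h
  }
  h <- numeric(d)
  for (t in rev(seq_len(T_len))) {
    h <- gru_step(bwd, h, inputs[t, ])
    Hb[t, ] <- h
  }
  cbind(Hf, Hb)
}

new_gru_params <- function(d, m, candidate_bias, init = c("xavier", "zero")) {
  init <- match.arg(init)
  mk <- function() {
    if (init == "zero") matrix(0, d, d + m) else xavier_init(d + m, d)
  }
  p <- list(Wz = mk(), Wr = mk(), Wc = mk(),
            bz = numeric(d), br = numeric(d))
  if (candidate_bias) p$bc <- numeric(d)
  p
}

#' Construct the three-layer BiGRU signal-processing network
#'
#' Builds the untrained network: three stacked bidirectional GRU layers
#' (layer 1 reads the scalar signal, layers 2-3 read the `2d`-wide
#' concatenated states) followed by a per-time-step fully connected head
#' producing one output value per input sample. Weight matrices are
#' Xavier-initialized (uniform within the +/- sqrt(6/(n_in + n_out))
#' bound); biases start at zero.
#'
#' @param hidden_size hidden units per direction (default 64).
#' @param candidate_bias if `TRUE`, the candidate state gets a bias term
#'   (framework-standard GRU); the default `FALSE` follows the bias-free
#'   candidate of the model equations.
#' @param seed optional integer seed for the initialization draws.
#' @param init `"xavier"` (default) or `"zero"` (mainly for tests).
#' @return an object of class `"bigru_net"`.
#' @examples
#' net <- bigru_network(hidden_size = 4, seed = 1)
#' network_forward(net, rnorm(20))
#' @export
bigru_network <- function(hidden_size = 64L, candidate_bias = FALSE,
                          seed = NULL, init = "xavier") {
  d <- as.integer(hidden_size)
  if (is.na(d) || d < 1L) stop_input("hidden_size must be >= 1")
  with_seed(seed, {
    layers <- lapply(1:3, function(l) {
      m <- if (l == 1L) 1L else 2L * d
      list(fwd = new_gru_params(d, m, candidate_bias, init),
           bwd = new_gru_params(d, m, candidate_bias, init))
    })
    fc_weight <- if (init == "zero") numeric(2L * d) else
      drop(xavier_init(2L * d, 1L))
    structure(list(hidden_size = d, candidate_bias = candidate_bias,
                   layers = layers, fc_weight = fc_weight, fc_bias = 0),
              class = "bigru_net")
  })
}

#' @export
print.bigru_net <- function(x, ...) {
  cat(sprintf(paste0("BiGRU signal-processing network: 3 bidirectional layers, ",
                     "%d hidden units/direction, %s candidate bias\n"),
              x$hidden_size, if (x$candidate_bias) "with" else "no"))
  cat(sprintf("  %d parameters\n", length(unlist(coef_list(x)))))
  invisible(x)
}

coef_list <- function(net) {
  c(unlist(lapply(seq_along(net$layers), function(l) {
    lay <- net$layers[[l]]
    stats::setNames(c(lay["fwd"], lay["bwd"]),
                    paste0("layer", l, c(".fwd", ".bwd")))
  }), recursive = FALSE),
  list(fc_weight = net$fc_weight, fc_bias = net$fc_bias))
}

# flatten the 1-column matrices C++ hands back into plain vectors
net_from_cpp <- function(net) {
  net$hidden_size <- as.integer(net$hidden_size)
  for (l in seq_along(net$layers))
    for (dir in c("fwd", "bwd"))
      for (nm in intersect(c("bz", "br", "bc"), names(net$layers[[l]][[dir]])))
        net$layers[[l]][[dir]][[nm]] <- as.numeric(net$layers[[l]][[dir]][[nm]])
  net$fc_weight <- as.numeric(net$fc_weight)
  net$fc_bias <- as.numeric(net$fc_bias)
  structure(net, class = "bigru_net")
}

# ensure bc is present when the flag says so (C++ expects it)
net_for_cpp <- function(net) {
  if (!net$candidate_bias) return(net)
  for (l in seq_along(net$layers))
    for (dir in c("fwd", "bwd"))
      if (is.null(net$layers[[l]][[dir]]$bc))
        net$layers[[l]][[dir]]$bc <- numeric(net$hidden_size)
  net
}

#' @rdname bigru_network
#' @param net a `"bigru_net"`.
#' @param signal numeric input signal (normalized ground truth).
#' @return `network_forward()` returns the filtered output signal, same
#'   length as the input.
#' @export
network_forward <- function(net, signal) {
  stopifnot(inherits(net, "bigru_net"))
  signal <- as.numeric(signal)
  check_numeric_vector(signal, "signal")
  as.numeric(cpp_network_forward(net_for_cpp(net), signal))
}

#' Save or load a network checkpoint
#'
#' Checkpoints are versioned JSON files holding every weight matrix, the
#' hidden size and the candidate-bias flag, so a trained model can be
#' reused across sessions (and inspected as plain text).
#'
#' @param net a `"bigru_net"` (a `"bigru_fit"` is accepted and its
#'   network extracted).
#' @param path file path for the checkpoint.
#' @return `read_bigru()` returns the restored `"bigru_net"`.
#' @export
write_bigru <- function(net, path) {
  if (inherits(net, "bigru_fit")) net <- net$net
  stopifnot(inherits(net, "bigru_net"))
  payload <- list(format = "squigglesim-bigru", version = 1L,
                  hidden_size = net$hidden_size,
                  candidate_bias = net$candidate_bias,
                  layers = net$layers, fc_weight = net$fc_weight,
                  fc_bias = net$fc_bias)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bigru
#' @export
read_bigru <- function(path) {
  if (!file.exists(path)) stop_input("checkpoint not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "squigglesim-bigru"))
    stop_input("not a squigglesim BiGRU checkpoint: ", path)
  if (p$version != 1L) stop_input("unsupported checkpoint version ", p$version)
  d <- as.integer(p$hidden_size)
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    # nested JSON arrays parse row-wise
    matrix(unlist(x), nrow = length(x), byrow = TRUE)
  }
  layers <- lapply(p$layers, function(lay) {
    lapply(lay[c("fwd", "bwd")], function(dir) {
      out <- list(Wz = as_mat(dir$Wz), Wr = as_mat(dir$Wr),
                  Wc = as_mat(dir$Wc),
                  bz = as.numeric(unlist(dir$bz)),
                  br = as.numeric(unlist(dir$br)))
      if (!is.null(dir$bc)) out$bc <- as.numeric(unlist(dir$bc))
      out
    })
  })
  structure(list(hidden_size = d,
                 candidate_bias = isTRUE(p$candidate_bias),
                 layers = layers,
                 fc_weight = as.numeric(unlist(p$fc_weight)),
                 fc_bias = as.numeric(p$fc_bias)),
            class = "bigru_net")
}
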