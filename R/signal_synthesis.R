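#' Repeat-time (dwell) model for expanding expected levels
#'
#' With MinION chemistry DNA translocates at ~450 bases/s while current
#' is sampled at 4 kHz, so each 6-mer is measured on average 8-9 times;
#' the actual repeat count fluctuates with the motor protein speed and
#' empirically follows a mixture of alpha distributions. An alpha
#' variate with shape `a`, location and scale is `location +
#' scale / (a - Z)` where `Z` is a standard normal truncated to
#' `Z < a`; draws are rounded to the nearest integer (ties to even) and
#' clamped to `[min_repeat, max_repeat]`.
#'
#' The default two-component mixture was calibrated once so that the
#' clamped, rounded draw has mean ~8.7 samples per 6-mer, matching the
#' 450 bp/s / 4 kHz dwell regime.
#'
#' @param components list of components, each a list with `weight`,
#'   `a` (shape, > 0), `location`, `scale` (> 0); weights must sum to 1.
#' @param min_repeat,max_repeat integer clamp bounds on the repeat count.
#' @return an object of class `"repeat_model"`.
#' @examples
#' counts <- sample_repeat_counts(1000, repeat_model(), seed = 1)
#' mean(counts)
#' @export
repeat_model <- function(components = list(
                           list(weight = 0.7, a = 4, location = 1, scale = 28),
                           list(weight = 0.3, a = 3, location = 2, scale = 18)),
                         min_repeat = 1L, max_repeat = 40L) {
  if (!length(components)) stop_input("repeat model needs at least one component")
  for (cm in components) {
    if (!all(c("weight", "a", "location", "scale") %in% names(cm)))
      stop_input("each component needs weight, a, location and scale")
    if (cm$weight <= 0 || cm$weight > 1) stop_input("component weights must be in (0, 1]")
    if (cm$a <= 0) stop_input("alpha shape 'a' must be positive")
    if (cm$scale < 0) stop_input("component scale must be non-negative")
  }
  w <- vapply(components, `[[`, numeric(1L), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop_input("component weights must sum to 1 (got ", format(sum(w)), ")")
  min_repeat <- as.integer(min_repeat); max_repeat <- as.integer(max_repeat)
  if (min_repeat < 1L) stop_input("min_repeat must be >= 1")
  if (min_repeat > max_repeat) stop_input("min_repeat must be <= max_repeat")
  structure(list(components = components, min_repeat = min_repeat,
                 max_repeat = max_repeat),
            class = "repeat_model")
}

#' @export
print.repeat_model <- function(x, ...) {
  cat(sprintf("mixture-alpha repeat model: %d component(s), clamp [%d, %d]\n",
              length(x$components), x$min_repeat, x$max_repeat))
  for (cm in x$components)
    cat(sprintf("  weight %.2f  a %.3g  location %.3g  scale %.3g\n",
                cm$weight, cm$a, cm$location, cm$scale))
  invisible(x)
}

#' @rdname repeat_model
#' @param n_positions number of counts to draw (one per expected-signal
#'   position).
#' @param model a `"repeat_model"`.
#' @param seed optional integer seed for reproducible draws.
#' @return `sample_repeat_counts()` returns an integer vector of length
#'   `n_positions`, each in `[min_repeat, max_repeat]`.
#' @export
sample_repeat_counts <- function(n_positions, model = repeat_model(),
                                 seed = NULL) {
  stopifnot(inherits(model, "repeat_model"))
  n_positions <- as.integer(n_positions)
  if (is.na(n_positions) || n_positions < 1L)
    stop_input("n_positions must be >= 1")
  with_seed(seed, {
    w <- vapply(model$components, `[[`, numeric(1L), "weight")
    ci <- sample.int(length(w), n_positions, replace = TRUE, prob = w)
    a <- vapply(model$components, `[[`, numeric(1L), "a")[ci]
    loc <- vapply(model$components, `[[`, numeric(1L), "location")[ci]
    sc <- vapply(model$components, `[[`, numeric(1L), "scale")[ci]
    # inverse-CDF draw of the alpha distribution: 1/(a - Z), Z ~ N(0,1) | Z < a
    z <- qnorm(runif(n_positions) * pnorm(a))
    x <- loc + sc / (a - z)
    as.integer(pmin(pmax(round(x), model$min_repeat), model$max_repeat))
  })
}

#' Assemble the square-wave ground-truth signal
#'
#' Repeats each expected level `repeats[i]` times in order, producing the
#' idealized piecewise-constant "ground-truth" signal whose length
#' distribution matches real raw reads.
#'
#' @param expected an [expected_signal()] (or plain numeric vector of
#'   levels, pA).
#' @param repeats integer vector of per-position repeat counts, same
#'   length as `expected`, all >= 1.
#' @return an object of class `"ground_truth"`: the numeric signal with
#'   attributes `repeats` and `expected`.
#' @examples
#' assemble_ground_truth(c(80, 95), c(2, 3))
#' @export
assemble_ground_truth <- function(expected, repeats) {
  ev <- as.numeric(expected)
  check_numeric_vector(ev, "expected")
  repeats <- as.integer(repeats)
  if (length(repeats) != length(ev))
    stop_input("length(repeats) must equal length(expected)")
  if (any(is.na(repeats)) || any(repeats < 1L))
    stop_input("all repeat counts must be integers >= 1")
  structure(rep(ev, times = repeats), repeats = repeats, expected = ev,
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground-truth signal: %d samples over %d 6-mer positions (mean dwell %.2f)\n",
              length(x), length(attr(x, "repeats")), mean(attr(x, "repeats"))))
  invisible(x)
}

#' Additive white Gaussian measurement noise
#'
#' Adds i.i.d. zero-mean Gaussian noise to every sample, emulating the
#' low signal-to-noise sequencing environment. The default standard
#' deviation of 2.0 pA matches the common simulation setting; the noise
#' is uncorrelated in time.
#'
#' @param signal numeric signal (pA).
#' @param std noise standard deviation, >= 0.
#' @param seed optional integer seed.
#' @return numeric vector of the same length.
#' @export
add_gaussian_noise <- function(signal, std = 2.0, seed = NULL) {
  signal <- as.numeric(signal)
  check_numeric_vector(signal, "signal")
  if (!is.numeric(std) || length(std) != 1L || is.na(std) || std < 0)
    stop_input("std must be a single number >= 0")
  if (std == 0) return(signal)
  with_seed(seed, signal + rnorm(length(signal), mean = 0, sd = std))
}

#' Per-read z-score normalization
#'
#' Centers by the sample mean and scales by the sample standard
#' deviation — the dominant nanopore convention for making reads
#' comparable across pores and channels. The returned stats invert the
#' transform exactly.
#'
#' @param signal numeric vector, length >= 2, not constant.
#' @return a list with `values` (the normalized signal) and `stats`
#'   (list with `center` and `spread`).
#' @examples
#' z <- zscore_normalize(c(1, 3))
#' zscore_denormalize(z$values, z$stats)
#' @export
zscore_normalize <- function(signal) {
  signal <- as.numeric(signal)
  check_numeric_vector(signal, "signal")
  if (length(signal) < 2L) stop_input("signal must have length >= 2")
  center <- mean(signal)
  spread <- sd(signal)
  if (!is.finite(spread) || spread == 0)
    stop_input("constant signal cannot be z-score normalized (zero spread)")
  list(values = (signal - center) / spread,
       stats = list(center = center, spread = spread))
}

#' @rdname zscore_normalize
#' @param values normalized values.
#' @param stats the `stats` element returned by `zscore_normalize()`.
#' @export
zscore_denormalize <- function(values, stats) {
  stopifnot(is.list(stats), all(c("center", "spread") %in% names(stats)))
  as.numeric(values) * stats$spread + stats$center
}
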