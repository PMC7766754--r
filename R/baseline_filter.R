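#' Windowed-sinc low-pass baseline filter
#'
#' The classical post-processing baseline: the square-wave ground-truth
#' signal is convolved with a Blackman-windowed sinc kernel to remove
#' the high-frequency components a real pore never produces. The default
#' cutoff of 950 Hz (at 4 kHz sampling) is the setting that makes the
#' low-pass simulation most similar to real signals; the trainable BiGRU
#' network ([bigru_fit()]) replaces this filter.
#'
#' @param cutoff_hz cutoff frequency in Hz, must be below Nyquist.
#' @param sample_rate_hz sampling rate in Hz (default 4000).
#' @param kernel_length odd number of FIR taps (default 129).
#' @return `filter_spec()` returns an object of class `"filter_spec"`.
#' @examples
#' k <- design_lowpass_kernel(filter_spec())
#' sum(k)  # unit DC gain
#' @export
filter_spec <- function(cutoff_hz = 950, sample_rate_hz = 4000,
                        kernel_length = 129L) {
  kernel_length <- as.integer(kernel_length)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0)
    stop_input("cutoff_hz must be positive")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop_input("sample_rate_hz must be positive")
  if (cutoff_hz >= sample_rate_hz / 2)
    stop_input("cutoff_hz must be below the Nyquist frequency ",
               sample_rate_hz / 2, " Hz")
  if (is.na(kernel_length) || kernel_length < 3L || kernel_length %% 2L == 0L)
    stop_input("kernel_length must be an odd integer >= 3")
  structure(list(cutoff_hz = cutoff_hz, sample_rate_hz = sample_rate_hz,
                 kernel_length = kernel_length),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("windowed-sinc low-pass: cutoff %g Hz @ %g Hz sampling, %d taps\n",
              x$cutoff_hz, x$sample_rate_hz, x$kernel_length))
  invisible(x)
}

#' @rdname filter_spec
#' @param spec a `"filter_spec"`.
#' @return `design_lowpass_kernel()` returns the numeric FIR kernel
#'   (symmetric, unit sum).
#' @export
design_lowpass_kernel <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- spec$kernel_length
  # fir1 takes the order (taps - 1) and the cutoff on [0, 1] of Nyquist
  w <- spec$cutoff_hz / (spec$sample_rate_hz / 2)
  k <- signal::fir1(n - 1L, w, type = "low", window = signal::blackman(n))
  as.numeric(k) / sum(k)
}

#' @rdname filter_spec
#' @param x numeric signal to filter.
#' @return `lowpass_filter()` returns the filtered signal, same length as
#'   the input (edges handled by replication padding).
#' @export
lowpass_filter <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- as.numeric(x)
  check_numeric_vector(x, "x")
  k <- design_lowpass_kernel(spec)
  half <- (spec$kernel_length - 1L) %/% 2L
  padded <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  out <- stats::convolve(padded, rev(k), type = "open")
  # "open" convolution has length n + 2*half + L - 1; keep the aligned core
  out[(2L * half + 1L):(2L * half + length(x))]
}

#' Magnitude frequency response of an FIR kernel
#'
#' Evaluates |H(f)| of a kernel on a frequency grid, used to verify the
#' designed cutoff (a windowed-sinc kernel has gain 1/2 at its cutoff).
#'
#' @param kernel numeric FIR kernel.
#' @param freqs_hz frequencies at which to evaluate, in Hz.
#' @param sample_rate_hz sampling rate in Hz.
#' @return numeric vector of magnitudes, one per frequency.
#' @export
kernel_response <- function(kernel, freqs_hz, sample_rate_hz = 4000) {
  kernel <- as.numeric(kernel)
  n <- seq_along(kernel) - 1L
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f / sample_rate_hz
    Mod(sum(kernel * exp(-1i * w * n)))
  }, numeric(1L))
}

#' @rdname kernel_response
#' @param spec a `"filter_spec"`; the gain-0.5 crossing of its kernel is
#'   located by bisection on a dense grid.
#' @return `half_gain_frequency()` returns the frequency (Hz) where the
#'   magnitude response crosses 0.5.
#' @export
half_gain_frequency <- function(spec = filter_spec()) {
  k <- design_lowpass_kernel(spec)
  grid <- seq(1, spec$sample_rate_hz / 2 - 1, by = 1)
  resp <- kernel_response(k, grid, spec$sample_rate_hz)
  below <- which(resp < 0.5)
  if (!length(below)) stop_input("response never falls below 0.5")
  i <- below[1L]
  if (i == 1L) return(grid[1L])
  # linear interpolation between the bracketing grid points
  f0 <- grid[i - 1L]; f1 <- grid[i]
  r0 <- resp[i - 1L]; r1 <- resp[i]
  f0 + (0.5 - r0) * (f1 - f0) / (r1 - r0)
}
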