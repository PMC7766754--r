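#' Simulate a nanopore raw current signal from a sequence
#'
#' The full simulation pipeline: the sequence is converted to its
#' expected 6-mer levels, each level is repeated for a dwell time drawn
#' from the mixture-alpha repeat model (giving the square-wave
#' ground-truth signal), the ground truth is post-processed either by
#' the trained BiGRU network or by the classical 950 Hz windowed-sinc
#' low-pass filter, and i.i.d. Gaussian noise (default sd 2 pA) is
#' added.
#'
#' With `filter = "bigru"` the ground truth is z-score normalized, run
#' through the network, and mapped back to pA with the ground truth's
#' own statistics before noise is added.
#'
#' @param sequence nucleotide string over A/C/G/T, length >= 6.
#' @param pore_model a [pore_model()]; defaults to the synthetic model.
#' @param filter `"bigru"`, `"lowpass"`, or `"none"`.
#' @param fit a [bigru_fit()] or `"bigru_net"` (required for
#'   `filter = "bigru"`).
#' @param repeat_model_ dwell model (default [repeat_model()]).
#' @param noise_std Gaussian noise standard deviation in pA.
#' @param cutoff_hz,sample_rate_hz,kernel_length low-pass filter
#'   parameters (used when `filter = "lowpass"`).
#' @param seed optional integer seed making the whole read reproducible.
#' @return an object of class `"squiggle"`: the simulated signal (pA)
#'   with components `signal`, `ground_truth`, `filtered`, `repeats`,
#'   `expected`, `sequence`, and the parameters used.
#' @examples
#' pm <- synthetic_pore_model(seed = 1)
#' sq <- simulate_squiggle(random_sequence(50, seed = 2), pm,
#'                         filter = "lowpass", seed = 3)
#' sq
#' @export
simulate_squiggle <- function(sequence, pore_model = synthetic_pore_model(),
                              filter = c("lowpass", "bigru", "none"),
                              fit = NULL, repeat_model_ = repeat_model(),
                              noise_std = 2.0, cutoff_hz = 950,
                              sample_rate_hz = 4000, kernel_length = 129L,
                              seed = NULL) {
  filter <- match.arg(filter)
  if (filter == "bigru") {
    if (inherits(fit, "bigru_fit")) fit <- fit$net
    if (!inherits(fit, "bigru_net"))
      stop_input("filter = \"bigru\" needs a bigru_fit or bigru_net in `fit`")
  }
  with_seed(seed, {
    ev <- expected_signal(sequence, pore_model)
    reps <- sample_repeat_counts(length(ev), repeat_model_)
    gt <- assemble_ground_truth(ev, reps)
    filtered <- switch(filter,
      none = as.numeric(gt),
      lowpass = lowpass_filter(as.numeric(gt),
                               filter_spec(cutoff_hz, sample_rate_hz,
                                           kernel_length)),
      bigru = {
        z <- zscore_normalize(as.numeric(gt))
        zscore_denormalize(network_forward(fit, z$values), z$stats)
      })
    signal <- add_gaussian_noise(filtered, noise_std)
    structure(list(signal = signal, filtered = filtered,
                   ground_truth = as.numeric(gt), repeats = reps,
                   expected = as.numeric(ev), sequence = sequence,
                   filter = filter, noise_std = noise_std,
                   sample_rate_hz = sample_rate_hz, seed = seed),
              class = "squiggle")
  })
}

#' @export
print.squiggle <- function(x, ...) {
  cat(sprintf(paste0("simulated squiggle: %d samples from %d bases ",
                     "(%s filter, noise sd %g pA)\n"),
              length(x$signal), nchar(x$sequence), x$filter, x$noise_std))
  cat(sprintf("  current range %.1f-%.1f pA, mean dwell %.2f samples/6-mer\n",
              min(x$signal), max(x$signal), mean(x$repeats)))
  invisible(x)
}

#' @export
plot.squiggle <- function(x, ...) {
  graphics::plot(seq_along(x$signal) / x$sample_rate_hz * 1000, x$signal,
                 type = "l", col = "grey50", xlab = "time (ms)",
                 ylab = "current (pA)", main = "simulated squiggle", ...)
  graphics::lines(seq_along(x$ground_truth) / x$sample_rate_hz * 1000,
                  x$ground_truth, col = "red")
  graphics::legend("topright", legend = c("simulated", "ground truth"),
                   col = c("grey50", "red"), lty = 1, bty = "n")
  invisible(x)
}
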