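#' Synthetic pore model, sequences and real-like target signals
#'
#' Everything needed to exercise the simulation and training pipeline
#' without external data: a reproducible stand-in pore model over all
#' 4096 6-mers, uniform random sequences, and "real-like" target
#' signals built from a known ground truth. The synthetic pore model is
#' labelled synthetic throughout: its levels are pseudo-random, not
#' measured pore currents.
#'
#' @param seed integer seed; the same seed always yields the same model.
#' @return `synthetic_pore_model()` returns a complete [pore_model()]
#'   with levels uniform in \[60, 120\] pA.
#' @examples
#' pm <- synthetic_pore_model(seed = 1)
#' length(pm)  # 4096
#' @export
synthetic_pore_model <- function(seed = 1L) {
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), 6L),
                                       stringsAsFactors = FALSE)[, 6:1])
  kmers <- sort(kmers)
  with_seed(seed, pore_model(setNames(runif(4096L, 60, 120), kmers)))
}

#' @rdname synthetic_pore_model
#' @param length sequence length in bases (>= 6).
#' @return `random_sequence()` returns a nucleotide string with i.i.d.
#'   uniform bases.
#' @export
random_sequence <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 6L) stop_input("length must be >= 6")
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Synthesize a real-like target signal from a ground truth
#'
#' Emulates the key qualitative feature of real raw signals relative to
#' the square-wave ground truth: the pore only rounds the signal at
#' 6-mer transitions while within-level samples stay flat. The square
#' wave is convolved with a short triangular kernel (unit sum, so
#' constant stretches are untouched) and Gaussian noise is added.
#'
#' @param ground_truth a [assemble_ground_truth()] result or numeric
#'   signal.
#' @param edge_smooth_taps odd kernel width >= 1; 1 means no smoothing.
#' @param noise_std Gaussian noise standard deviation (same units as the
#'   signal).
#' @param seed optional integer seed.
#' @return numeric signal of the same length.
#' @export
synthesize_real_like <- function(ground_truth, edge_smooth_taps = 5L,
                                 noise_std = 0.15, seed = NULL) {
  x <- as.numeric(ground_truth)
  check_numeric_vector(x, "ground_truth")
  taps <- as.integer(edge_smooth_taps)
  if (is.na(taps) || taps < 1L || taps %% 2L == 0L)
    stop_input("edge_smooth_taps must be an odd integer >= 1")
  if (!is.numeric(noise_std) || noise_std < 0)
    stop_input("noise_std must be >= 0")
  if (taps > 1L) {
    half <- (taps - 1L) %/% 2L
    tri <- half + 1L - abs(seq(-half, half))
    k <- tri / sum(tri)
    padded <- c(rep(x[1L], half), x, rep(x[length(x)], half))
    x <- as.numeric(stats::filter(padded, k, method = "convolution",
                                  sides = 2L))[(half + 1L):(half + length(x))]
  }
  add_gaussian_noise(x, noise_std, seed)
}

#' Generate a complete synthetic training dataset
#'
#' For each read: a random sequence is drawn, converted to its expected
#' signal under a synthetic pore model, expanded by sampled repeat
#' counts into a square-wave ground truth, and turned into a real-like
#' target by transition smoothing plus Gaussian noise (injected in
#' normalized units so difficulty does not depend on the pore-model
#' scale). Pairs are z-score normalized; the manifest records every
#' parameter so the dataset regenerates bit-identically from its seed.
#'
#' @param n_reads number of reads (default 200).
#' @param seq_length bases per read (default 500).
#' @param edge_smooth_taps,noise_std passed to [synthesize_real_like()];
#'   `noise_std` is in normalized (z-score) units.
#' @param repeat_model_ dwell model for [sample_repeat_counts()].
#' @param pore_model_seed seed of the synthetic pore model.
#' @param seed master seed for the whole dataset.
#' @return a list with `pairs` (list of [training_pair()]), `reads`
#'   (per-read sequence, ground truth, target and repeats) and
#'   `manifest` (all generation parameters).
#' @examples
#' ds <- make_dataset(n_reads = 3, seq_length = 60, seed = 1)
#' length(ds$pairs)
#' @export
make_dataset <- function(n_reads = 200L, seq_length = 500L,
                         edge_smooth_taps = 5L, noise_std = 0.15,
                         repeat_model_ = repeat_model(),
                         pore_model_seed = 1L, seed = 1L) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) stop_input("n_reads must be >= 1")
  pm <- synthetic_pore_model(pore_model_seed)
  manifest <- list(n_reads = n_reads, seq_length = as.integer(seq_length),
                   edge_smooth_taps = as.integer(edge_smooth_taps),
                   noise_std = noise_std,
                   repeat_model = unclass(repeat_model_),
                   pore_model_seed = as.integer(pore_model_seed),
                   seed = as.integer(seed))
  with_seed(seed, {
    reads <- vector("list", n_reads)
    pairs <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      sq <- random_sequence(seq_length)
      ev <- expected_signal(sq, pm)
      reps <- sample_repeat_counts(length(ev), repeat_model_)
      gt <- assemble_ground_truth(ev, reps)
      zg <- zscore_normalize(gt)
      # smooth + noise in normalized units
      target <- synthesize_real_like(zg$values, edge_smooth_taps, noise_std)
      pairs[[r]] <- training_pair(zg$values, target,
                                  tag = sprintf("synthetic_read_%03d", r))
      reads[[r]] <- list(sequence = sq, repeats = reps,
                         ground_truth = as.numeric(gt),
                         ground_truth_stats = zg$stats,
                         target = target)
    }
    list(pairs = pairs, reads = reads, manifest = manifest)
  })
}
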