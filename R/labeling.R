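#' Dynamic time warping between two signals
#'
#' Classical DTW with local cost `|a_i - b_j|` and steps consuming one
#' sample of either or both signals. The optimal path is monotone and
#' continuous, starting at (1, 1) and ending at (length(a), length(b)).
#' Ties are broken deterministically: the diagonal step is preferred,
#' then the step consuming `a`. An optional Sakoe-Chiba band (scaled to
#' the length ratio) restricts the search corridor; with a band the
#' returned path is optimal within the band. By default no band is used
#' for signals up to 50,000 samples and a radius of 1000 above that.
#'
#' @param a,b non-empty numeric signals.
#' @param band_radius corridor half-width in samples (>= 1), `NULL` for
#'   the length-based default, `Inf`/negative to force no band.
#' @return an object of class `"warp_path"`: list with `steps` (two-column
#'   matrix of aligned 1-based indices into `a` and `b`) and
#'   `total_cost`.
#' @examples
#' dtw_path(c(1, 2, 3), c(1, 3))
#' @export
dtw_path <- function(a, b, band_radius = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  check_numeric_vector(a, "a"); check_numeric_vector(b, "b")
  if (is.null(band_radius))
    band_radius <- if (max(length(a), length(b)) > 50000L) 1000L else -1L
  else if (!is.finite(band_radius) || band_radius < 0)
    band_radius <- -1L
  else {
    band_radius <- as.integer(band_radius)
    if (band_radius < 1L)
      stop_input("band_radius must be >= 1 (or NULL/Inf for no band)")
  }
  res <- cpp_dtw(a, b, as.integer(band_radius))
  structure(list(steps = cbind(i = res$i, j = res$j),
                 total_cost = res$cost),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf("DTW warp path: %d steps, (1,1) -> (%d,%d), total cost %.4g\n",
              n, x$steps[n, 1L], x$steps[n, 2L], x$total_cost))
  invisible(x)
}

#' Label a raw signal with its ground truth via DTW
#'
#' Maps every raw-signal sample onto the expected signal by dynamic time
#' warping (both signals are z-score normalized before warping), then
#' reads off the expected level matched to each raw position — the
#' ground-truth signal of the read. When a raw position matches several
#' expected positions the first match is kept. The result is the
#' supervised pair (normalized ground truth as input `I`, normalized raw
#' signal as target `R`) used to train the network.
#'
#' Because the raw signal's per-read statistics weight each level by its
#' dwell time, independently z-scored signals differ by a small affine
#' error that can shift level boundaries by a sample. `refine`
#' re-estimates the affine map from expected to raw levels on the
#' current alignment (least squares) and re-warps, which removes the
#' boundary slippage.
#'
#' @param raw numeric raw signal (pA or normalized).
#' @param expected the matching [expected_signal()] (or numeric levels).
#' @param band_radius passed to [dtw_path()].
#' @param refine number of affine-rescaling re-warping iterations
#'   (default 1).
#' @return a [training_pair()]; its attribute `"expected_index"` gives,
#'   for each raw position, the 1-based expected-signal position it was
#'   matched to.
#' @export
label_read <- function(raw, expected, band_radius = NULL, refine = 1L) {
  raw <- as.numeric(raw)
  ev <- as.numeric(expected)
  check_numeric_vector(raw, "raw"); check_numeric_vector(ev, "expected")
  zr <- if (length(raw) > 1L && sd(raw) > 0) zscore_normalize(raw)$values
        else raw
  ze <- if (length(ev) > 1L && sd(ev) > 0) zscore_normalize(ev)$values
        else ev
  first_match <- function(path) {
    first <- !duplicated(path$steps[, 1L])
    path$steps[first, 2L]
  }
  idx <- first_match(dtw_path(zr, ze, band_radius))
  for (it in seq_len(max(0L, as.integer(refine)))) {
    if (sd(ze[idx]) == 0) break
    ab <- stats::coef(stats::lm.fit(cbind(1, ze[idx]), zr))
    idx <- first_match(dtw_path(zr, ab[1L] + ab[2L] * ze, band_radius))
  }
  G <- ev[idx]
  gI <- if (length(G) > 1L && sd(G) > 0) zscore_normalize(G)$values else G
  out <- training_pair(gI, zr, tag = "labeled")
  attr(out, "expected_index") <- idx
  attr(out, "ground_truth") <- G
  out
}
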