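#' Normalized DTW distance between two signals
#'
#' The DTW total cost divided by the warp-path length (its number of
#' aligned index pairs), making signals of different lengths
#' comparable. Both signals are z-score normalized first so the measure
#' is invariant to offset and scale; set `normalize = FALSE` to compare
#' raw values.
#'
#' @param a,b numeric signals.
#' @param normalize z-score both signals before warping (default TRUE).
#' @param band_radius passed to [dtw_path()].
#' @return the normalized DTW distance (>= 0; 0 iff warp-identical).
#' @examples
#' normalized_dtw(sin(1:100 / 5), sin(1:100 / 5))
#' @export
normalized_dtw <- function(a, b, normalize = TRUE, band_radius = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (normalize) {
    a <- zscore_normalize(a)$values
    b <- zscore_normalize(b)$values
  }
  p <- dtw_path(a, b, band_radius)
  p$total_cost / nrow(p$steps)
}

#' Continuous wavelet spectrum (Morlet)
#'
#' Computes the magnitude of the continuous wavelet transform with the
#' analytic Morlet wavelet (center frequency `omega0 = 6`) over
#' logarithmically spaced scales whose pseudo-frequencies span
#' `[sample_rate/length, sample_rate/2]`. The transform is evaluated in
#' the frequency domain (Torrence-Compo normalization), so it is exact,
#' deterministic, and fast.
#'
#' @param x numeric signal, length >= 16.
#' @param n_scales number of scales (default 64).
#' @param sample_rate_hz sampling rate in Hz (default 4000).
#' @param omega0 Morlet center frequency (default 6).
#' @return an object of class `"cwt_spectrum"`: list with `magnitudes`
#'   (`n_scales x length(x)`, rows ordered by descending frequency),
#'   `frequencies_hz`, and `sample_rate_hz`.
#' @export
cwt_spectrum <- function(x, n_scales = 64L, sample_rate_hz = 4000,
                         omega0 = 6) {
  x <- as.numeric(x)
  check_numeric_vector(x, "x")
  n <- length(x)
  if (n < 16L) stop_input("signal too short for a CWT (need >= 16 samples)")
  n_scales <- as.integer(n_scales)
  if (is.na(n_scales) || n_scales < 2L) stop_input("n_scales must be >= 2")
  dt <- 1 / sample_rate_hz
  # Fourier factor: wavelength per unit scale for the Morlet wavelet
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  freqs <- exp(seq(log(sample_rate_hz / 2), log(sample_rate_hz / n),
                   length.out = n_scales))
  scales <- 1 / (fourier_factor * freqs * dt)     # in samples
  # FFT angular frequencies (radians/sample), positive then negative half
  omega_k <- if (n %% 2L == 0L)
    2 * pi * c(0:(n %/% 2), -((n %/% 2 - 1):1)) / n
  else
    2 * pi * c(0:(n %/% 2), -((n %/% 2):1)) / n
  xh <- fft(x)
  mags <- matrix(0, n_scales, n)
  for (s in seq_len(n_scales)) {
    sc <- scales[s]
    psi_hat <- numeric(n)
    pos <- omega_k > 0
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * sc) *
      exp(-(sc * omega_k[pos] - omega0)^2 / 2)
    w <- fft(xh * psi_hat, inverse = TRUE) / n
    mags[s, ] <- Mod(w)
  }
  structure(list(magnitudes = mags, frequencies_hz = freqs,
                 sample_rate_hz = sample_rate_hz),
            class = "cwt_spectrum")
}

#' @export
print.cwt_spectrum <- function(x, ...) {
  cat(sprintf("CWT spectrum: %d scales x %d samples, %.2f-%.1f Hz @ %g Hz\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$frequencies_hz), max(x$frequencies_hz),
              x$sample_rate_hz))
  invisible(x)
}

#' Pearson correlation between two CWT spectra
#'
#' Flattens the two magnitude matrices and computes their Pearson
#' correlation coefficient, overall and separately for the
#' low-frequency (`< split_hz`) and high-frequency (`>= split_hz`)
#' scale rows. The default split of 450 Hz is the base-translocation
#' rate, separating level-transition content from within-level content.
#'
#' @param s1,s2 `"cwt_spectrum"` objects with identical shape and
#'   frequency axes.
#' @param split_hz frequency splitting the low and high bands.
#' @return a list with `pcc_all`, `pcc_low`, `pcc_high`.
#' @export
spectrum_pcc <- function(s1, s2, split_hz = 450) {
  stopifnot(inherits(s1, "cwt_spectrum"), inherits(s2, "cwt_spectrum"))
  if (!all(dim(s1$magnitudes) == dim(s2$magnitudes)))
    stop_input("spectra have different shapes")
  if (max(abs(s1$frequencies_hz - s2$frequencies_hz)) > 1e-9)
    stop_input("spectra have different frequency axes")
  pcc <- function(m1, m2) {
    v1 <- as.numeric(m1); v2 <- as.numeric(m2)
    if (sd(v1) == 0 || sd(v2) == 0)
      stop_input("zero-variance spectrum part: correlation undefined")
    cor(v1, v2)
  }
  low <- s1$frequencies_hz < split_hz
  if (!any(low) || all(low))
    stop_input("split_hz leaves an empty low- or high-frequency band")
  list(pcc_all = pcc(s1$magnitudes, s2$magnitudes),
       pcc_low = pcc(s1$magnitudes[low, ], s2$magnitudes[low, ]),
       pcc_high = pcc(s1$magnitudes[!low, ], s2$magnitudes[!low, ]))
}
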