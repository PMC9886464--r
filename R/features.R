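# Hand-crafted feature extraction: 10 time-domain statistics, 3 spectral
# quality metrics (SNR/SINAD/THD), 13 mel-frequency cepstral coefficients.

#' Canonical names of the 26 extracted features, in fixed order
#' @return Character vector of length 26.
#' @export
feature_names <- function() {
  c("rms", "shape_factor", "skewness", "kurtosis", "peak", "impulse_factor",
    "crest_factor", "clearance_factor", "mean", "std",
    "snr_db", "sinad_db", "thd_db",
    paste0("mfcc", 1:13))
}

#' Time-domain features
#'
#' Ten statistics of the raw waveform. Skewness and kurtosis are the third
#' and fourth standardized central moments with the 1/N convention; kurtosis
#' is the raw moment (a Gaussian gives 3 -- no excess-kurtosis subtraction).
#' `std` uses the sample (N-1) divisor. The factor features are the classic
#' waveform-shape ratios:
#' \describe{
#'   \item{rms}{`sqrt(mean(x^2))`}
#'   \item{shape_factor}{`rms / mean(|x|)`}
#'   \item{peak}{`max(|x|)`}
#'   \item{impulse_factor}{`peak / mean(|x|)`}
#'   \item{crest_factor}{`peak / rms`}
#'   \item{clearance_factor}{`peak / mean(sqrt(|x|))^2`}
#' }
#'
#' @param signal A [pcg_signal] with >= 2 samples, not all zero and not
#'   constant.
#' @return Named numeric vector of length 10.
#' @export
time_domain_features <- function(signal) {
  stopifnot(inherits(signal, "pcg_signal"))
  x <- signal$samples
  n <- length(x)
  if (n < 2L) abort_validation("need at least 2 samples, got %d", n)
  if (all(x == 0))
    abort_degenerate("all-zero signal: ratio denominators vanish")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0)
    abort_degenerate("constant signal: moment denominators vanish")
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  abs_mean <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  c(rms              = rms,
    shape_factor     = rms / abs_mean,
    skewness         = m3 / m2^1.5,
    kurtosis         = m4 / m2^2,
    peak             = peak,
    impulse_factor   = peak / abs_mean,
    crest_factor     = peak / rms,
    clearance_factor = peak / mean(sqrt(abs(x)))^2,
    mean             = mu,
    std              = stats::sd(x))
}

#' Spectral quality features: SNR, SINAD, THD (dB)
#'
#' Computed from a Kaiser-windowed periodogram. The fundamental is the
#' largest non-DC spectral component; spectral peaks are grouped with
#' `peak_halfwidth` bins on either side to absorb window leakage. With
#' `P_f` the fundamental power, `P_h` the summed power of the first
#' `n_harmonics` harmonics and `P_n` all remaining (noise) power excluding
#' the DC region: `snr_db = 10 log10(P_f / P_n)`,
#' `sinad_db = 10 log10(P_f / (P_n + P_h))`,
#' `thd_db = 10 log10(P_h / P_f)`.
#'
#' @param signal A [pcg_signal] with >= 64 samples.
#' @param n_harmonics Number of harmonics (orders 2..n+1) treated as
#'   distortion; default 6.
#' @param peak_halfwidth Bins on each side of a peak grouped with it;
#'   default 16 (covers the Kaiser beta = 38 mainlobe).
#' @return Named numeric vector `snr_db`, `sinad_db`, `thd_db`.
#' @export
spectral_quality_features <- function(signal, n_harmonics = 6, peak_halfwidth = 16) {
  stopifnot(inherits(signal, "pcg_signal"))
  x <- signal$samples
  n <- length(x)
  if (n < 64L) abort_validation("need >= 64 samples for a periodogram, got %d", n)
  x <- x - mean(x)
  w <- signal::kaiser(n, 38)
  P <- Mod(stats::fft(x * w))^2
  half <- floor(n / 2) + 1L
  P <- P[seq_len(half)]                       # one-sided power, bin 1 = DC
  hw <- as.integer(peak_halfwidth)

  dc_zone <- seq_len(min(half, 1L + hw))
  search <- setdiff(seq_len(half), dc_zone)
  if (!length(search) || max(P[search]) <= 0 ||
      max(P[search]) < .Machine$double.eps * sum(P))
    abort_degenerate("flat spectrum: no fundamental component found")
  f_bin <- search[which.max(P[search])]
  zone <- function(center) {
    lo <- max(1L, center - hw); hi <- min(half, center + hw)
    lo:hi
  }
  f_zone <- zone(f_bin)
  p_fund <- sum(P[f_zone])

  p_harm <- 0
  h_zones <- integer(0)
  f0 <- f_bin - 1L                            # fundamental in bin offsets
  for (k in 2:(n_harmonics + 1L)) {
    hb <- f0 * k + 1L
    if (hb - hw > half) break
    lo <- max(1L, hb - hw); hi <- min(half, hb + hw)
    cand <- lo:hi
    cand <- setdiff(cand, c(f_zone, h_zones, dc_zone))
    if (!length(cand)) next
    pk <- cand[which.max(P[cand])]            # re-center on the local peak
    hz <- setdiff(zone(pk), c(f_zone, h_zones, dc_zone))
    p_harm <- p_harm + sum(P[hz])
    h_zones <- c(h_zones, hz)
  }
  noise_bins <- setdiff(seq_len(half), c(dc_zone, f_zone, h_zones))
  p_noise <- sum(P[noise_bins])

  c(snr_db   = 10 * log10(p_fund / p_noise),
    sinad_db = 10 * log10(p_fund / (p_noise + p_harm)),
    thd_db   = 10 * log10(p_harm / p_fund))
}

#' Mel scale conversion
#'
#' `mel(f) = 2595 * log10(1 + f / 700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @return Mel value(s).
#' @examples
#' mel_scale(700)  # 2595 * log10(2)
#' @export
mel_scale <- function(f) 2595 * log10(1 + f / 700)

#' @rdname mel_scale
#' @param m Mel value.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel-frequency cepstral coefficients of a recording
#'
#' Per frame: Hamming window, FFT power spectrum, triangular mel filter
#' bank (band edges equally spaced on the [mel_scale()]), log filter
#' energies, orthonormal type-II DCT. The recording-level features are the
#' per-coefficient mean over frames. Coefficients 0..12 are retained by
#' default (the 0th is the log-energy-like constant-basis coefficient).
#'
#' @param signal A [pcg_signal] at least one frame long.
#' @param n_coeffs Coefficients retained (default 13).
#' @param frame_len Frame length in seconds (default 0.025).
#' @param hop Frame hop in seconds (default 0.010).
#' @param n_filters Mel filters (default 26).
#' @param include_c0 Keep the 0th coefficient (default TRUE); if FALSE,
#'   coefficients 1..n_coeffs are returned instead.
#' @return Named numeric vector `mfcc1`..`mfcc13` (c0 maps to `mfcc1`).
#' @export
mfcc_features <- function(signal, n_coeffs = 13, frame_len = 0.025, hop = 0.010,
                          n_filters = 26, include_c0 = TRUE) {
  stopifnot(inherits(signal, "pcg_signal"))
  x <- signal$samples
  rate <- signal$rate
  flen <- round(frame_len * rate)
  fhop <- max(1L, round(hop * rate))
  if (length(x) < flen)
    abort_validation("signal (%d samples) is shorter than one %d-sample frame",
                     length(x), flen)
  nfft <- 2^ceiling(log2(flen))
  fb <- mel_filterbank(n_filters, nfft, rate)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  starts <- seq(1L, length(x) - flen + 1L, by = fhop)

  n_keep <- n_coeffs
  dct_rows <- if (include_c0) 0:(n_keep - 1L) else 1:n_keep
  D <- dct_ortho_matrix(n_filters)[dct_rows + 1L, , drop = FALSE]

  acc <- numeric(n_keep)
  for (s in starts) {
    fr <- x[s:(s + flen - 1L)] * ham
    spec <- Mod(stats::fft(c(fr, numeric(nfft - flen))))^2
    spec <- spec[seq_len(nfft / 2 + 1L)]
    e <- as.vector(fb %*% spec)
    acc <- acc + as.vector(D %*% log(pmax(e, .Machine$double.xmin)))
  }
  out <- acc / length(starts)
  names(out) <- paste0("mfcc", seq_len(n_keep))
  out
}

# Triangular mel filter bank: n_filters x (nfft/2 + 1) weight matrix, band
# edges equally spaced in mel between 0 and rate/2 (HTK-style triangles
# evaluated at the FFT bin frequencies).
mel_filterbank <- function(n_filters, nfft, rate, fmin = 0, fmax = rate / 2) {
  pts <- mel_to_hz(seq(mel_scale(fmin), mel_scale(fmax), length.out = n_filters + 2L))
  bins <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_filters, nfft / 2 + 1L)
  for (i in seq_len(n_filters)) {
    lo <- pts[i]; mid <- pts[i + 1L]; hi <- pts[i + 2L]
    up <- (bins - lo) / (mid - lo)
    down <- (hi - bins) / (hi - mid)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal type-II DCT matrix (M x M).
dct_ortho_matrix <- function(M) {
  k <- 0:(M - 1L)
  D <- sqrt(2 / M) * cos(pi * outer(k, (k + 0.5)) / M)
  D[1L, ] <- D[1L, ] / sqrt(2)
  D
}

#' Extract the full 26-feature vector of a recording
#'
#' Concatenates [time_domain_features()], [spectral_quality_features()] and
#' [mfcc_features()] in the canonical [feature_names()] order.
#'
#' @param signal A valid [pcg_signal] (typically resampled to 8000 Hz and
#'   z-score normalized).
#' @param mfcc Named list of arguments forwarded to [mfcc_features()].
#' @return Named numeric vector of 26 finite values.
#' @export
extract_features <- function(signal, mfcc = list()) {
  v <- c(time_domain_features(signal),
         spectral_quality_features(signal),
         do.call(mfcc_features, c(list(signal = signal), mfcc)))
  stopifnot(identical(names(v), feature_names()))
  v
}

#' Extract a feature table for a collection of recordings
#'
#' @param signals List of labeled [pcg_signal] objects.
#' @param normalize Apply [zscore_normalize()] to each recording first
#'   (default TRUE).
#' @param mfcc Passed to [extract_features()].
#' @return Data.frame with the 26 feature columns plus a `label` column.
#' @export
extract_feature_table <- function(signals, normalize = TRUE, mfcc = list()) {
  rows <- lapply(signals, function(s) {
    if (normalize) s <- zscore_normalize(s)
    extract_features(s, mfcc = mfcc)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- vapply(signals, function(s) s$label %||% NA_character_, character(1))
  df
}
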