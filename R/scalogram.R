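# Continuous wavelet transform with the generalized Morse wavelet and
# export of 224 x 224 RGB scalogram images for transfer-learning datasets.

#' Continuous wavelet transform scalogram (generalized Morse wavelet)
#'
#' Computes the CWT of a signal with an analytic generalized Morse wavelet
#' filter bank (symmetry parameter `gamma = 3`, time-bandwidth product
#' `P^2 = 60` by default) evaluated in the frequency domain, with peak-
#' normalized (L-infinity) wavelets so a unit sinusoid produces a unit-
#' magnitude ridge at its frequency. Center frequencies are spaced
#' geometrically with `voices_per_octave` voices per octave.
#'
#' @param signal A [pcg_signal] (normalize with [zscore_normalize()] first
#'   for comparable images).
#' @param voices_per_octave Voices per octave (default 12).
#' @param gamma Morse symmetry parameter (default 3).
#' @param time_bandwidth Time-bandwidth product `beta * gamma` (default 60).
#' @param freq_range Optional `c(fmin, fmax)` in Hz. By default `fmax` is
#'   0.45 of the sample rate and `fmin` is the lowest frequency whose
#'   wavelet time support fits the recording; an explicit `fmin` whose
#'   wavelet does not fit is a validation error.
#' @return A `pcg_scalogram`: list with `magnitude` (freq x time,
#'   non-negative), `freqs` (Hz, descending), `times` (s, increasing).
#' @export
cwt_scalogram <- function(signal, voices_per_octave = 12, gamma = 3,
                          time_bandwidth = 60, freq_range = NULL) {
  stopifnot(inherits(signal, "pcg_signal"))
  x <- signal$samples
  n <- length(x)
  rate <- signal$rate
  beta <- time_bandwidth / gamma
  omega_p <- (beta / gamma)^(1 / gamma)       # wavelet peak (radian) frequency
  p_dur <- sqrt(beta * gamma)                 # wavelet duration in radians

  # lowest admissible frequency: two full wavelet supports in the record
  fmin_auto <- 2 * p_dur / (pi * (n / rate))
  if (is.null(freq_range)) {
    fmax <- 0.45 * rate
    fmin <- fmin_auto
  } else {
    fmin <- freq_range[1]; fmax <- freq_range[2]
    if (fmin < fmin_auto)
      abort_validation(
        "signal (%.3f s) is shorter than the wavelet support at %.2f Hz (min %.2f Hz)",
        n / rate, fmin, fmin_auto)
  }
  if (fmin >= fmax)
    abort_validation("empty frequency range [%g, %g]", fmin, fmax)

  n_oct <- log2(fmax / fmin)
  freqs <- fmax * 2^(-(0:floor(n_oct * voices_per_octave)) / voices_per_octave)
  omega <- 2 * pi * (0:(n - 1)) / n           # DFT radian frequencies
  pos <- omega > 0 & omega <= pi              # analytic wavelet: positive axis

  X <- stats::fft(x)
  mag <- matrix(0, length(freqs), n)
  ln_norm <- beta * log(omega_p) - omega_p^gamma
  for (i in seq_along(freqs)) {
    s <- omega_p / (2 * pi * freqs[i] / rate) # scale in samples
    psi <- numeric(n)
    so <- s * omega[pos]
    psi[pos] <- 2 * exp(beta * log(so) - so^gamma - ln_norm)
    mag[i, ] <- Mod(stats::fft(X * psi, inverse = TRUE)) / n
  }
  structure(list(magnitude = mag, freqs = freqs, times = (0:(n - 1)) / rate,
                 rate = rate, gamma = gamma, time_bandwidth = time_bandwidth,
                 voices_per_octave = voices_per_octave),
            class = "pcg_scalogram")
}

#' @export
print.pcg_scalogram <- function(x, ...) {
  cat(sprintf("<pcg_scalogram> %d freqs (%.1f-%.1f Hz) x %d times (%.3f s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), max(x$times)))
  invisible(x)
}

# 128-level jet-style colormap, rows = levels, columns = R,G,B in [0,1].
scalogram_palette <- function(levels = 128) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#007FFF", "#00FFFF",
                                 "#7FFF7F", "#FFFF00", "#FF7F00", "#FF0000",
                                 "#7F0000"))
  ramp(seq(0, 1, length.out = levels)) / 255
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Magnitudes are min-max scaled per image (so a global gain change leaves
#' the image untouched), bilinearly resized to `size x size`, quantized to
#' a fixed 128-level jet-style colormap and expanded to 3 channels. A
#' constant-magnitude scalogram maps to the colormap's lowest level.
#'
#' @param scalogram A `pcg_scalogram`.
#' @param size Output side length in pixels (default 224, the input size
#'   of standard image-classification networks).
#' @param levels Colormap levels (default 128).
#' @return A `size x size x 3` numeric array in `[0, 1]` (rows top-down
#'   from the highest frequency).
#' @export
to_rgb_image <- function(scalogram, size = 224, levels = 128) {
  stopifnot(inherits(scalogram, "pcg_scalogram"))
  m <- scalogram$magnitude
  if (length(m) == 0L) abort_validation("empty scalogram")
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  # EBImage images are x (columns) first: transpose so time -> x, freq -> y
  rs <- EBImage::resize(t(m), w = size, h = size)
  rs <- t(rs)
  rs <- pmin(pmax(rs, 0), 1)
  idx <- pmin(floor(rs * levels) + 1L, levels)
  pal <- scalogram_palette(levels)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- pal[idx, ch]
  img
}

#' Export a labeled signal collection as a scalogram image dataset
#'
#' Writes one PNG per recording into a folder named after its class, plus
#' a `manifest.csv` mapping file to label -- the layout consumed by
#' external image-classifier trainers. All recordings must share one
#' sample rate (resample first with [resample_to()]).
#'
#' @param signals List of labeled [pcg_signal] objects.
#' @param out_dir Output directory.
#' @param size Image side length (default 224).
#' @param normalize Apply [zscore_normalize()] before the CWT (default
#'   TRUE).
#' @param ... Passed to [cwt_scalogram()].
#' @return Data.frame manifest (file, label), invisibly.
#' @export
export_image_dataset <- function(signals, out_dir, size = 224,
                                 normalize = TRUE, ...) {
  labels <- vapply(signals, function(s) s$label %||% NA_character_, character(1))
  if (anyNA(labels))
    abort_validation("all signals must carry a class label")
  rates <- unique(vapply(signals, function(s) s$rate, numeric(1)))
  if (length(rates) > 1L)
    abort_validation("mixed sample rates (%s): resample_to(8000) first",
                     paste(rates, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io("cannot create %s", out_dir)

  counter <- stats::setNames(integer(length(unique(labels))), unique(labels))
  files <- character(length(signals))
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    counter[s$label] <- counter[s$label] + 1L
    rel <- file.path(s$label, sprintf("%s_%04d.png", s$label, counter[s$label]))
    dir.create(file.path(out_dir, s$label), showWarnings = FALSE)
    if (normalize) s <- zscore_normalize(s)
    img <- to_rgb_image(cwt_scalogram(s, ...), size = size)
    png::writePNG(img, file.path(out_dir, rel))
    files[i] <- rel
  }
  manifest <- data.frame(file = files, label = labels, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
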