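# Synthetic phonocardiogram simulator. S1/S2 valve-closure sounds are
# Gaussian-windowed tone bursts; murmurs are envelope-modulated band-passed
# white noise -- standard PCG phenomenology, spectrally controllable, cheap.

#' Default cycle recipe for a diagnostic class
#'
#' Returns the fixed constants describing one cardiac cycle for a class:
#' heart rate, S1/S2 burst center frequencies and durations, the murmur
#' window (in fractional systole/diastole coordinates), murmur frequency
#' band and envelope shape, optional mid-systolic click, and additive noise
#' SNR. These defaults are the study conditions for all seeded tests.
#'
#' Class phenomenology: N has S1/S2 only; AS a diamond-envelope systolic
#' ejection murmur (~100-400 Hz); MR a plateau holosystolic murmur; MS a
#' low-frequency (~40-100 Hz) diastolic rumble; MVP a mid-systolic click
#' followed by a late-systolic crescendo murmur.
#'
#' @param class_label One of [PCG_CLASSES].
#' @return A named list (the cycle recipe).
#' @export
default_recipe <- function(class_label) {
  if (!(class_label %in% PCG_CLASSES))
    abort_validation("unknown class label '%s'", paste(class_label, collapse = ","))
  base <- list(
    heart_rate   = 70,      # bpm
    s1_freq      = 90,      # Hz
    s1_dur       = 0.10,    # s
    s2_freq      = 140,
    s2_dur       = 0.07,
    systole_frac = 0.35,    # S2 onset as a fraction of the cycle
    murmur_phase = NULL, murmur_window = NULL, murmur_band = NULL,
    murmur_envelope = NULL, murmur_amp = 0,
    click        = NULL,
    noise_snr    = 25       # dB
  )
  mods <- switch(class_label,
    N   = list(),
    AS  = list(murmur_phase = "systole", murmur_window = c(0.10, 0.95),
               murmur_band = c(100, 400), murmur_envelope = "diamond",
               murmur_amp = 0.50),
    MR  = list(murmur_phase = "systole", murmur_window = c(0.00, 1.00),
               murmur_band = c(100, 350), murmur_envelope = "plateau",
               murmur_amp = 0.40),
    MS  = list(murmur_phase = "diastole", murmur_window = c(0.25, 0.85),
               murmur_band = c(40, 100), murmur_envelope = "decrescendo",
               murmur_amp = 0.55),
    MVP = list(murmur_phase = "systole", murmur_window = c(0.55, 1.00),
               murmur_band = c(150, 400), murmur_envelope = "late-crescendo",
               murmur_amp = 0.45,
               click = list(pos = 0.45, freq = 300, dur = 0.025, amp = 0.7))
  )
  utils::modifyList(base, mods)
}

#' Synthesize one labeled phonocardiogram
#'
#' Deterministic for a fixed seed. The recording contains periodic S1/S2
#' bursts plus the class-specific murmur of [default_recipe()], additive
#' Gaussian noise at the recipe's SNR, and is peak-normalized to 0.9 so no
#' sample clips.
#'
#' @param class_label One of [PCG_CLASSES].
#' @param duration Recording length in seconds (must cover at least one
#'   cardiac cycle).
#' @param rate Sample rate in Hz.
#' @param seed Integer RNG seed.
#' @param recipe_override Named list of recipe fields to override (e.g.
#'   `list(noise_snr = Inf)` for a noise-free recording).
#' @return A labeled [pcg_signal].
#' @examples
#' s <- synth_recording("AS", duration = 3, seed = 1)
#' @export
synth_recording <- function(class_label, duration = 3, rate = 8000, seed = 1,
                            recipe_override = NULL) {
  rec <- default_recipe(class_label)
  if (!is.null(recipe_override)) rec <- utils::modifyList(rec, recipe_override)
  cycle <- 60 / rec$heart_rate
  if (duration < cycle)
    abort_validation("duration %.2f s is shorter than one cardiac cycle (%.2f s)",
                     duration, cycle)
  if (!is.null(rec$murmur_band) && rec$murmur_band[2] >= rate / 2)
    abort_validation("murmur band upper edge %g Hz must be below Nyquist %g Hz",
                     rec$murmur_band[2], rate / 2)

  n <- round(duration * rate)
  t <- (0:(n - 1)) / rate
  with_seed(seed, {
    x <- numeric(n)
    starts <- seq(0, duration, by = cycle)
    sys_on <- rec$s1_dur                      # systole: S1 end .. S2 onset
    sys_off <- rec$systole_frac * cycle
    dia_on <- sys_off + rec$s2_dur            # diastole: S2 end .. next S1
    dia_off <- cycle

    for (t0 in starts) {
      x <- x + gauss_burst(t, t0 + rec$s1_dur / 2, rec$s1_dur, rec$s1_freq, 1.0)
      x <- x + gauss_burst(t, t0 + sys_off + rec$s2_dur / 2, rec$s2_dur, rec$s2_freq, 0.8)
      if (!is.null(rec$click)) {
        ct <- t0 + sys_on + rec$click$pos * (sys_off - sys_on)
        x <- x + gauss_burst(t, ct, rec$click$dur, rec$click$freq, rec$click$amp)
      }
    }

    if (!is.null(rec$murmur_phase) && rec$murmur_amp > 0) {
      noise <- stats::rnorm(n)
      bf <- signal::butter(4, rec$murmur_band / (rate / 2), type = "pass")
      bp <- signal::filtfilt(bf, noise)
      bp <- bp / stats::sd(bp)
      win <- if (rec$murmur_phase == "systole") c(sys_on, sys_off) else c(dia_on, dia_off)
      env <- numeric(n)
      for (t0 in starts) {
        a <- t0 + win[1] + rec$murmur_window[1] * (win[2] - win[1])
        b <- t0 + win[1] + rec$murmur_window[2] * (win[2] - win[1])
        idx <- which(t >= a & t <= b)
        if (length(idx)) {
          u <- (t[idx] - a) / (b - a)
          env[idx] <- murmur_envelope(u, rec$murmur_envelope)
        }
      }
      x <- x + rec$murmur_amp * env * bp
    }

    if (is.finite(rec$noise_snr)) {
      p_sig <- mean(x^2)
      x <- x + stats::rnorm(n, sd = sqrt(p_sig / 10^(rec$noise_snr / 10)))
    }
    x <- 0.9 * x / max(abs(x))
    pcg_signal(x, rate, class_label)
  })
}

gauss_burst <- function(t, center, dur, freq, amp) {
  amp * exp(-0.5 * ((t - center) / (dur / 6))^2) * sin(2 * pi * freq * (t - center))
}

murmur_envelope <- function(u, shape) {
  switch(shape,
    diamond          = 1 - abs(2 * u - 1),
    plateau          = pmin(1, u / 0.1, (1 - u) / 0.1),
    decrescendo      = 1 - 0.8 * u,
    `late-crescendo` = 0.2 + 0.8 * u,
    abort_validation("unknown murmur envelope '%s'", shape)
  )
}

#' Synthesize a balanced labeled dataset
#'
#' Generates `n_per_class` recordings for each of the five classes. Per-
#' recording seeds are derived deterministically from the master seed;
#' heart rate (+-10%) and murmur amplitude (+-20%) are jittered within a
#' class so recordings are not identical.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param duration,rate As in [synth_recording()].
#' @param seed Master integer seed.
#' @return A list with `signals` (list of labeled [pcg_signal]) and
#'   `manifest` (data.frame: filename, label, rate, duration, seed).
#' @export
synth_dataset <- function(n_per_class, duration = 3, rate = 8000, seed = 1) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    abort_validation("n_per_class must be >= 1")
  n_per_class <- as.integer(n_per_class)
  signals <- vector("list", 5L * n_per_class)
  rows <- vector("list", 5L * n_per_class)
  i <- 0L
  for (cls in PCG_CLASSES) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      s_jit <- derive_seed(seed, 2L * i)
      s_rec <- derive_seed(seed, 2L * i + 1L)
      ov <- with_seed(s_jit, {
        base <- default_recipe(cls)
        list(heart_rate = base$heart_rate * stats::runif(1, 0.9, 1.1),
             murmur_amp = base$murmur_amp * stats::runif(1, 0.8, 1.2))
      })
      signals[[i]] <- synth_recording(cls, duration, rate, s_rec, ov)
      rows[[i]] <- data.frame(
        filename = file.path(cls, sprintf("%s_%03d.wav", cls, j)),
        label = cls, rate = rate, duration = duration, seed = s_rec,
        stringsAsFactors = FALSE)
    }
  }
  list(signals = signals, manifest = do.call(rbind, rows))
}

#' Write a labeled dataset as WAV files in class-named folders
#'
#' @param dataset A list as returned by [synth_dataset()].
#' @param out_dir Output directory; class subfolders are created. A
#'   `manifest.csv` is written at the root.
#' @return `out_dir`, invisibly.
#' @export
write_pcg_dataset <- function(dataset, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io("cannot create output directory %s", out_dir)
  for (i in seq_along(dataset$signals)) {
    write_wav(dataset$signals[[i]],
              file.path(out_dir, dataset$manifest$filename[i]))
  }
  write_manifest(dataset$manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

#' Read a labeled dataset written by [write_pcg_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A list with `signals` and `manifest`, as [synth_dataset()].
#' @export
read_pcg_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  signals <- lapply(seq_len(nrow(manifest)), function(i)
    read_wav(file.path(dir, manifest$filename[i]), label = manifest$label[i]))
  list(signals = signals, manifest = manifest)
}
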