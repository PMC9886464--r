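#' Diagnostic classes recognised by the toolkit
#'
#' The five phonocardiogram classes, in the fixed order used by confusion
#' matrices and metric tables: aortic stenosis (AS), mitral regurgitation
#' (MR), mitral stenosis (MS), mitral valve prolapse (MVP) and normal (N).
#'
#' @format Character vector of length 5.
#' @export
PCG_CLASSES <- c("AS", "MR", "MS", "MVP", "N")

#' Construct a phonocardiogram signal
#'
#' The universal unit of audio exchange in the toolkit: a mono sample
#' sequence with its sample rate and an optional diagnostic class label.
#'
#' @param samples Numeric vector of dimensionless amplitudes (non-empty,
#'   all finite).
#' @param rate Sample rate in Hz (positive scalar).
#' @param label Optional class tag, one of [PCG_CLASSES].
#' @return An object of class `pcg_signal`: a list with elements `samples`,
#'   `rate` and `label`.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(s)
#' @export
pcg_signal <- function(samples, rate, label = NULL) {
  samples <- as.double(samples)
  if (length(samples) == 0L)
    abort_validation("signal must contain at least one sample")
  if (!all(is.finite(samples)))
    abort_validation("signal samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    abort_validation("sample rate must be a positive finite scalar, got %s",
                     paste(rate, collapse = ","))
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != 1L || !(label %in% PCG_CLASSES))
      abort_validation("unknown class label '%s' (expected one of %s)",
                       paste(label, collapse = ","),
                       paste(PCG_CLASSES, collapse = ", "))
  }
  structure(list(samples = samples, rate = as.double(rate), label = label),
            class = "pcg_signal")
}

#' @export
print.pcg_signal <- function(x, ...) {
  cat(sprintf("<pcg_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal A [pcg_signal].
#' @return Length in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "pcg_signal"))
  length(signal$samples) / signal$rate
}

#' Z-score normalize a signal
#'
#' Centers and scales a signal to zero mean and unit standard deviation,
#' `x_new = (x - mu) / sigma`, the canonical amplitude normalization applied
#' before feature extraction and scalogram computation. Rate and label are
#' preserved.
#'
#' @param signal A [pcg_signal] with at least 2 samples and non-zero
#'   standard deviation.
#' @param sd_type Standard-deviation convention: `"sample"` (divisor N-1,
#'   the default) or `"population"` (divisor N).
#' @return The normalized [pcg_signal].
#' @examples
#' zscore_normalize(pcg_signal(c(1, 2, 3), 10))$samples  # -1 0 1
#' @export
zscore_normalize <- function(signal, sd_type = c("sample", "population")) {
  stopifnot(inherits(signal, "pcg_signal"))
  sd_type <- match.arg(sd_type)
  x <- signal$samples
  n <- length(x)
  if (n < 2L)
    abort_validation("normalization requires at least 2 samples, got %d", n)
  mu <- mean(x)
  s2 <- sum((x - mu)^2) / (if (sd_type == "sample") n - 1 else n)
  s <- sqrt(s2)
  if (s == 0 || !is.finite(s))
    abort_degenerate("constant signal (sigma = 0) cannot be z-score normalized")
  pcg_signal((x - mu) / s, signal$rate, signal$label)
}
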