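#' Resample a signal with polyphase band-limited interpolation
#'
#' Rational-ratio resampling by zero-stuffing, a Kaiser-windowed linear-phase
#' FIR anti-aliasing/anti-imaging low-pass, and decimation, evaluated
#' polyphase so only the requested output samples are computed. Plain
#' decimation without filtering is never performed: aliasing would fold
#' high-frequency content into the murmur bands.
#'
#' @param signal A [pcg_signal].
#' @param target_rate Target sample rate in Hz (default 8000, the rate all
#'   downstream stages assume).
#' @param filter_half_len Half-length of the prototype low-pass in input
#'   zero-crossings (default 10; the FIR has `2 * filter_half_len *
#'   max(p, q) + 1` taps for the reduced ratio `p/q`).
#' @return The resampled [pcg_signal]; returned unchanged if already at
#'   `target_rate`. Duration is preserved to within one output sample period.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 100 * (0:44099) / 44100), 44100)
#' resample_to(s, 8000)
#' @export
resample_to <- function(signal, target_rate = 8000, filter_half_len = 10) {
  stopifnot(inherits(signal, "pcg_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    abort_validation("target_rate must be a positive scalar")
  if (signal$rate == target_rate) return(signal)

  # reduce the ratio to integers p/q (rates are scaled up if fractional)
  r_in <- signal$rate
  scale <- 1
  while (abs(target_rate * scale - round(target_rate * scale)) > 1e-9 ||
         abs(r_in * scale - round(r_in * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) abort_validation("cannot express rate ratio %g/%g as a rational",
                                      target_rate, r_in)
  }
  p <- as.integer(round(target_rate * scale))
  q <- as.integer(round(r_in * scale))
  g <- gcd_int(p, q)
  p <- p %/% g; q <- q %/% g

  y <- upfirdn_poly(signal$samples, p, q, filter_half_len)
  pcg_signal(y, target_rate, signal$label)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# Polyphase upfirdn: conceptually upsample x by p, filter with h, downsample
# by q -- but computed per output phase so the p-fold upsampled signal is
# never materialized. h is a Kaiser-windowed FIR (beta 7.8562, ~80 dB
# stopband) at cutoff 1/max(p,q) with passband gain p.
upfirdn_poly <- function(x, p, q, K = 10) {
  n <- length(x)
  M <- max(p, q)
  N <- 2L * K * M + 1L                       # odd taps, linear phase
  h <- signal::fir1(N - 1L, 1 / M, window = signal::kaiser(N, 7.8562)) * p
  delay <- (N - 1L) / 2
  n_out <- ceiling(n * p / q)
  L <- ceiling(N / p)
  xp <- c(numeric(L + 1L), x, numeric(L + 2L))    # zero padding for edges
  m_all <- 0:(n_out - 1L)
  u <- delay + m_all * q                     # index into the virtual upsampled stream
  r_all <- u %% p
  km <- u %/% p
  y <- numeric(n_out)
  for (grp in split(seq_len(n_out), r_all)) {
    r <- r_all[grp[1L]]
    ks <- km[grp]
    acc <- numeric(length(grp))
    s <- 0L
    while (r + s * p <= N - 1L) {
      acc <- acc + h[r + s * p + 1L] * xp[ks - s + 2L + L]
      s <- s + 1L
    }
    y[grp] <- acc
  }
  y
}
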