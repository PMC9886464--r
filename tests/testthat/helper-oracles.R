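# Independent reference implementations used as oracles. These are written
# from the defining formulas with explicit loops / direct DFTs and share no
# code path with the package internals.

naive_time_features <- function(x) {
  n <- length(x)
  mu <- 0; for (v in x) mu <- mu + v; mu <- mu / n
  m2 <- 0; m3 <- 0; m4 <- 0; sabs <- 0; ssq <- 0; ssqrt <- 0; pk <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
    sabs <- sabs + abs(v); ssq <- ssq + v^2; ssqrt <- ssqrt + sqrt(abs(v))
    if (abs(v) > pk) pk <- abs(v)
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  rms <- sqrt(ssq / n); abs_mean <- sabs / n
  c(rms = rms,
    shape_factor = rms / abs_mean,
    skewness = m3 / m2^(3 / 2),
    kurtosis = m4 / m2^2,
    peak = pk,
    impulse_factor = pk / abs_mean,
    crest_factor = pk / rms,
    clearance_factor = pk / (ssqrt / n)^2,
    mean = mu,
    std = sqrt(m2 * n / (n - 1)))
}

# Kaiser window from the Bessel-function definition.
naive_kaiser <- function(n, beta) {
  k <- 0:(n - 1)
  besselI(beta * sqrt(1 - (2 * k / (n - 1) - 1)^2), 0) / besselI(beta, 0)
}

# Direct (matrix) DFT one-sided power spectrum.
naive_power_spectrum <- function(x) {
  n <- length(x)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  P <- Mod(W %*% x)^2
  P[seq_len(floor(n / 2) + 1L)]
}

naive_spectral_quality <- function(x, n_harmonics = 6, hw = 16) {
  n <- length(x)
  x <- x - sum(x) / n
  P <- naive_power_spectrum(x * naive_kaiser(n, 38))
  half <- length(P)
  dc <- 1:(1 + hw)
  srch <- setdiff(seq_len(half), dc)
  fb <- srch[which.max(P[srch])]
  zone <- function(c0) max(1, c0 - hw):min(half, c0 + hw)
  fz <- zone(fb)
  p_f <- sum(P[fz])
  hz_all <- integer(0); p_h <- 0
  for (k in 2:(n_harmonics + 1)) {
    hb <- (fb - 1) * k + 1
    if (hb - hw > half) break
    cand <- setdiff(zone(hb), c(fz, hz_all, dc))
    if (!length(cand)) next
    pk <- cand[which.max(P[cand])]
    hz <- setdiff(zone(pk), c(fz, hz_all, dc))
    p_h <- p_h + sum(P[hz]); hz_all <- c(hz_all, hz)
  }
  p_n <- sum(P[setdiff(seq_len(half), c(dc, fz, hz_all))])
  c(snr_db = 10 * log10(p_f / p_n),
    sinad_db = 10 * log10(p_f / (p_n + p_h)),
    thd_db = 10 * log10(p_h / p_f))
}

naive_mfcc <- function(x, rate, n_coeffs = 13, frame_len = 0.025, hop = 0.010,
                       n_filters = 26) {
  flen <- round(frame_len * rate); fhop <- round(hop * rate)
  nfft <- 2^ceiling(log2(flen))
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(0, mel(rate / 2), length.out = n_filters + 2))
  bins <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_filters, nfft / 2 + 1)
  for (i in seq_len(n_filters)) {
    for (b in seq_along(bins)) {
      f <- bins[b]
      if (f >= pts[i] && f <= pts[i + 1]) {
        fb[i, b] <- (f - pts[i]) / (pts[i + 1] - pts[i])
      } else if (f > pts[i + 1] && f <= pts[i + 2]) {
        fb[i, b] <- (pts[i + 2] - f) / (pts[i + 2] - pts[i + 1])
      }
    }
  }
  starts <- seq(1, length(x) - flen + 1, by = fhop)
  acc <- numeric(n_coeffs)
  for (s in starts) {
    fr <- c(x[s:(s + flen - 1)] * ham, numeric(nfft - flen))
    P <- naive_power_spectrum(fr)
    e <- numeric(n_filters)
    for (i in seq_len(n_filters)) e[i] <- sum(fb[i, ] * P)
    le <- log(pmax(e, .Machine$double.xmin))
    cc <- numeric(n_coeffs)
    for (k in 0:(n_coeffs - 1)) {
      s_k <- 0
      for (j in 0:(n_filters - 1))
        s_k <- s_k + le[j + 1] * cos(pi * k * (j + 0.5) / n_filters)
      cc[k + 1] <- s_k * sqrt(2 / n_filters) * (if (k == 0) 1 / sqrt(2) else 1)
    }
    acc <- acc + cc
  }
  out <- acc / length(starts)
  names(out) <- paste0("mfcc", seq_len(n_coeffs))
  out
}

naive_all_features <- function(sig) {
  c(naive_time_features(sig$samples),
    naive_spectral_quality(sig$samples),
    naive_mfcc(sig$samples, sig$rate))
}

# Brute-force weighted-KNN prediction: explicit standardization, full
# distance sort, explicit class weight sums.
brute_wknn <- function(train, labels, k, query, standardize = TRUE) {
  n <- nrow(train); p <- ncol(train)
  if (standardize) {
    ctr <- numeric(p); scl <- numeric(p)
    for (j in seq_len(p)) {
      ctr[j] <- mean(train[, j]); scl[j] <- sd(train[, j])
      if (scl[j] == 0) scl[j] <- 1
    }
    Z <- train
    for (j in seq_len(p)) Z[, j] <- (train[, j] - ctr[j]) / scl[j]
    q <- (query - ctr) / scl
  } else { Z <- train; q <- query }
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((Z[i, ] - q)^2))
  ord <- order(d, seq_len(n))[seq_len(k)]
  dn <- d[ord]; ln <- labels[ord]
  if (any(dn == 0)) { ln <- ln[dn == 0]; w <- rep(1, length(ln)) } else w <- 1 / dn
  cls <- unique(labels)
  tot <- sapply(cls, function(cl) sum(w[ln == cl]))
  best <- cls[tot == max(tot)]
  ln[ln %in% best][1]
}

spectral_centroid <- function(sig) {
  P <- Mod(stats::fft(sig$samples))^2
  n <- length(P)
  half <- seq_len(floor(n / 2))
  fr <- (half - 1) * sig$rate / n
  sum(fr * P[half]) / sum(P[half])
}

# Hand-written stereo PCM16 WAV (the package only writes mono).
write_stereo_wav <- function(path, left, right, rate) {
  n <- length(left)
  inter <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  data_size <- 4L * n
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(36L + data_size, con, 4, endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 4L), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(as.vector(inter), con, 2, endian = "little")
  invisible(path)
}

# Random test signal: tones plus noise, length n at `rate`.
random_signal <- function(n = 512, rate = 8000) {
  f <- runif(2, 50, 900)
  x <- runif(1, 0.3, 2) * sin(2 * pi * f[1] * (0:(n - 1)) / rate) +
    runif(1, 0.1, 0.8) * sin(2 * pi * f[2] * (0:(n - 1)) / rate + runif(1, 0, 2 * pi)) +
    rnorm(n, sd = runif(1, 0.05, 0.5))
  pcg_signal(x, rate)
}

# Full feature->selection->WKNN pipeline accuracy on one synthetic dataset.
pipeline_holdout_accuracy <- function(n_per_class, seed, k = 10, top_k = 15,
                                      duration = 3) {
  ds <- synth_dataset(n_per_class, duration = duration, seed = seed)
  ft <- extract_feature_table(ds$signals)
  X <- as.matrix(ft[feature_names()])
  sp <- holdout_split(ft$label, 0.8, seed = seed)
  rk <- chi2_rank(X[sp$train, , drop = FALSE], ft$label[sp$train])
  sel <- select_top_k(rk, top_k)
  m <- wknn_fit(X[sp$train, sel, drop = FALSE], ft$label[sp$train], k = k)
  pred <- predict(m, X[sp$validation, sel, drop = FALSE])
  list(accuracy = mean(pred == ft$label[sp$validation]),
       truth = ft$label[sp$validation], pred = pred)
}
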