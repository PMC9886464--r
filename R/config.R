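#' Pipeline configuration
#'
#' A single object carrying every tunable of the end-to-end pipeline, with
#' the toolkit defaults; serializable to human-readable YAML so every run
#' is reproducible from its config file and master seed.
#'
#' @param sample_rate Working sample rate in Hz (default 8000).
#' @param normalize Apply z-score normalization before feature extraction
#'   and scalograms (default TRUE).
#' @param mfcc Named list of MFCC parameters (`n_coeffs`, `frame_len`,
#'   `hop`, `n_filters`, `include_c0`); see [mfcc_features()].
#' @param n_bins Quantile bins for [chi2_rank()] (default 10).
#' @param top_k Features kept by [select_top_k()] (default 15).
#' @param knn_k Neighbour count for [wknn_fit()] (default 10).
#' @param train_fraction Holdout training fraction (default 0.8).
#' @param seed Master seed governing all randomness (default 1).
#' @param duration Synthetic recording length in seconds (default 3).
#' @return A named list with class `pcg_config`.
#' @export
pipeline_config <- function(sample_rate = 8000, normalize = TRUE,
                            mfcc = list(), n_bins = 10, top_k = 15,
                            knn_k = 10, train_fraction = 0.8, seed = 1,
                            duration = 3) {
  cfg <- list(sample_rate = sample_rate, normalize = normalize, mfcc = mfcc,
              n_bins = n_bins, top_k = top_k, knn_k = knn_k,
              train_fraction = train_fraction, seed = seed,
              duration = duration)
  validate_config(cfg)
  structure(cfg, class = "pcg_config")
}

validate_config <- function(cfg) {
  pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!pos(cfg$sample_rate)) abort_validation("sample_rate must be a positive scalar")
  if (!is.logical(cfg$normalize)) abort_validation("normalize must be TRUE/FALSE")
  if (!pos(cfg$n_bins) || cfg$n_bins < 2) abort_validation("n_bins must be >= 2")
  if (!pos(cfg$top_k) || cfg$top_k > 26) abort_validation("top_k must be in 1..26")
  if (!pos(cfg$knn_k)) abort_validation("knn_k must be >= 1")
  if (!pos(cfg$train_fraction) || cfg$train_fraction >= 1)
    abort_validation("train_fraction must be in (0, 1)")
  if (!pos(cfg$duration)) abort_validation("duration must be positive")
  invisible(cfg)
}

#' Read or write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `pcg_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_io("config file does not exist: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A `pcg_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
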