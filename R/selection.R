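# Chi-square filter feature selection: quantile-bin each feature, test
# independence against the class label, score by -ln(p).

#' Rank features by chi-square importance
#'
#' Each continuous feature is discretized into equal-frequency (quantile)
#' bins; a bins x classes contingency table is formed and the chi-square
#' independence statistic computed with df = (bins - 1)(classes - 1). The
#' predictor importance score is `-ln(p)`; p-values are floored at the
#' smallest positive double so scores stay finite. Bin boundaries are
#' type-1 (inverse-ECDF) quantiles, i.e. order statistics, so the ranking
#' depends only on feature ranks and is invariant under strictly monotone
#' transforms.
#'
#' A constant feature carries no association and gets p = 1, score 0.
#'
#' @param features Numeric matrix or data.frame, recordings x features.
#' @param labels Class tag per recording (>= 2 classes present).
#' @param n_bins Number of quantile bins (default 10).
#' @return A `pcg_ranking`: list with `table` (data.frame: feature,
#'   p_value, score), `order` (feature indices by descending score, ties
#'   broken by original column order) and `n_bins`.
#' @export
chi2_rank <- function(features, labels, n_bins = 10) {
  X <- as.matrix(features)
  if (!is.numeric(X)) abort_validation("features must be numeric")
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    abort_validation("features has %d rows but %d labels given", nrow(X), length(labels))
  if (length(unique(labels)) < 2L)
    abort_validation("need >= 2 classes, got %d", length(unique(labels)))

  p_values <- vapply(seq_len(ncol(X)), function(j) {
    chi2_feature_pvalue(X[, j], labels, n_bins)
  }, numeric(1))
  p_values <- pmax(p_values, .Machine$double.xmin)
  scores <- -log(p_values)
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(
    table = data.frame(feature = nm, p_value = p_values, score = scores,
                       stringsAsFactors = FALSE),
    order = order(-scores, seq_along(scores)),
    n_bins = n_bins
  ), class = "pcg_ranking")
}

chi2_feature_pvalue <- function(x, labels, n_bins) {
  if (length(unique(x)) < 2L) return(1)      # constant feature: no association
  # type-1 quantile breaks are order statistics -> rank-based binning
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               type = 1, names = FALSE))
  if (length(br) < 3L) {
    bins <- as.integer(x > br[1L])           # two distinct value groups
  } else {
    bins <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  O <- table(bins, labels)
  O <- O[rowSums(O) > 0, , drop = FALSE]
  if (nrow(O) < 2L) return(1)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' @export
print.pcg_ranking <- function(x, ...) {
  cat(sprintf("<pcg_ranking> %d features, %d quantile bins\n",
              nrow(x$table), x$n_bins))
  print(utils::head(x$table[x$order, ], 10))
  invisible(x)
}

#' Select the top-k features of a ranking
#'
#' @param ranking A `pcg_ranking` from [chi2_rank()].
#' @param k Number of features to keep (default 15). Ties in score are
#'   broken by original feature order (deterministic).
#' @return Integer vector of the k selected feature indices (named by
#'   feature), in descending score order.
#' @export
select_top_k <- function(ranking, k = 15) {
  stopifnot(inherits(ranking, "pcg_ranking"))
  p <- nrow(ranking$table)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p)
    abort_validation("k must be in 1..%d, got %s", p, paste(k, collapse = ","))
  idx <- ranking$order[seq_len(as.integer(k))]
  names(idx) <- ranking$table$feature[idx]
  idx
}

#' Export a feature ranking as CSV
#'
#' Columns: feature, p_value, score, selected flag for the given k.
#'
#' @param ranking A `pcg_ranking`.
#' @param path Output CSV path.
#' @param k Selection size used for the `selected` flag (default 15).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, k = 15) {
  sel <- select_top_k(ranking, k)
  out <- ranking$table
  out$selected <- seq_len(nrow(out)) %in% sel
  out <- out[ranking$order, ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
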