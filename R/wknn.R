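# Distance-weighted k-nearest-neighbour classifier over standardized
# features. Plain KNN majority voting can be flipped by a denser far-away
# class; weighting each neighbour's vote by 1/distance restores the
# influence of close neighbours.

#' Fit a weighted KNN model
#'
#' Stores the training matrix z-scored per feature with training-set
#' statistics (a constant column gets deviation 1 so standardization stays
#' defined). There is no iterative training.
#'
#' @param features Numeric matrix/data.frame, recordings x features.
#' @param labels Class tag per recording (>= 2 classes).
#' @param k Neighbour count (default 10; must not exceed the number of
#'   training recordings).
#' @param standardize Z-score features with training statistics (default
#'   TRUE).
#' @return A `wknn_model`.
#' @export
wknn_fit <- function(features, labels, k = 10, standardize = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  n <- nrow(X)
  if (length(labels) != n)
    abort_validation("features has %d rows but %d labels given", n, length(labels))
  if (length(unique(labels)) < 2L)
    abort_validation("need >= 2 classes in the training data")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    abort_validation("k must be in 1..%d, got %s", n, paste(k, collapse = ","))

  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  structure(list(
    train = Z, labels = labels, k = as.integer(k),
    center = center, scale = scale,
    feature_names = colnames(X), metric = "euclidean"
  ), class = "wknn_model")
}

#' @export
print.wknn_model <- function(x, ...) {
  cat(sprintf("<wknn_model> n = %d, p = %d, k = %d, classes: %s\n",
              nrow(x$train), ncol(x$train), x$k,
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

#' Predict with a weighted KNN model
#'
#' Euclidean distances in the standardized feature space; the k nearest
#' neighbours each vote with weight 1/distance (or weight 1 with
#' `weights = "uniform"`, plain KNN). If any of the k neighbours is at
#' distance exactly 0, classification is by majority among the
#' zero-distance neighbours only. Ties are broken in favour of the class
#' appearing first among the nearest neighbours.
#'
#' @param object A `wknn_model`.
#' @param newdata Feature vector, or matrix with one query per row, in the
#'   model's raw (unstandardized) feature space and dimension.
#' @param type `"label"` (default) for predicted labels, `"shares"` for
#'   the per-class normalized weight shares as a matrix.
#' @param weights `"inverse"` (1/d, default) or `"uniform"`.
#' @param ... Unused.
#' @return Character vector of labels, or a queries x classes share matrix.
#' @export
predict.wknn_model <- function(object, newdata, type = c("label", "shares"),
                               weights = c("inverse", "uniform"), ...) {
  type <- match.arg(type)
  weights <- match.arg(weights)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Xq <- as.matrix(newdata)
  storage.mode(Xq) <- "double"
  if (ncol(Xq) != ncol(object$train))
    abort_validation("query has %d features but model expects %d",
                     ncol(Xq), ncol(object$train))
  Zq <- sweep(sweep(Xq, 2, object$center), 2, object$scale, "/")

  classes <- unique(object$labels)           # stable first-seen order
  shares <- matrix(0, nrow(Zq), length(classes), dimnames = list(NULL, classes))
  lab <- character(nrow(Zq))
  tr <- object$train
  sq_tr <- rowSums(tr^2)
  for (i in seq_len(nrow(Zq))) {
    d2 <- pmax(0, sq_tr - 2 * as.vector(tr %*% Zq[i, ]) + sum(Zq[i, ]^2))
    ord <- order(d2, seq_along(d2))          # ties by training index
    nn <- ord[seq_len(object$k)]
    d <- sqrt(d2[nn])
    nl <- object$labels[nn]
    if (weights == "inverse" && any(d == 0)) {
      nl0 <- nl[d == 0]
      w <- rep(1, length(nl0))
      votes <- vote_sum(nl0, w, classes)
    } else {
      w <- if (weights == "inverse") 1 / d else rep(1, length(d))
      votes <- vote_sum(nl, w, classes)
    }
    shares[i, ] <- votes / sum(votes)
    # argmax with ties broken by first appearance among the neighbours
    best <- max(votes)
    cand <- classes[votes == best]
    lab[i] <- nl[match(TRUE, nl %in% cand)]
  }
  if (type == "label") lab else shares
}

vote_sum <- function(nl, w, classes) {
  v <- stats::setNames(numeric(length(classes)), classes)
  agg <- tapply(w, factor(nl, levels = classes), sum)
  v[names(agg)[!is.na(agg)]] <- agg[!is.na(agg)]
  v
}

#' Stratified holdout split
#'
#' Splits labeled recordings into training and validation sets preserving
#' per-class proportions within one recording, deterministically for a
#' seed. An 80/20 split of 200 recordings per class yields 160/40.
#'
#' @param labels Class tag per recording; every class needs >= 2 members.
#' @param train_fraction Fraction assigned to training (default 0.8); must
#'   leave both sets non-empty in every class.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
holdout_split <- function(labels, train_fraction = 0.8, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    abort_validation("every class needs >= 2 recordings (got %s)",
                     paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    abort_validation("train_fraction must be strictly between 0 and 1")
  train <- integer(0)
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- which(labels == cls)
      n_tr <- round(train_fraction * length(idx))
      if (n_tr < 1L || n_tr >= length(idx))
        abort_validation("train_fraction %.2f leaves class %s without both splits",
                         train_fraction, cls)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Choose k by cross-validated accuracy
#'
#' @param features,labels Training data as in [wknn_fit()].
#' @param ks Candidate neighbour counts (default `c(1, 3, 5, 7, 10, 15)`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `k` (the best candidate; ties go to the smaller k)
#'   and `accuracy` (named vector of CV accuracies).
#' @export
wknn_choose_k <- function(features, labels, ks = c(1, 3, 5, 7, 10, 15),
                          folds = 5, seed = 1) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(X)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  acc <- stats::setNames(numeric(length(ks)), ks)
  for (j in seq_along(ks)) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (ks[j] > sum(tr)) next
      m <- wknn_fit(X[tr, , drop = FALSE], labels[tr], k = ks[j])
      hits <- hits + sum(predict(m, X[!tr, , drop = FALSE]) == labels[!tr])
    }
    acc[j] <- hits / n
  }
  list(k = ks[which.max(acc)], accuracy = acc)
}

#' Serialize a weighted KNN model to a portable JSON file
#'
#' Schema: `k`, `metric`, `center`, `scale`, `labels`, `train` (row-major
#' standardized matrix), `feature_names`, plus free-form `meta` (e.g. the
#' selected feature subset and preprocessing flags).
#'
#' @param model A `wknn_model`.
#' @param path Output path.
#' @param meta Optional named list stored alongside the model.
#' @return `path`, invisibly.
#' @export
save_wknn <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "wknn_model"))
  obj <- list(
    format = "pcgdx-wknn-1",
    k = model$k, metric = model$metric,
    center = model$center, scale = model$scale,
    labels = model$labels,
    feature_names = model$feature_names,
    train = as.vector(t(model$train)),
    n = nrow(model$train), p = ncol(model$train),
    meta = meta
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_wknn
#' @export
load_wknn <- function(path) {
  if (!file.exists(path)) abort_io("model file does not exist: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pcgdx-wknn-1"))
    abort_validation("unrecognized model file format in %s", path)
  m <- structure(list(
    train = matrix(obj$train, nrow = obj$n, ncol = obj$p, byrow = TRUE),
    labels = obj$labels, k = as.integer(obj$k),
    center = obj$center, scale = obj$scale,
    feature_names = obj$feature_names, metric = obj$metric
  ), class = "wknn_model")
  attr(m, "meta") <- obj$meta
  m
}
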