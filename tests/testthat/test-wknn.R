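test_that("model fitting validates inputs and handles degenerate columns", {
  X <- matrix(rnorm(10), 5, 2)
  lab <- c("N", "AS", "N", "AS", "N")
  expect_s3_class(wknn_fit(X, lab, k = 5), "wknn_model")      # k = n boundary
  expect_error(wknn_fit(X, lab, k = 6), class = "pcgdx_validation_error")
  expect_error(wknn_fit(X, rep("N", 5), k = 2), class = "pcgdx_validation_error")
  Xc <- cbind(X, 7)                                           # constant column
  m <- wknn_fit(Xc, lab, k = 3)
  expect_equal(unname(m$scale[3]), 1)
  expect_identical(wknn_fit(X, lab, k = 3), wknn_fit(X, lab, k = 3))
})

test_that("inverse-distance weighting flips the dense-far-class majority vote", {
  # query at the origin; 2 near neighbours of one class at d = 0.5,
  # 3 far neighbours of the other at d = 2.0, k = 5
  X <- rbind(c(0.5, 0), c(0, 0.5), c(2, 0), c(0, 2), c(-2, 0))
  lab <- c("MR", "MR", "AS", "AS", "AS")
  m <- wknn_fit(X, lab, k = 5, standardize = FALSE)
  expect_equal(predict(m, c(0, 0), weights = "uniform"), "AS")  # plain KNN wrong
  expect_equal(predict(m, c(0, 0)), "MR")                       # 1/d vote right
  sh <- predict(m, c(0, 0), type = "shares")
  expect_equal(unname(sh[1, "MR"]), 4 / 5.5, tolerance = 1e-12) # 2/0.5 vs 3/2
  expect_equal(sum(sh), 1)
})

test_that("zero-distance neighbours decide the vote alone", {
  X <- rbind(c(0, 0), c(0.1, 0), c(0.1, 0.1), c(1, 1))
  lab <- c("N", "AS", "AS", "MS")
  m <- wknn_fit(X, lab, k = 4, standardize = FALSE)
  expect_equal(predict(m, c(0, 0)), "N")
  # single training point, k = 1: its label with share 1
  m1 <- wknn_fit(rbind(c(0, 0), c(5, 5)), c("MVP", "N"), k = 1,
                 standardize = FALSE)
  expect_equal(predict(m1, c(1, 1)), "MVP")
  expect_equal(unname(predict(m1, c(1, 1), type = "shares")[1, "MVP"]), 1)
})

test_that("predictions equal the brute-force weighted-vote oracle", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  lab <- sample(c("N", "AS", "MS"), n, replace = TRUE)
  m <- wknn_fit(X, lab, k = 7)
  for (i in 1:50) {
    q <- rnorm(4)
    expect_identical(predict(m, q), brute_wknn(X, lab, 7, q))
  }
})

test_that("predictions are invariant to a global feature rescaling", {
  set.seed(22)
  X <- matrix(rnorm(200), 50, 4)
  lab <- sample(c("N", "MR"), 50, replace = TRUE)
  Q <- matrix(rnorm(40), 10, 4)
  m1 <- wknn_fit(X, lab, k = 5)
  m2 <- wknn_fit(X * 13, lab, k = 5)
  expect_identical(predict(m1, Q), predict(m2, Q * 13))
})

test_that("k = 1 weighted prediction equals the nearest neighbour", {
  set.seed(23)
  X <- matrix(rnorm(120), 30, 4)
  lab <- sample(c("N", "AS", "MVP"), 30, replace = TRUE)
  m <- wknn_fit(X, lab, k = 1)
  for (i in 1:20) {
    q <- rnorm(4)
    z <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
    qz <- (q - m$center) / m$scale
    nn <- which.min(sqrt(rowSums(sweep(z, 2, qz)^2)))
    expect_identical(predict(m, q), lab[nn])
    expect_identical(predict(m, q), predict(m, q, weights = "uniform"))
  }
})

test_that("dimension mismatches are rejected", {
  m <- wknn_fit(matrix(rnorm(20), 10, 2), rep(c("N", "AS"), 5), k = 3)
  expect_error(predict(m, c(1, 2, 3)), class = "pcgdx_validation_error")
})

test_that("stratified holdout preserves class proportions deterministically", {
  lab <- rep(PCG_CLASSES, each = 200)
  sp <- holdout_split(lab, 0.8, seed = 5)
  for (cls in PCG_CLASSES) {
    expect_equal(sum(lab[sp$train] == cls), 160)
    expect_equal(sum(lab[sp$validation] == cls), 40)
  }
  expect_identical(sp, holdout_split(lab, 0.8, seed = 5))
  expect_false(identical(sp$train, holdout_split(lab, 0.8, seed = 6)$train))
  expect_error(holdout_split(lab, 1.0), class = "pcgdx_validation_error")
  expect_error(holdout_split(c("N", "AS", "AS"), 0.5),
               class = "pcgdx_validation_error")
  # odd class sizes: proportions within one recording
  lab2 <- c(rep("N", 7), rep("AS", 9))
  sp2 <- holdout_split(lab2, 0.75, seed = 1)
  expect_equal(sum(lab2[sp2$train] == "N"), round(0.75 * 7))
  expect_equal(sum(lab2[sp2$train] == "AS"), round(0.75 * 9))
})

test_that("cross-validation helper picks an accurate k deterministically", {
  set.seed(31)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 3), 50, 2))
  lab <- rep(c("N", "AS"), each = 50)
  res <- wknn_choose_k(X, lab, ks = c(1, 5, 25), seed = 2)
  expect_true(res$k %in% c(1, 5, 25))
  expect_gte(max(res$accuracy), 0.9)
  expect_identical(res, wknn_choose_k(X, lab, ks = c(1, 5, 25), seed = 2))
})

test_that("models serialize to JSON and predict identically after reload", {
  d <- withr::local_tempdir()
  set.seed(33)
  X <- matrix(rnorm(150), 30, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  lab <- sample(c("N", "MS", "MR"), 30, replace = TRUE)
  m <- wknn_fit(X, lab, k = 4)
  p <- file.path(d, "model.json")
  save_wknn(m, p, meta = list(selected_features = colnames(X)))
  m2 <- load_wknn(p)
  Q <- matrix(rnorm(25), 5, 5)
  expect_identical(predict(m, Q), predict(m2, Q))
  expect_equal(predict(m, Q, type = "shares"), predict(m2, Q, type = "shares"),
               tolerance = 1e-12)
  expect_identical(attr(m2, "meta")$selected_features, colnames(X))
  expect_error(load_wknn(file.path(d, "missing.json")), class = "pcgdx_io_error")
})
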