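test_that("confusion matrix counts true-by-predicted labels", {
  cm <- confusion_matrix(c("AS", "AS", "N"), c("AS", "N", "N"))
  expect_equal(unname(cm["AS", "AS"]), 1L)
  expect_equal(unname(cm["AS", "N"]), 1L)
  expect_equal(unname(cm["N", "N"]), 1L)
  expect_equal(sum(cm), 3L)
  y <- sample(PCG_CLASSES, 30, replace = TRUE)
  expect_true(all(unclass(confusion_matrix(y, y))[upper.tri(diag(5))] == 0))
  expect_error(confusion_matrix(character(0), character(0)),
               class = "pcgdx_validation_error")
  expect_error(confusion_matrix("AS", "XX"), class = "pcgdx_validation_error")
  expect_error(confusion_matrix(c("AS", "N"), "AS"),
               class = "pcgdx_validation_error")
})

test_that("one-vs-rest metrics follow their defining ratios exactly", {
  # AS: TP 40, FN 0, FP 2, TN 158 in a 200-recording validation set
  cm <- matrix(0L, 5, 5, dimnames = list(PCG_CLASSES, PCG_CLASSES))
  diag(cm) <- c(40L, 38L, 40L, 40L, 40L)
  cm["MR", "AS"] <- 2L
  met <- class_metrics(cm, "AS")
  cnt <- attr(met, "counts")
  expect_equal(unname(cnt), c(40, 0, 2, 158))
  expect_equal(unname(met["accuracy"]), 100 * 198 / 200)
  expect_equal(unname(met["sensitivity"]), 100)
  expect_equal(unname(met["specificity"]), 100 * 158 / 160)
  expect_equal(unname(met["f1"]),
               f1_spec_sens(100, 100 * 158 / 160))
  # consistency identity: accuracy * total == TP + TN in integers
  expect_equal(met[["accuracy"]] / 100 * sum(cm), cnt[["TP"]] + cnt[["TN"]])
  # perfect matrix
  perfect <- diag(c(40L, 40L, 40L, 40L, 40L))
  dimnames(perfect) <- list(PCG_CLASSES, PCG_CLASSES)
  for (cl in PCG_CLASSES)
    expect_equal(unname(class_metrics(perfect, cl)), rep(100, 4),
                 ignore_attr = TRUE)
})

test_that("the published per-class F1 values follow from sensitivity and specificity", {
  sens_a <- c(AS = 100.00, MR = 97.50, MS = 100.00, MVP = 90.00, N = 100.00)
  spec_a <- c(AS = 98.75, MR = 99.38, MS = 99.38, MVP = 99.38, N = 100.00)
  f1_a   <- c(AS = 99.37, MR = 98.43, MS = 99.69, MVP = 94.46, N = 100.00)
  sens_b <- c(AS = 95.00, MR = 77.50, MS = 85.00, MVP = 87.50, N = 100.00)
  spec_b <- c(AS = 99.38, MR = 95.00, MS = 97.50, MVP = 95.00, N = 99.38)
  f1_b   <- c(AS = 97.14, MR = 85.36, MS = 90.82, MVP = 91.10, N = 99.69)
  for (cl in PCG_CLASSES) {
    expect_equal(unname(pcgdx:::round_half_up(f1_spec_sens(sens_a[cl], spec_a[cl]), 2)),
                 unname(f1_a[cl]))
    expect_equal(unname(pcgdx:::round_half_up(f1_spec_sens(sens_b[cl], spec_b[cl]), 2)),
                 unname(f1_b[cl]))
  }
})

test_that("macro averages over the four disease classes match the published means", {
  mk <- function(a, se, sp, f) c(accuracy = a, sensitivity = se,
                                 specificity = sp, f1 = f)
  model_a <- list(AS  = mk(99.00, 100.00, 98.75, 99.37),
                  MR  = mk(99.00, 97.50, 99.38, 98.43),
                  MS  = mk(99.50, 100.00, 99.38, 99.69),
                  MVP = mk(97.50, 90.00, 99.38, 94.46))
  avg_a <- pcgdx:::round_half_up(macro_average(model_a), 2)
  expect_equal(unname(avg_a), c(98.75, 96.88, 99.22, 97.99))
  model_b <- list(AS  = mk(98.50, 95.00, 99.38, 97.14),
                  MR  = mk(91.50, 77.50, 95.00, 85.36),
                  MS  = mk(95.00, 85.00, 97.50, 90.82),
                  MVP = mk(93.50, 87.50, 95.00, 91.10))
  avg_b <- pcgdx:::round_half_up(macro_average(model_b), 2)
  expect_equal(unname(avg_b), c(94.63, 86.25, 96.72, 91.11))
  # mean of four identical sets is that set
  same <- list(AS = mk(90, 80, 95, 86.9), MR = mk(90, 80, 95, 86.9),
               MS = mk(90, 80, 95, 86.9), MVP = mk(90, 80, 95, 86.9))
  expect_equal(unname(macro_average(same)), c(90, 80, 95, 86.9))
  expect_error(macro_average(same[1:3]), class = "pcgdx_validation_error")
})

test_that("field-evaluation accuracies follow from the recorded counts", {
  # 18 recordings: 6 normal (5 correct), 12 diseased (11 correct)
  y_true <- c(rep("N", 6), rep("D", 12))
  y_pred <- c(rep("N", 5), "D", rep("D", 11), "N")
  cm <- confusion_matrix(y_true, y_pred, classes = c("N", "D"))
  overall <- 100 * sum(diag(unclass(cm))) / sum(cm)
  expect_equal(pcgdx:::round_half_up(overall, 2), 88.89)
  expect_equal(pcgdx:::round_half_up(class_metrics(cm, "N")[["sensitivity"]], 2),
               83.33)
  expect_equal(pcgdx:::round_half_up(class_metrics(cm, "D")[["sensitivity"]], 2),
               91.67)
})

test_that("metric edge cases: undefined flags, bounds, F1 conventions", {
  cm <- matrix(0L, 2, 2, dimnames = list(c("AS", "N"), c("AS", "N")))
  cm["AS", "AS"] <- 5L                         # no negatives at all
  met <- class_metrics(cm, "AS")
  expect_true(is.na(met["specificity"]))
  expect_true("specificity" %in% attr(met, "undefined"))
  expect_error(class_metrics(cm, "N"), class = "pcgdx_validation_error")

  set.seed(12)
  y <- sample(PCG_CLASSES, 100, replace = TRUE)
  p <- sample(PCG_CLASSES, 100, replace = TRUE)
  cm2 <- confusion_matrix(y, p)
  for (cl in PCG_CLASSES) {
    m <- class_metrics(cm2, cl)
    expect_true(all(m >= 0 & m <= 100, na.rm = TRUE))
    lo <- min(m["sensitivity"], m["specificity"])
    hi <- max(m["sensitivity"], m["specificity"])
    expect_gte(m[["f1"]] + 1e-9, lo)
    expect_lte(m[["f1"]] - 1e-9, hi)
    cnt <- attr(m, "counts")
    expect_equal(m[["accuracy"]] / 100 * sum(cm2), cnt[["TP"]] + cnt[["TN"]])
  }
  # f1 equals sensitivity when sensitivity == specificity
  expect_equal(f1_spec_sens(87.5, 87.5), 87.5)
  # the precision-recall F1 is a different quantity
  expect_false(isTRUE(all.equal(f1_precision_recall(cm2, "AS"),
                                class_metrics(cm2, "AS")[["f1"]])))
})

test_that("published sensitivity/specificity pairs are integer-realizable at 40 per class", {
  tab <- rbind(
    c(100.00, 98.75), c(97.50, 99.38), c(100.00, 99.38), c(90.00, 99.38),
    c(100.00, 100.00),
    c(95.00, 99.38), c(77.50, 95.00), c(85.00, 97.50), c(87.50, 95.00),
    c(100.00, 99.38))
  for (r in seq_len(nrow(tab))) {
    cnt <- ovr_counts(tab[r, 1], tab[r, 2], n_pos = 40, n_neg = 160)
    expect_false(is.null(cnt))
    expect_equal(sum(cnt), 200)
  }
  # AS column of the first model: accuracy follows from the counts
  cnt <- ovr_counts(100.00, 98.75, 40, 160)
  expect_equal(unname(cnt), c(40, 0, 2, 158))
  expect_equal(100 * (cnt[["TP"]] + cnt[["TN"]]) / 200, 99.00)
  # an impossible pair is reported as such
  expect_null(ovr_counts(99.99, 50, 40, 160))
})

test_that("metrics_table renders all five classes at two decimals", {
  set.seed(13)
  y <- rep(PCG_CLASSES, each = 20)
  p <- ifelse(stats::runif(100) < 0.9, y, sample(PCG_CLASSES, 100, TRUE))
  tab <- metrics_table(confusion_matrix(y, p))
  expect_equal(dim(tab), c(4, 5))
  expect_identical(names(tab), PCG_CLASSES)
  expect_true(all(tab == round(tab, 2)))
})
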