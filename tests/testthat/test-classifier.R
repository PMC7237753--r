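# SVM classification: LOOCV evaluation, forward selection,
# sensitivity/specificity, ROC/AUC.

makeSeparated <- function(n = 12L, gap = 10, seed = 61) {
  set.seed(seed)
  X <- cbind(sep = c(rnorm(n), rnorm(n) + gap),
             noise = rnorm(2 * n))
  rownames(X) <- sprintf("s%02d", seq_len(2 * n))
  list(X = X, labels = rep(c("neg", "pos"), each = n))
}

test_that("sensitivity and specificity follow their definitions", {
  expect_equal(sensitivitySpecificity(c("p", "p", "n", "n"),
                                      c("p", "p", "n", "n"), "p"),
               c(sensitivity = 1, specificity = 1))
  # TP=3, FN=1, TN=4, FP=0
  pred <- c(rep("p", 3), "n", rep("n", 4))
  truth <- c(rep("p", 4), rep("n", 4))
  expect_equal(sensitivitySpecificity(pred, truth, "p"),
               c(sensitivity = 0.75, specificity = 1))
  # inverted predictions
  expect_equal(sensitivitySpecificity(truth[c(5:8, 1:4)], truth, "p"),
               c(sensitivity = 0, specificity = 0))
  expect_error(sensitivitySpecificity(rep("p", 3), rep("p", 3), "p"),
               "both classes")
})

test_that("ROC/AUC handles separation, ties, and hand-counted cases", {
  r1 <- rocAuc(c(2, 3, 0, 1), c("p", "p", "n", "n"), "p")
  expect_equal(r1$auc, 1)
  # concordant pairs 3 of 4
  expect_equal(rocAuc(c(1, 3, 0, 2), c("p", "p", "n", "n"), "p")$auc, 0.75)
  # all tied scores: midrank convention gives 0.5
  expect_equal(rocAuc(rep(1, 6), rep(c("p", "n"), 3), "p")$auc, 0.5)

  # curve anatomy
  roc <- r1$roc
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))

  expect_error(rocAuc(1:3, rep("p", 3), "p"), "absent")
})

test_that("AUC equals brute-force pair concordance and is invariant to
           monotone transforms", {
  set.seed(62)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    labels <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    scores <- sample(seq_len(6), n, replace = TRUE)  # integer ties likely
    a <- rocAuc(scores, labels, "p")$auc
    expect_equal(a, bruteAUC(scores, labels, "p"), tolerance = 1e-12)
    # strictly monotone transforms leave AUC unchanged
    expect_equal(rocAuc(exp(scores / 2), labels, "p")$auc, a,
                 tolerance = 1e-12)
    expect_equal(rocAuc(3 * scores - 7, labels, "p")$auc, a,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  for (rep in 1:5) {
    scores <- rnorm(30)
    labels <- sample(c("p", "n"), 30, replace = TRUE, prob = c(0.4, 0.6))
    ours <- rocAuc(scores, labels, "p")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          levels = c("n", "p"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("LOOCV separates a wide-margin problem and is order-invariant", {
  d <- makeSeparated()
  ev <- loocvEvaluate(d$X, d$labels, "sep", positive = "pos")
  expect_equal(ev$predictions, d$labels)
  expect_equal(balancedAccuracy <- mean(
    sensitivitySpecificity(ev$predictions, d$labels, "pos")), 1)
  expect_equal(rocAuc(ev$scores, d$labels, "pos")$auc, 1)

  # shuffling specimen order changes no per-specimen prediction
  set.seed(64)
  perm <- sample(nrow(d$X))
  evP <- loocvEvaluate(d$X[perm, ], d$labels[perm], "sep",
                       positive = "pos")
  expect_equal(evP$predictions[order(perm)], ev$predictions)
  expect_equal(evP$scores[order(perm)], ev$scores, tolerance = 1e-8)

  # a class reduced to one specimen cannot be cross-validated
  expect_error(loocvEvaluate(d$X[c(1, 13:24), ],
                             d$labels[c(1, 13:24)], "sep",
                             positive = "pos"), "degenerate")
})

test_that("label-permuted LOOCV accuracy sits at chance", {
  set.seed(65)
  n <- 11L
  X <- cbind(f1 = rnorm(2 * n), f2 = rnorm(2 * n))
  acc <- replicate(20, {
    labs <- sample(rep(c("a", "b"), each = n))
    ev <- loocvEvaluate(X, labs, c("f1", "f2"), positive = "a")
    mean(ev$predictions == labs)
  })
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("forward selection adds only informative, non-redundant
           features with a non-decreasing criterion", {
  d <- makeSeparated()
  X <- cbind(d$X, dup = d$X[, "sep"])
  pv <- c(sep = 1e-6, noise = 0.4, dup = 1e-5)

  # informative single candidate beats the majority baseline
  fs1 <- forwardSelect(X, d$labels, "sep", positive = "pos", pvalues = pv)
  expect_equal(fs1$selected, "sep")

  # uninformative single candidate is not selected
  fs0 <- forwardSelect(X, d$labels, "noise", positive = "pos",
                       pvalues = pv)
  expect_length(fs0$selected, 0L)

  # a duplicate of a selected feature is never added
  fs2 <- forwardSelect(X, d$labels, c("sep", "dup", "noise"),
                       positive = "pos", pvalues = pv, mode = "joint")
  expect_false(all(c("sep", "dup") %in% fs2$selected))

  # the selection criterion is non-decreasing along the trace
  sizes <- c(a = 14L, b = 14L)
  set.seed(66)
  Xm <- cbind(f1 = c(rnorm(14), rnorm(14) + 1.2),
              f2 = c(rnorm(14), rnorm(14) + 1.0),
              f3 = rnorm(28))
  fs3 <- forwardSelect(Xm, rep(c("a", "b"), each = 14), colnames(Xm),
                       positive = "b", mode = "joint")
  if (nrow(fs3$trace) > 1L)
    expect_false(is.unsorted(fs3$trace$criterion))

  expect_error(forwardSelect(X, d$labels, character(), positive = "pos"),
               "nonempty")
})

test_that("task runner respects the wavelength window and yields chance
           AUC on identical classes", {
  # small fabricated cohort: signal only in 385-405 nm lifetimes
  sizes <- c(esophagus_normal = 10L, duodenum = 10L)
  lt <- fakeLifetimeTable(sizes, seed = 67)
  sel <- lt$tissue_class == "duodenum" &
    lt$wavelength_nm %in% c(385, 395, 405)
  lt$tau_avg_ns[sel] <- lt$tau_avg_ns[sel] + 0.5
  ft <- buildFeatureTable(lt)

  ev <- runTask(ft, taskSpec("duodenum", "esophagus_normal",
                             window = c(375, 425)))
  wlSel <- as.numeric(sub("^[a-z]+_", "", selectedFeatures(ev)))
  expect_true(all(wlSel >= 375 & wlSel <= 425))
  expect_gt(ev@auc, 0.9)
  # signal concentrated where it was injected
  lifeSel <- selectedFeatures(ev)[grepl("^lifetime_", selectedFeatures(ev))]
  expect_true(all(as.numeric(sub("lifetime_", "", lifeSel)) %in%
                    c(385, 395, 405)))

  # no-signal path: when the screening gate retains nothing, the task
  # reports the null model (majority predictions, AUC exactly 0.5)
  lt0 <- fakeLifetimeTable(sizes, seed = 210)
  ft0 <- buildFeatureTable(lt0)
  ev0 <- suppressMessages(runTask(ft0, taskSpec("duodenum",
                                                "esophagus_normal",
                                                alphaSig = 1e-8)))
  expect_length(selectedFeatures(ev0), 0L)
  expect_equal(ev0@auc, 0.5)
  expect_equal(length(unique(ev0@predictions)), 1L)
})
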