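## Binary SVM classification with forward feature selection, LOOCV
## evaluation, and sensitivity/specificity + ROC/AUC reporting.

#' Sensitivity and specificity of hard predictions
#'
#' `sens = TP/(TP+FN)`, `spec = TN/(TN+FP)` for the designated positive
#' class.
#'
#' @param predictions character vector of predicted labels.
#' @param labels character vector of true labels.
#' @param positive the positive class name.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' sensitivitySpecificity(c("a", "a", "b"), c("a", "b", "b"), "a")
#' @export
sensitivitySpecificity <- function(predictions, labels, positive) {
  stopifnot(length(predictions) == length(labels))
  isPos <- labels == positive
  if (!any(isPos) || all(isPos))
    stop("both classes must be present in the labels")
  tp <- sum(predictions == positive & isPos)
  fn <- sum(predictions != positive & isPos)
  tn <- sum(predictions != positive & !isPos)
  fp <- sum(predictions == positive & !isPos)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

balancedAccuracy <- function(predictions, labels, positive) {
  ss <- sensitivitySpecificity(predictions, labels, positive)
  mean(ss)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the pooled decision scores (predict positive
#' when score >= threshold); tied scores contribute a single diagonal step
#' so that the trapezoidal AUC equals the midrank (Mann-Whitney)
#' statistic U / (n_pos * n_neg).
#'
#' @param scores numeric decision scores, larger favouring the positive
#'   class.
#' @param labels true labels.
#' @param positive positive class name.
#' @return List with `roc` (data.frame of `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' rocAuc(c(2, 3, 0, 1), c("p", "p", "n", "n"), "p")$auc
#' @export
rocAuc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite")
  isPos <- labels == positive
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC undefined: one class is absent")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & isPos),
                     numeric(1)) / nPos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !isPos),
                     numeric(1)) / nNeg)
  aucVal <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = aucVal)
}

## Fit a linear SVM on (X, y) and return signed decision scores for
## newdata, positive scores favouring `positive`.
svmDecision <- function(X, y, newX, positive, negative, cost = 1,
                        classWeights = TRUE) {
  yf <- factor(y, levels = c(positive, negative))
  w <- if (classWeights) {
    tab <- table(yf)
    ww <- length(yf) / (2 * tab)
    stats::setNames(as.numeric(ww), names(tab))
  } else NULL
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                    class.weights = w, scale = FALSE)
  pr <- predict(fit, newX, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1])
  # e1071 signs decision values toward the first label of the pair name
  if (!startsWith(colnames(dv)[1], positive)) score <- -score
  list(predictions = as.character(pr), scores = score)
}

#' Leave-one-out cross-validated SVM predictions
#'
#' For each specimen, trains a linear SVM (cost `cost`, classes weighted
#' inversely to their training-fold frequencies) on all other specimens
#' using only the given feature subset, with features z-scored by
#' training-fold mean and SD (held-out specimen transformed by the same
#' statistics — no leakage), and records the held-out hard prediction and
#' signed decision score (positive favouring the positive class).
#' Deterministic.
#'
#' @param X specimens x features numeric matrix (or feature table from
#'   [buildFeatureTable()]).
#' @param labels per-specimen labels.
#' @param features character vector of feature (column) names to use.
#' @param positive positive class name; default the first label level.
#' @param cost SVM regularization parameter; default 1.
#' @param classWeights weight classes inversely to training-fold
#'   frequency; default TRUE.
#' @return List with `predictions` (character) and `scores` (numeric),
#'   one entry per specimen.
#' @export
loocvEvaluate <- function(X, labels, features, positive = NULL, cost = 1,
                          classWeights = TRUE) {
  if (!is.matrix(X)) X <- featureMatrix(X)
  labels <- as.character(labels)
  if (!length(features)) stop("feature subset must be nonempty")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes are required")
  if (is.null(positive)) positive <- classes[1]
  negative <- setdiff(classes, positive)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("degenerate LOOCV fold: class '",
         names(counts)[which.min(counts)],
         "' has fewer than 2 specimens, so a training fold would lose it")
  n <- nrow(X)
  Xs <- X[, features, drop = FALSE]
  preds <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- Xs[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, sd)
    sdv[sdv == 0] <- 1
    trZ <- sweep(sweep(tr, 2, mu), 2, sdv, `/`)
    teZ <- matrix((Xs[i, ] - mu) / sdv, nrow = 1,
                  dimnames = list(NULL, features))
    out <- svmDecision(trZ, labels[-i], teZ, positive, negative, cost,
                       classWeights)
    preds[i] <- out$predictions
    scores[i] <- out$scores
  }
  list(predictions = preds, scores = scores)
}

featureCatalog <- function(features) {
  ifelse(grepl("^intensity_", features), "intensity",
         ifelse(grepl("^lifetime_", features), "lifetime", "other"))
}

#' Greedy forward feature selection wrapped around the LOOCV SVM
#'
#' At each step, adds the candidate feature maximizing the LOOCV balanced
#' accuracy of the augmented subset; stops at the first step with no
#' strict improvement or when `maxFeatures` features are selected. Ties
#' are broken by smaller screening p-value, then by feature-table column
#' order (kind, then wavelength). By default selection runs independently
#' within the intensity catalog and the lifetime catalog and the final
#' subset is the union (`mode = "per-catalog"`, mirroring per-catalog
#' reporting of spectral and lifetime features); `mode = "joint"` selects
#' over all candidates at once. The empty-subset baseline is the
#' majority-class balanced accuracy, 0.5. Fully deterministic.
#'
#' @inheritParams loocvEvaluate
#' @param candidates character vector of candidate feature names
#'   (post-screening).
#' @param pvalues optional named screening p-values used for tie-breaking.
#' @param maxFeatures cap on selected features per catalog; default 6.
#' @param mode `"per-catalog"` (default) or `"joint"`.
#' @return List with `selected` (character, in selection order) and
#'   `trace` (data.frame: catalog, feature, criterion after adding).
#' @export
forwardSelect <- function(X, labels, candidates, positive = NULL,
                          pvalues = NULL, maxFeatures = 6L, cost = 1,
                          classWeights = TRUE,
                          mode = c("per-catalog", "joint")) {
  mode <- match.arg(mode)
  if (!is.matrix(X)) X <- featureMatrix(X)
  if (!length(candidates)) stop("candidate set must be nonempty")
  if (maxFeatures < 1L) stop("maxFeatures must be >= 1")
  labels <- as.character(labels)
  if (is.null(positive)) positive <- unique(labels)[1]
  # deterministic candidate order: feature-table column order
  candidates <- candidates[order(match(candidates, colnames(X)))]
  catalogs <- if (mode == "per-catalog") {
    split(candidates, factor(featureCatalog(candidates),
                             levels = c("intensity", "lifetime", "other")))
  } else list(all = candidates)
  catalogs <- Filter(length, catalogs)

  selectWithin <- function(cand, catalogName) {
    selected <- character()
    crit <- 0.5                      # majority-class balanced accuracy
    trace <- list()
    while (length(selected) < maxFeatures && length(cand)) {
      best <- NULL
      for (f in cand) {
        ev <- loocvEvaluate(X, labels, c(selected, f), positive, cost,
                            classWeights)
        ba <- balancedAccuracy(ev$predictions, labels, positive)
        better <- is.null(best) || ba > best$ba + 1e-12 ||
          (abs(ba - best$ba) <= 1e-12 && !is.null(pvalues) &&
             isTRUE(pvalues[f] < pvalues[best$f]))
        if (better) best <- list(f = f, ba = ba)
      }
      if (best$ba <= crit + 1e-12) break
      selected <- c(selected, best$f)
      cand <- setdiff(cand, best$f)
      crit <- best$ba
      trace[[length(trace) + 1L]] <-
        data.frame(catalog = catalogName, feature = best$f,
                   criterion = best$ba, stringsAsFactors = FALSE)
    }
    list(selected = selected,
         trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(catalog = character(), feature = character(),
                      criterion = numeric(), stringsAsFactors = FALSE))
  }

  res <- Map(selectWithin, catalogs, names(catalogs))
  list(selected = unlist(lapply(res, `[[`, "selected"), use.names = FALSE),
       trace = do.call(rbind, c(lapply(res, `[[`, "trace"),
                                make.row.names = FALSE)))
}
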