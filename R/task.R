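## Pairwise tissue-classification tasks: screening -> forward selection
## -> LOOCV -> sensitivity/specificity -> ROC/AUC.

#' Specify a pairwise tissue-classification task
#'
#' @param positive,negative tissue-class names (must differ).
#' @param window optional length-2 numeric wavelength window (nm); when
#'   set, only features whose wavelength lies inside it are considered.
#' @param maxFeatures forward-selection cap per catalog; default 6.
#' @param cost SVM regularization; default 1.
#' @param alphaSig ANOVA significance threshold; default 0.05.
#' @param rThreshold correlation redundancy threshold; default 0.5.
#' @param selectionMode `"per-catalog"` or `"joint"` forward selection.
#' @return Validated task list.
#' @export
taskSpec <- function(positive, negative, window = NULL, maxFeatures = 6L,
                     cost = 1, alphaSig = 0.05, rThreshold = 0.5,
                     selectionMode = c("per-catalog", "joint")) {
  if (identical(positive, negative))
    stop("positive and negative classes must differ")
  if (!is.null(window) &&
      (length(window) != 2L || window[1] > window[2]))
    stop("window must be an increasing length-2 wavelength range")
  if (alphaSig <= 0 || alphaSig >= 1)
    stop("alphaSig must lie strictly in (0, 1)")
  if (rThreshold < 0 || rThreshold > 1)
    stop("rThreshold must lie in [0, 1]")
  list(positive = positive, negative = negative, window = window,
       maxFeatures = as.integer(maxFeatures), cost = cost,
       alphaSig = alphaSig, rThreshold = rThreshold,
       selectionMode = match.arg(selectionMode))
}

#' Default pairwise tasks of the synthetic study
#'
#' The four comparisons against normal esophagus: duodenum, stomach body,
#' antrum, and esophagitis (the latter restricted to the short-wavelength
#' 375-425 nm window).
#'
#' @return Named list of [taskSpec()] objects.
#' @export
defaultTasks <- function() {
  list(
    duodenum_vs_esophagus     = taskSpec("duodenum", "esophagus_normal"),
    stomach_body_vs_esophagus = taskSpec("stomach_body", "esophagus_normal"),
    antrum_vs_esophagus       = taskSpec("antrum", "esophagus_normal"),
    esophagitis_vs_esophagus  = taskSpec("esophagitis", "esophagus_normal",
                                         window = c(375, 425))
  )
}

#' Run one pairwise classification task end to end
#'
#' Restricts the feature table to the task's two classes (and wavelength
#' window, if any), screens features (ANOVA then correlation
#' de-duplication), forward-selects within each feature catalog, and
#' evaluates the selected union by LOOCV, reporting sensitivity,
#' specificity and the pooled-score ROC/AUC. If screening retains no
#' significant feature, or forward selection keeps none, the task
#' reports a no-signal null model — majority-class predictions with
#' all-zero decision scores, hence AUC 0.5 under the midrank convention —
#' rather than evaluating a feature that failed its own significance
#' gate (logged via `message()`).
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param task a [taskSpec()].
#' @return A [ClassifierEvaluation-class].
#' @export
runTask <- function(ft, task) {
  labels <- featureLabels(ft)
  keep <- labels %in% c(task$positive, task$negative)
  if (sum(labels == task$positive) < 2L ||
      sum(labels == task$negative) < 2L)
    stop("both task classes need >= 2 specimens in the feature table")
  sub <- ft[, keep]
  labs <- featureLabels(sub)
  if (!is.null(task$window)) {
    wl <- rowData(sub)$wavelength
    sub <- sub[wl >= task$window[1] & wl <= task$window[2], ]
  }
  screening <- screenFeatures(sub, labs, task$alphaSig, task$rThreshold)
  candidates <- retainedFeatures(screening)
  X <- featureMatrix(sub)
  emptyTrace <- data.frame(catalog = character(), feature = character(),
                           criterion = numeric(), stringsAsFactors = FALSE)
  if (length(candidates)) {
    fs <- forwardSelect(X, labs, candidates, positive = task$positive,
                        pvalues = featurePValues(screening),
                        maxFeatures = task$maxFeatures, cost = task$cost,
                        mode = task$selectionMode)
    selected <- fs$selected
    trace <- fs$trace
  } else {
    message("screening retained no significant feature for ",
            task$positive, " vs ", task$negative)
    selected <- character()
    trace <- emptyTrace
  }
  if (length(selected)) {
    ev <- loocvEvaluate(X, labs, selected, positive = task$positive,
                        cost = task$cost)
  } else {
    # no-signal null model: majority class, uninformative scores
    message("no feature selected for ", task$positive, " vs ",
            task$negative, "; reporting the no-signal null model")
    majority <- names(which.max(table(labs)))
    ev <- list(predictions = rep(majority, length(labs)),
               scores = numeric(length(labs)))
  }
  ss <- sensitivitySpecificity(ev$predictions, labs, task$positive)
  ra <- rocAuc(ev$scores, labs, task$positive)
  new("ClassifierEvaluation", task = task, selected = selected,
      trace = trace, predictions = ev$predictions, scores = ev$scores,
      labels = labs, sensitivity = unname(ss["sensitivity"]),
      specificity = unname(ss["specificity"]), roc = ra$roc,
      auc = ra$auc, screening = screening)
}
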