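## Feature construction and two-stage screening (one-way ANOVA
## significance, then Pearson-correlation de-duplication).

featureName <- function(kind, wavelength) paste0(kind, "_", wavelength)

#' Build the per-wavelength feature table
#'
#' Assembles the specimens x features table from per-wavelength lifetime
#' results: 37 normalized-intensity features and 37 lifetime features on
#' the 370-550 nm (5 nm) grid, intensity vectors divided by their own
#' per-specimen maximum, lifetime columns left in ns. Column order is
#' fixed: intensities by ascending wavelength, then lifetimes by ascending
#' wavelength. Specimens missing any required wavelength (unfittable or
#' absent) are excluded with a warning naming them; an error is raised if
#' no specimen survives.
#'
#' @param lifetimeTable long data.frame as produced by [processCohort()]
#'   (columns `specimen_id`, `tissue_class`, `wavelength_nm`,
#'   `tau_avg_ns`, `intensity`, `flag`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with features as
#'   rows (rowData columns `kind`, `wavelength`) and specimens as columns
#'   (colData columns `specimen_id`, `tissue_class`).
#' @export
buildFeatureTable <- function(lifetimeTable) {
  wl <- featureWavelengths()
  keep <- lifetimeTable$wavelength_nm %in% wl
  lt <- lifetimeTable[keep, , drop = FALSE]
  ids <- unique(lt$specimen_id)
  rows <- list()
  excluded <- character()
  for (sid in ids) {
    s <- lt[lt$specimen_id == sid, , drop = FALSE]
    s <- s[match(wl, s$wavelength_nm), , drop = FALSE]
    ok <- !is.na(s$tau_avg_ns) & !is.na(s$intensity) &
      (!("flag" %in% names(s)) | s$flag == "ok")
    if (any(!ok) || anyNA(s$wavelength_nm)) {
      excluded <- c(excluded, sid)
      next
    }
    rows[[sid]] <- list(tissue_class = s$tissue_class[1],
                        intensity = s$intensity / max(s$intensity),
                        lifetime = s$tau_avg_ns)
  }
  if (length(excluded))
    warning("excluded ", length(excluded),
            " specimen(s) with unfittable or missing wavelengths: ",
            paste(excluded, collapse = ", "))
  if (!length(rows))
    stop("no specimen has a complete set of fittable wavelengths")
  featNames <- c(featureName("intensity", wl), featureName("lifetime", wl))
  mat <- vapply(rows, function(r) c(r$intensity, r$lifetime),
                numeric(2 * length(wl)))
  rownames(mat) <- featNames
  rowInfo <- DataFrame(kind = rep(c("intensity", "lifetime"),
                                  each = length(wl)),
                       wavelength = rep(wl, 2), row.names = featNames)
  colInfo <- DataFrame(specimen_id = names(rows),
                       tissue_class = vapply(rows, `[[`, character(1),
                                             "tissue_class"),
                       row.names = names(rows))
  se <- SummarizedExperiment(assays = list(features = mat),
                             rowData = rowInfo, colData = colInfo)
  metadata(se)$excluded_specimens <- excluded
  se
}

#' Specimens-by-features matrix of a feature table
#'
#' @param ft feature table from [buildFeatureTable()].
#' @return Numeric matrix, specimens in rows, features in columns.
#' @export
featureMatrix <- function(ft) t(assay(ft, "features"))

#' Tissue-class labels of a feature table
#'
#' @inheritParams featureMatrix
#' @return Character vector of per-specimen labels.
#' @export
featureLabels <- function(ft) as.character(colData(ft)$tissue_class)

#' Pearson correlation with explicit degeneracy handling
#'
#' Sample Pearson correlation of two equal-length vectors. Constant input
#' raises an error of class `trflab_undefined_correlation`; the screening
#' caller treats that case as r = 0 and logs it.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' pearsonCor(c(1, 2, 3), c(2, 4, 6))
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop(errorCondition("correlation undefined for constant input",
                        class = c("trflab_undefined_correlation", "error",
                                  "condition")))
  cor(x, y, method = "pearson")
}

#' One-way ANOVA feature filter
#'
#' Per-feature one-way fixed-effects ANOVA of the feature values across
#' tissue groups; the significant set is every feature with p <
#' `alphaSig`. Features constant across all specimens (no within- or
#' between-group variance) are defined as not significant (p = 1) so
#' screening never aborts on degenerate input.
#'
#' @param ft feature table from [buildFeatureTable()], or a plain
#'   specimens x features numeric matrix.
#' @param labels group labels, one per specimen; defaults to the feature
#'   table's tissue classes.
#' @param alphaSig significance threshold; default 0.05.
#' @return List with `pvalues` (named numeric) and `significant`
#'   (character vector of feature names with p < alphaSig).
#' @export
anovaFilter <- function(ft, labels = NULL, alphaSig = 0.05) {
  X <- if (is.matrix(ft)) ft else featureMatrix(ft)
  if (is.null(labels)) {
    if (is.matrix(ft)) stop("labels are required with a plain matrix")
    labels <- featureLabels(ft)
  }
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 specimens: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  pv <- apply(X, 2, function(x) {
    if (diff(range(x)) == 0) return(1)
    a <- stats::anova(stats::lm(x ~ g))
    p <- a$`Pr(>F)`[1]
    if (is.na(p)) {
      # zero residual variance: perfectly separated unless between-group
      # variance is also zero
      msb <- a$`Mean Sq`[1]
      p <- if (is.finite(msb) && msb > 0) 0 else 1
    }
    p
  })
  names(pv) <- colnames(X)
  list(pvalues = pv, significant = names(pv)[pv < alphaSig])
}

#' Correlation-based de-duplication of significant features
#'
#' Greedy pass over the significant features sorted by ascending ANOVA
#' p-value (ties broken by feature-table column order, i.e. kind then
#' wavelength): a feature is retained unless its absolute Pearson
#' correlation with an already-retained feature reaches `rThreshold`, in
#' which case the smaller-p representative already retained stands for it.
#' Anticorrelated features are treated as equally redundant (absolute
#' value). Deterministic.
#'
#' @inheritParams anovaFilter
#' @param significant character vector of significant feature names.
#' @param pvalues named numeric p-values covering `significant`.
#' @param rThreshold absolute-correlation redundancy threshold; default
#'   0.5.
#' @return Character vector of retained feature names.
#' @export
correlationDedup <- function(ft, significant, pvalues, rThreshold = 0.5) {
  if (!length(significant)) stop("significant set must be nonempty")
  X <- if (is.matrix(ft)) ft else featureMatrix(ft)
  ord <- order(pvalues[significant],
               match(significant, colnames(X)))
  cand <- significant[ord]
  retained <- character()
  for (f in cand) {
    redundant <- FALSE
    for (r in retained) {
      rv <- tryCatch(pearsonCor(X[, f], X[, r]),
                     trflab_undefined_correlation = function(e) {
                       message("constant feature in correlation check (",
                               f, " vs ", r, "); treating r as 0")
                       0
                     })
      if (abs(rv) >= rThreshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, f)
  }
  retained
}

#' Two-stage feature screening
#'
#' Runs [anovaFilter()] then [correlationDedup()] and packages the result.
#'
#' @inheritParams anovaFilter
#' @inheritParams correlationDedup
#' @return A [ScreeningResult-class].
#' @export
screenFeatures <- function(ft, labels = NULL, alphaSig = 0.05,
                           rThreshold = 0.5) {
  av <- anovaFilter(ft, labels, alphaSig)
  X <- if (is.matrix(ft)) ft else featureMatrix(ft)
  sig <- av$significant
  retained <- if (length(sig)) {
    correlationDedup(ft, sig, av$pvalues, rThreshold)
  } else character()
  cm <- if (length(sig) > 1L) {
    suppressWarnings(cor(X[, sig, drop = FALSE]))
  } else matrix(1, length(sig), length(sig),
                dimnames = list(sig, sig))
  new("ScreeningResult", pvalues = av$pvalues, significant = sig,
      retained = retained, corMatrix = cm, alphaSig = alphaSig,
      rThreshold = rThreshold)
}
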