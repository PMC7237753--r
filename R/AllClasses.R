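## Central S4 classes for the TRF analysis pipeline.

#' Discrete acquisition time axis
#'
#' Shared time axis for excitation pulses, decay recordings and fitted
#' impulse responses: `nSamples` bins of width `dt` nanoseconds starting at
#' t = 0.
#'
#' @slot nSamples integer, number of time bins (>= 2).
#' @slot dt numeric, sampling interval in nanoseconds (> 0).
#' @export
setClass("TimeGrid", representation(nSamples = "integer", dt = "numeric"))

setValidity("TimeGrid", function(object) {
  msg <- character()
  if (length(object@nSamples) != 1L || is.na(object@nSamples) ||
      object@nSamples < 2L)
    msg <- c(msg, "nSamples must be a single integer >= 2")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (ns)")
  if (length(msg)) msg else TRUE
})

#' Construct a time grid
#'
#' @param nSamples number of time bins; default 2000.
#' @param dt sampling interval in nanoseconds; default 0.025 ns, which
#'   resolves a 0.3 ns excitation pulse and spans 50 ns — more than ten
#'   lifetimes of the slowest (~3.5 ns) tissue decay.
#' @param maxLifetime optional longest lifetime (ns) that will be simulated
#'   on this grid; a warning is emitted when the span does not exceed ten
#'   times this value.
#' @return A [TimeGrid-class] object.
#' @examples
#' g <- timeGrid()
#' gridSpan(g)
#' @export
timeGrid <- function(nSamples = 2000L, dt = 0.025, maxLifetime = NULL) {
  g <- new("TimeGrid", nSamples = as.integer(nSamples), dt = as.numeric(dt))
  if (!is.null(maxLifetime) && gridSpan(g) <= 10 * maxLifetime)
    warning("time grid span (", gridSpan(g),
            " ns) does not exceed 10x the longest lifetime (", maxLifetime,
            " ns); lifetime estimates will be truncation-biased")
  g
}

#' Measured or simulated excitation pulse
#'
#' The laser excitation pulse sampled on a [TimeGrid-class], peak-normalized
#' to 1 for simulated pulses.
#'
#' @slot grid the [TimeGrid-class].
#' @slot amplitude numeric vector, one nonnegative value per time bin.
#' @slot fwhm numeric, nominal full width at half maximum in nanoseconds.
#' @export
setClass("ExcitationPulse",
         representation(grid = "TimeGrid", amplitude = "numeric",
                        fwhm = "numeric"))

setValidity("ExcitationPulse", function(object) {
  msg <- character()
  if (length(object@amplitude) != object@grid@nSamples)
    msg <- c(msg, "amplitude length must equal grid nSamples")
  if (any(!is.finite(object@amplitude)) || any(object@amplitude < 0))
    msg <- c(msg, "amplitudes must be finite and nonnegative")
  if (!any(object@amplitude > 0))
    msg <- c(msg, "at least one amplitude must be positive")
  if (length(msg)) msg else TRUE
})

#' Fluorescence decay recording at one emission wavelength
#'
#' @slot wavelength numeric, emission wavelength in nm (360-550, multiple
#'   of 5).
#' @slot samples numeric, detector signal per time bin (arbitrary units).
#' @slot nSweeps integer, number of independently acquired sweeps averaged
#'   into `samples`.
#' @export
setClass("DecayCurve",
         representation(wavelength = "numeric", samples = "numeric",
                        nSweeps = "integer"))

setValidity("DecayCurve", function(object) {
  msg <- character()
  w <- object@wavelength
  if (length(w) != 1L || w < 360 || w > 550 || (w %% 5) != 0)
    msg <- c(msg, "wavelength must lie in [360, 550] nm on the 5 nm grid")
  if (length(object@nSweeps) != 1L || object@nSweeps < 1L)
    msg <- c(msg, "nSweeps must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' One biopsy specimen: decays across the emission wavelength grid
#'
#' Holds the full 360-550 nm (5 nm step) set of sweep-averaged decay
#' recordings for one specimen, as a time-bins x wavelengths matrix, plus
#' the tissue-class label.
#'
#' @slot specimenId character scalar.
#' @slot tissueClass one of the six upper-GI tissue classes (see
#'   [tissueClassNames()]).
#' @slot wavelengths numeric vector of emission wavelengths (nm).
#' @slot curves numeric matrix, nSamples x length(wavelengths).
#' @slot nSweeps integer, sweeps averaged per curve.
#' @export
setClass("SpecimenMeasurement",
         representation(specimenId = "character", tissueClass = "character",
                        wavelengths = "numeric", curves = "matrix",
                        nSweeps = "integer"))

#' Tissue class labels used throughout the package
#'
#' @return Character vector of the six recognised tissue classes.
#' @export
tissueClassNames <- function() {
  c("duodenum", "antrum", "stomach_body", "esophagus_normal",
    "esophagitis", "dysplastic_BE")
}

setValidity("SpecimenMeasurement", function(object) {
  msg <- character()
  if (!(object@tissueClass %in% tissueClassNames()))
    msg <- c(msg, paste0("unknown tissueClass '", object@tissueClass, "'"))
  full <- measurementWavelengths()
  if (!identical(as.numeric(object@wavelengths), full))
    msg <- c(msg, "wavelengths must be the complete 360-550 nm, 5 nm grid")
  if (ncol(object@curves) != length(object@wavelengths))
    msg <- c(msg, "one curve (matrix column) required per wavelength")
  if (length(msg)) msg else TRUE
})

#' Emission wavelength grids
#'
#' `measurementWavelengths()` is the acquisition grid (360-550 nm, 5 nm
#' step, 39 points); `featureWavelengths()` is the grid used for feature
#' construction (370-550 nm, 37 points).
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
measurementWavelengths <- function() seq(360, 550, by = 5)

#' @rdname measurementWavelengths
#' @export
featureWavelengths <- function() seq(370, 550, by = 5)

#' Orthonormal discrete Laguerre basis
#'
#' @slot grid the [TimeGrid-class].
#' @slot order integer, number of basis functions L.
#' @slot alpha numeric scale parameter in (0, 1).
#' @slot functions numeric matrix, nSamples x L; column j is b_{j-1}(n).
#' @export
setClass("LaguerreBasis",
         representation(grid = "TimeGrid", order = "integer",
                        alpha = "numeric", functions = "matrix"))

setValidity("LaguerreBasis", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie strictly in (0, 1)")
  if (object@order < 1L || object@order > 30L)
    msg <- c(msg, "order must lie in [1, 30]")
  if (!identical(dim(object@functions),
                 c(object@grid@nSamples, object@order)))
    msg <- c(msg, "functions must be an nSamples x order matrix")
  if (length(msg)) msg else TRUE
})

#' Fitted intrinsic fluorescence impulse response
#'
#' The deconvolved impulse response h(n) (the decay the tissue would show
#' under instantaneous excitation) together with its Laguerre expansion
#' coefficients and the least-squares residual norm.
#'
#' @slot h numeric vector, fitted impulse response per time bin.
#' @slot coefficients numeric vector of L expansion coefficients.
#' @slot residualNorm numeric, l2 norm of the fit residual.
#' @slot alpha numeric, Laguerre scale used.
#' @slot order integer, Laguerre order used.
#' @slot grid the [TimeGrid-class].
#' @export
setClass("ImpulseResponse",
         representation(h = "numeric", coefficients = "numeric",
                        residualNorm = "numeric", alpha = "numeric",
                        order = "integer", grid = "TimeGrid"))

setValidity("ImpulseResponse", function(object) {
  msg <- character()
  if (length(object@h) != object@grid@nSamples)
    msg <- c(msg, "h length must equal grid nSamples")
  if (object@residualNorm < 0)
    msg <- c(msg, "residualNorm must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort of specimen measurements
#'
#' Container returned by [simulateCohort()]: the specimen list, the shared
#' excitation pulse and time grid, and a ground-truth table recording every
#' parameter drawn by the generator.
#'
#' @slot specimens list of [SpecimenMeasurement-class] objects.
#' @slot pulse the shared [ExcitationPulse-class].
#' @slot grid the shared [TimeGrid-class].
#' @slot truth data.frame of per-specimen, per-wavelength ground truth
#'   (true discrete average lifetime, relative intensity, specimen lifetime
#'   offset, per-curve SNR in dB).
#' @slot seed integer seed used.
#' @slot params list of generator parameters (cohort spec).
#' @export
setClass("TRFCohort",
         representation(specimens = "list", pulse = "ExcitationPulse",
                        grid = "TimeGrid", truth = "data.frame",
                        seed = "integer", params = "list"))

#' Feature screening result
#'
#' @slot pvalues named numeric vector, one-way ANOVA p-value per feature.
#' @slot significant character vector of features with p < alphaSig.
#' @slot retained character vector kept after Pearson-correlation
#'   de-duplication (retained is a subset of significant).
#' @slot corMatrix correlation matrix of the significant features.
#' @slot alphaSig numeric significance threshold used.
#' @slot rThreshold numeric absolute-correlation redundancy threshold used.
#' @export
setClass("ScreeningResult",
         representation(pvalues = "numeric", significant = "character",
                        retained = "character", corMatrix = "matrix",
                        alphaSig = "numeric", rThreshold = "numeric"))

setValidity("ScreeningResult", function(object) {
  msg <- character()
  if (!all(object@retained %in% object@significant))
    msg <- c(msg, "retained features must be a subset of significant ones")
  if (!all(object@significant %in% names(object@pvalues)))
    msg <- c(msg, "significant features must have p-values")
  p <- object@pvalues
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation for one pairwise tissue task
#'
#' @slot task list describing the task (positive/negative class, window,
#'   classifier settings).
#' @slot selected character vector of selected features, in selection
#'   order (intensity catalog first, then lifetime catalog).
#' @slot trace data.frame selection trace: catalog, feature added,
#'   criterion (LOOCV balanced accuracy) after adding it.
#' @slot predictions character vector, one held-out LOOCV prediction per
#'   specimen.
#' @slot scores numeric vector of signed decision scores (positive favours
#'   the positive class).
#' @slot labels character vector of true labels.
#' @slot sensitivity,specificity numeric in [0, 1].
#' @slot roc data.frame with columns fpr, tpr.
#' @slot auc numeric in [0, 1].
#' @slot screening the [ScreeningResult-class] used.
#' @export
setClass("ClassifierEvaluation",
         representation(task = "list", selected = "character",
                        trace = "data.frame", predictions = "character",
                        scores = "numeric", labels = "character",
                        sensitivity = "numeric", specificity = "numeric",
                        roc = "data.frame", auc = "numeric",
                        screening = "ScreeningResult"))

setValidity("ClassifierEvaluation", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && x >= 0 && x <= 1
  if (!inUnit(object@sensitivity)) msg <- c(msg, "sensitivity not in [0,1]")
  if (!inUnit(object@specificity)) msg <- c(msg, "specificity not in [0,1]")
  if (!inUnit(object@auc)) msg <- c(msg, "AUC not in [0,1]")
  if (length(object@predictions) != length(object@labels))
    msg <- c(msg, "one prediction required per specimen")
  r <- object@roc
  if (nrow(r)) {
    if (r$fpr[1] != 0 || r$tpr[1] != 0 ||
        r$fpr[nrow(r)] != 1 || r$tpr[nrow(r)] != 1)
      msg <- c(msg, "ROC must run from (0,0) to (1,1)")
    if (is.unsorted(r$fpr) || is.unsorted(r$tpr))
      msg <- c(msg, "ROC must be monotone nondecreasing")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn timeGrid Time points (ns) of the grid, starting at 0.
#' @param grid a [TimeGrid-class].
#' @export
timePoints <- function(grid) (seq_len(grid@nSamples) - 1L) * grid@dt

#' @describeIn timeGrid Total span of the grid in ns (nSamples * dt).
#' @export
gridSpan <- function(grid) grid@nSamples * grid@dt

#' Accessors for pipeline objects
#'
#' Small read-only accessors used instead of direct slot access.
#'
#' @param object an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pulseAmplitude", function(object) standardGeneric("pulseAmplitude"))
#' @rdname accessors
#' @export
setMethod("pulseAmplitude", "ExcitationPulse", function(object) object@amplitude)

#' @rdname accessors
#' @export
setGeneric("basisFunctions", function(object) standardGeneric("basisFunctions"))
#' @rdname accessors
#' @export
setMethod("basisFunctions", "LaguerreBasis", function(object) object@functions)

#' @rdname accessors
#' @export
setGeneric("impulseResponse", function(object) standardGeneric("impulseResponse"))
#' @rdname accessors
#' @export
setMethod("impulseResponse", "ImpulseResponse", function(object) object@h)

#' @rdname accessors
#' @export
setGeneric("laguerreCoefficients",
           function(object) standardGeneric("laguerreCoefficients"))
#' @rdname accessors
#' @export
setMethod("laguerreCoefficients", "ImpulseResponse",
          function(object) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))
#' @rdname accessors
#' @export
setMethod("residualNorm", "ImpulseResponse", function(object) object@residualNorm)

#' @rdname accessors
#' @export
setGeneric("specimens", function(object) standardGeneric("specimens"))
#' @rdname accessors
#' @export
setMethod("specimens", "TRFCohort", function(object) object@specimens)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "TRFCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(object) standardGeneric("retainedFeatures"))
#' @rdname accessors
#' @export
setMethod("retainedFeatures", "ScreeningResult", function(object) object@retained)

#' @rdname accessors
#' @export
setGeneric("significantFeatures",
           function(object) standardGeneric("significantFeatures"))
#' @rdname accessors
#' @export
setMethod("significantFeatures", "ScreeningResult",
          function(object) object@significant)

#' @rdname accessors
#' @export
setGeneric("featurePValues", function(object) standardGeneric("featurePValues"))
#' @rdname accessors
#' @export
setMethod("featurePValues", "ScreeningResult", function(object) object@pvalues)

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "ClassifierEvaluation",
          function(object) object@selected)

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setMethod("rocPoints", "ClassifierEvaluation", function(object) object@roc)

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "ClassifierEvaluation", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("decisionScores", function(object) standardGeneric("decisionScores"))
#' @rdname accessors
#' @export
setMethod("decisionScores", "ClassifierEvaluation", function(object) object@scores)

## ---- show methods ----

setMethod("show", "TimeGrid", function(object) {
  cat("TimeGrid:", object@nSamples, "samples, dt =", object@dt,
      "ns (span", gridSpan(object), "ns)\n")
})

setMethod("show", "ExcitationPulse", function(object) {
  cat("ExcitationPulse: nominal FWHM", object@fwhm, "ns on",
      object@grid@nSamples, "bins (dt =", object@grid@dt, "ns)\n")
})

setMethod("show", "LaguerreBasis", function(object) {
  cat("LaguerreBasis: order", object@order, ", alpha =", object@alpha,
      ",", object@grid@nSamples, "time bins\n")
})

setMethod("show", "ImpulseResponse", function(object) {
  cat("ImpulseResponse: order", object@order, ", alpha =", object@alpha,
      ", residual norm", format(object@residualNorm, digits = 4), "\n")
})

setMethod("show", "SpecimenMeasurement", function(object) {
  cat("SpecimenMeasurement", object@specimenId, "(", object@tissueClass,
      "):", length(object@wavelengths), "wavelengths x",
      nrow(object@curves), "time bins,", object@nSweeps, "sweeps averaged\n")
})

setMethod("show", "TRFCohort", function(object) {
  cls <- vapply(object@specimens, function(s) s@tissueClass, character(1))
  cat("TRFCohort:", length(object@specimens), "specimens, seed",
      object@seed, "\n")
  print(table(tissue_class = cls))
})

setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult:", length(object@pvalues), "features screened;",
      length(object@significant), "significant (p <", object@alphaSig,
      "),", length(object@retained), "retained after |r| >=",
      object@rThreshold, "de-duplication\n")
})

setMethod("show", "ClassifierEvaluation", function(object) {
  cat("ClassifierEvaluation:", object@task$positive, "vs",
      object@task$negative, "\n  selected features:",
      paste(object@selected, collapse = ", "), "\n  sensitivity",
      format(object@sensitivity, digits = 3), ", specificity",
      format(object@specificity, digits = 3), ", AUC",
      format(object@auc, digits = 3), "\n")
})
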