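## On-disk formats: plain delimited tables plus YAML metadata/config.
## No binary containers — the field has no standard one for TRF point
## spectroscopy, and plain text stays diffable.

#' Write and read a synthetic cohort dataset
#'
#' `writeCohort()` writes three files into `dir`: `metadata.yaml` (grid,
#' pulse and cohort parameters, seed, class table), `decays.csv` (long
#' table: specimen_id, tissue_class, wavelength_nm, bin_index, value) and
#' `truth.csv` (the ground-truth table). `readCohort()` reconstructs the
#' [TRFCohort-class]; the round trip is lossless (values written with
#' full round-trip precision, the pulse regenerated deterministically
#' from its recorded parameters).
#'
#' @param cohort a [TRFCohort-class].
#' @param dir output directory (created if missing).
#' @return `writeCohort()` returns `dir` invisibly; `readCohort()` a
#'   [TRFCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  p <- cohort@params
  meta <- list(
    n_samples = cohort@grid@nSamples, dt_ns = cohort@grid@dt,
    pulse_fwhm_ns = cohort@pulse@fwhm, pulse_t0_ns = p$pulseT0,
    n_sweeps = p$nSweeps, snr_range_db = p$snrRange,
    seed = cohort@seed,
    class_sizes = as.list(p$classSizes))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  long <- data.table::rbindlist(lapply(cohort@specimens, function(sp) {
    nw <- length(sp@wavelengths)
    n <- nrow(sp@curves)
    data.table::data.table(
      specimen_id = sp@specimenId, tissue_class = sp@tissueClass,
      wavelength_nm = rep(sp@wavelengths, each = n),
      bin_index = rep.int(seq_len(n) - 1L, nw),
      value = as.vector(sp@curves))
  }))
  data.table::fwrite(long, file.path(dir, "decays.csv"))
  data.table::fwrite(cohort@truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  spec <- cohortSpec(
    classSizes = stats::setNames(as.integer(unlist(meta$class_sizes)),
                                 names(meta$class_sizes)),
    snrRange = as.numeric(meta$snr_range_db), nSweeps = meta$n_sweeps,
    nSamples = meta$n_samples, dt = meta$dt_ns,
    pulseFWHM = meta$pulse_fwhm_ns, pulseT0 = meta$pulse_t0_ns)
  grid <- timeGrid(spec$nSamples, spec$dt)
  pulse <- makeExcitationPulse(grid, spec$pulseFWHM, spec$pulseT0)
  long <- data.table::fread(file.path(dir, "decays.csv"))
  truth <- as.data.frame(data.table::fread(file.path(dir, "truth.csv")))
  sids <- unique(long$specimen_id)
  specimensOut <- lapply(sids, function(sid) {
    d <- long[long$specimen_id == sid, ]
    wl <- sort(unique(d$wavelength_nm))
    curves <- matrix(d$value[order(match(d$wavelength_nm, wl),
                                   d$bin_index)],
                     nrow = grid@nSamples, ncol = length(wl))
    new("SpecimenMeasurement", specimenId = sid,
        tissueClass = d$tissue_class[1], wavelengths = as.numeric(wl),
        curves = curves, nSweeps = as.integer(meta$n_sweeps))
  })
  new("TRFCohort", specimens = specimensOut, pulse = pulse, grid = grid,
      truth = truth, seed = as.integer(meta$seed), params = spec)
}

#' Write and read the per-wavelength lifetime results table
#'
#' Delimited table with columns `specimen_id`, `tissue_class`,
#' `wavelength_nm`, `tau_avg_ns`, `intensity`, `residual_norm`, `alpha`,
#' `order`, `flag`.
#'
#' @param lifetimeTable data.frame from [processCohort()].
#' @param path output file.
#' @return `writeLifetimeTable()` returns `path` invisibly;
#'   `readLifetimeTable()` the data.frame.
#' @export
writeLifetimeTable <- function(lifetimeTable, path) {
  data.table::fwrite(lifetimeTable, path)
  invisible(path)
}

#' @rdname writeLifetimeTable
#' @export
readLifetimeTable <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write and read a feature table
#'
#' Wide delimited table: one row per specimen (`specimen_id`,
#' `tissue_class`, then one column per feature, named `kind_wavelength`).
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param path output file.
#' @return `writeFeatureTable()` returns `path` invisibly;
#'   `readFeatureTable()` a reconstructed
#'   [SummarizedExperiment::SummarizedExperiment].
#' @export
writeFeatureTable <- function(ft, path) {
  X <- featureMatrix(ft)
  df <- data.frame(specimen_id = colData(ft)$specimen_id,
                   tissue_class = colData(ft)$tissue_class,
                   X, check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  featNames <- setdiff(names(df), c("specimen_id", "tissue_class"))
  mat <- t(as.matrix(df[, featNames, drop = FALSE]))
  colnames(mat) <- df$specimen_id
  kind <- sub("_.*$", "", featNames)
  wl <- as.numeric(sub("^[a-z]+_", "", featNames))
  SummarizedExperiment(
    assays = list(features = mat),
    rowData = DataFrame(kind = kind, wavelength = wl,
                        row.names = featNames),
    colData = DataFrame(specimen_id = df$specimen_id,
                        tissue_class = df$tissue_class,
                        row.names = df$specimen_id))
}

#' Write a structured per-task report
#'
#' YAML report containing the task spec, screening summary, selection
#' trace, confusion matrix, sensitivity/specificity, ROC points, AUC and
#' the study seed. Contains no timestamps, so identical runs produce
#' byte-identical reports.
#'
#' @param evaluation a [ClassifierEvaluation-class].
#' @param path output file.
#' @param seed study seed recorded in the report.
#' @return `path`, invisibly.
#' @export
writeTaskReport <- function(evaluation, path, seed = NA_integer_) {
  e <- evaluation
  cm <- table(truth = e@labels, predicted = e@predictions)
  rep <- list(
    task = e@task[!vapply(e@task, is.null, logical(1))],
    seed = seed,
    screening = list(
      n_features = length(e@screening@pvalues),
      n_significant = length(e@screening@significant),
      n_retained = length(e@screening@retained),
      retained = as.list(e@screening@retained)),
    selection_trace = if (nrow(e@trace)) {
      lapply(seq_len(nrow(e@trace)), function(i)
        list(catalog = e@trace$catalog[i], feature = e@trace$feature[i],
             criterion = e@trace$criterion[i]))
    } else list(),
    selected_features = as.list(e@selected),
    confusion_matrix = lapply(rownames(cm), function(r)
      stats::setNames(as.list(as.integer(cm[r, ])), colnames(cm))),
    sensitivity = e@sensitivity,
    specificity = e@specificity,
    auc = e@auc,
    roc = list(fpr = e@roc$fpr, tpr = e@roc$tpr))
  yaml::write_yaml(rep, path, precision = 15)
  invisible(path)
}
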