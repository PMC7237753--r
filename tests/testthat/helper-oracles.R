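# Independent oracles used to freeze expected values, deliberately
# written as direct (slow) summations/enumerations rather than through
# the package's own code paths.

# Eq.-1 first-moment lifetime by explicit loop summation.
bruteLifetime <- function(h, dt) {
  num <- 0
  den <- 0
  for (n in seq_along(h)) {
    num <- num + (n - 1) * h[n]
    den <- den + h[n]
  }
  dt * num / den
}

# AUC as the fraction of concordant positive/negative pairs, ties half.
bruteAUC <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Direct O(n^2) causal convolution, y(n) = dt * sum_m p(m) h(n-m).
bruteConvolve <- function(p, h, dt) {
  n <- length(h)
  y <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (m in seq_len(i)) s <- s + p[m] * h[i - m + 1]
    y[i] <- dt * s
  }
  y
}

# A compact grid for tests that do not depend on the default resolution.
testGrid <- function(nSamples = 720L, dt = 0.05) timeGrid(nSamples, dt)

# Delta excitation pulse (single unit bin at t = 0).
deltaPulse <- function(grid) {
  amp <- numeric(grid@nSamples)
  amp[1] <- 1
  new("ExcitationPulse", grid = grid, amplitude = amp, fwhm = grid@dt)
}

# Two-class presets that differ ONLY in (flat) lifetime: identical
# spectra and wavelength-constant lifetimes, so normalized intensity
# features carry no class signal while lifetime features separate.
lifetimeOnlyPresets <- function(tauA = 3.3, tauB = 2.7, sd = 0.05) {
  base <- tissueClassPresets()$esophagus_normal
  mk <- function(name, tau) {
    p <- base
    p$name <- name
    p$lifetime$anchorTau <- tau
    p$lifetime$terminalTau <- tau
    p$sdOffset <- sd
    p
  }
  list(esophagus_normal = mk("esophagus_normal", tauA),
       dysplastic_BE = mk("dysplastic_BE", tauB))
}

# Fabricated per-wavelength lifetime table (no deconvolution) for
# feature-construction tests: flat spectra/lifetimes plus class shifts.
fakeLifetimeTable <- function(classSizes, seed = 1,
                              wavelengths = measurementWavelengths()) {
  set.seed(seed)
  rows <- list()
  for (cls in names(classSizes)) {
    for (k in seq_len(classSizes[[cls]])) {
      sid <- sprintf("%s_%02d", cls, k)
      rows[[sid]] <- data.frame(
        specimen_id = sid, tissue_class = cls,
        wavelength_nm = wavelengths,
        tau_avg_ns = 3 + 0.05 * rnorm(length(wavelengths)),
        intensity = exp(-((wavelengths - 455) / 60)^2) *
          (1 + 0.02 * rnorm(length(wavelengths))),
        residual_norm = 0.1, alpha = 0.9, order = 12L, flag = "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Memoized full default study (with written reports) shared by the
# end-to-end tests.
.studyCache <- new.env(parent = emptyenv())
defaultStudy <- function() {
  if (is.null(.studyCache$res)) {
    dir <- file.path(tempdir(), "trflab-default-study")
    .studyCache$res <- suppressMessages(
      runStudy(pipelineConfig(seed = 101L), outdir = dir))
    .studyCache$dir <- dir
  }
  list(res = .studyCache$res, dir = .studyCache$dir)
}
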