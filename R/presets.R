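## Tissue-class presets: the population-level fluorescence signatures the
## synthetic cohort generator realizes.

#' Default tissue-class presets for the synthetic cohort generator
#'
#' Each preset describes one upper-GI tissue class by (i) an emission
#' spectrum model — a Gaussian band peaking at 455 nm with an optional
#' multiplicative short-wavelength enhancement band — and (ii) a lifetime
#' curve — an anchor average lifetime (ns) at an anchor wavelength,
#' linearly interpolated in wavelength to a terminal lifetime at 520 nm
#' and held constant beyond both anchors.
#'
#' Lifetime anchors follow the published class curves for upper-GI mucosa:
#' stomach body 3.13 ns at 380 nm falling to 2.12 ns at 520 nm; antrum
#' 3.25 ns at 385 nm to 2.58 ns at 520 nm; duodenum about 3 ns in the UV
#' falling to 2.79 ns at 520 nm; normal esophagus nearly flat (3.10 ns);
#' esophagitis peaking at 3.46 ns at 390 nm; dysplastic Barrett's
#' esophagus flat at 3.09 ns. Between-specimen standard deviations convert
#' the reported standard errors to population spread via SD = SE * sqrt(n)
#' using the per-class sample sizes.
#'
#' @param kinetics `"mono"` (default) for mono-exponential decay kinetics
#'   at every wavelength, or `"bi"` for bi-exponential kinetics with a
#'   fixed 60/40 fractional amplitude split.
#' @return Named list of presets, one per tissue class; each preset is a
#'   list with elements `name`, `spectrum` (peak, width, optional `band`),
#'   `lifetime` (anchorTau, anchorWavelength, terminalTau at 520 nm),
#'   `sdOffset` (between-specimen lifetime SD, ns) and `kinetics`.
#' @examples
#' p <- tissueClassPresets()
#' p$stomach_body$lifetime
#' @export
tissueClassPresets <- function(kinetics = c("mono", "bi")) {
  kinetics <- match.arg(kinetics)
  mk <- function(name, anchorTau, anchorWavelength, terminalTau, sdOffset,
                 band = NULL) {
    list(name = name,
         spectrum = list(peak = 455, width = 55, band = band),
         lifetime = list(anchorTau = anchorTau,
                         anchorWavelength = anchorWavelength,
                         terminalTau = terminalTau,
                         terminalWavelength = 520),
         sdOffset = sdOffset,
         kinetics = kinetics)
  }
  list(
    duodenum         = mk("duodenum",         3.05, 380, 2.79, 0.05 * sqrt(27)),
    antrum           = mk("antrum",           3.25, 385, 2.58, 0.02 * sqrt(5)),
    stomach_body     = mk("stomach_body",     3.13, 380, 2.12, 0.03 * sqrt(19)),
    esophagus_normal = mk("esophagus_normal", 3.10, 380, 3.10, 0.10),
    esophagitis      = mk("esophagitis",      3.46, 390, 2.90, 0.03 * sqrt(8),
                          band = list(center = 400, width = 18, amp = 0.25)),
    dysplastic_BE    = mk("dysplastic_BE",    3.09, 380, 3.09, 0.11 * sqrt(3),
                          band = list(center = 400, width = 15, amp = 0.12))
  )
}

#' Evaluate a preset's emission spectrum
#'
#' Relative emission intensity (arbitrary units) of a tissue-class preset
#' at the requested wavelengths: a Gaussian band at the spectral peak,
#' optionally multiplied by (1 + amp * Gaussian enhancement band) to model
#' short-wavelength enrichment.
#'
#' @param preset one element of [tissueClassPresets()].
#' @param wavelength numeric vector of emission wavelengths (nm).
#' @return Numeric vector of nonnegative relative intensities.
#' @export
presetSpectrum <- function(preset, wavelength) {
  s <- preset$spectrum
  main <- exp(-((wavelength - s$peak)^2) / (2 * s$width^2))
  if (!is.null(s$band)) {
    b <- s$band
    main <- main * (1 + b$amp * exp(-((wavelength - b$center)^2) /
                                      (2 * b$width^2)))
  }
  main
}

#' Evaluate a preset's lifetime curve
#'
#' Population-mean average lifetime (ns) at the requested wavelengths:
#' linear interpolation between the anchor and terminal (520 nm) values,
#' constant extension beyond both.
#'
#' @inheritParams presetSpectrum
#' @return Numeric vector of lifetimes in ns.
#' @export
presetLifetime <- function(preset, wavelength) {
  lt <- preset$lifetime
  w0 <- lt$anchorWavelength
  w1 <- lt$terminalWavelength
  frac <- pmin(1, pmax(0, (wavelength - w0) / (w1 - w0)))
  lt$anchorTau + frac * (lt$terminalTau - lt$anchorTau)
}
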