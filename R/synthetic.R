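## Synthetic-data generator: excitation pulses, decay kernels, noisy
## sweep-averaged decay recordings, and full labeled cohorts.

#' Simulate a Gaussian excitation pulse
#'
#' Samples a Gaussian laser pulse of nominal full width at half maximum
#' `fwhm` centered at `t0` on the time grid, truncated at the grid bounds
#' and peak-normalized to 1. The default 0.3 ns FWHM matches a picosecond
#' Nd:YAG excitation source.
#'
#' @param grid a [TimeGrid-class].
#' @param fwhm pulse full width at half maximum in ns (> 0); a warning is
#'   emitted below 2 * dt, where the sampled pulse degenerates towards a
#'   single-bin delta.
#' @param t0 pulse center in ns; default 2 ns.
#' @return An [ExcitationPulse-class].
#' @examples
#' p <- makeExcitationPulse(timeGrid(), fwhm = 0.3)
#' @export
makeExcitationPulse <- function(grid, fwhm = 0.3, t0 = 2) {
  stopifnot(is(grid, "TimeGrid"))
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be a positive number of nanoseconds")
  if (fwhm < 2 * grid@dt)
    warning("fwhm (", fwhm, " ns) is below 2*dt (", 2 * grid@dt,
            " ns); the sampled pulse approaches a single-bin delta")
  t <- timePoints(grid)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amp <- exp(-((t - t0)^2) / (2 * sigma^2))
  amp <- amp / max(amp)
  new("ExcitationPulse", grid = grid, amplitude = amp, fwhm = fwhm)
}

#' Empirical FWHM of a sampled pulse
#'
#' Full width at half maximum measured on the sampled amplitudes by linear
#' interpolation of the half-maximum crossings.
#'
#' @param pulse an [ExcitationPulse-class].
#' @return FWHM in ns.
#' @export
pulseFWHM <- function(pulse) {
  a <- pulse@amplitude
  t <- timePoints(pulse@grid)
  half <- max(a) / 2
  above <- which(a >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  crossL <- if (i1 > 1) {
    t[i1 - 1] + (half - a[i1 - 1]) / (a[i1] - a[i1 - 1]) * pulse@grid@dt
  } else t[i1]
  crossR <- if (i2 < length(a)) {
    t[i2] + (a[i2] - half) / (a[i2] - a[i2 + 1]) * pulse@grid@dt
  } else t[i2]
  crossR - crossL
}

## Causal discrete convolution y(n) = dt * sum_m p(m) h(n-m), zero-padded,
## truncated to the grid. FFT-based; an optionally precomputed padded pulse
## FFT avoids recomputation across the thousands of curves in a cohort.
convolveCausal <- function(pulseAmp, h, dt, pulseFFT = NULL, nfft = NULL) {
  n <- length(h)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(2 * n - 1))
  if (is.null(pulseFFT)) pulseFFT <- fft(c(pulseAmp, numeric(nfft - n)))
  hf <- fft(c(h, numeric(nfft - n)))
  y <- Re(fft(pulseFFT * hf, inverse = TRUE)) / nfft
  dt * y[seq_len(n)]
}

## Discrete first-moment lifetime of a raw kernel (internal; the exported
## estimator for fitted impulse responses is averageLifetime()).
discreteLifetime <- function(h, dt) {
  s <- sum(h)
  if (s <= 0) return(NA_real_)
  dt * sum((seq_along(h) - 1) * h) / s
}

#' Noise-free decay kernel realizing a tissue-class preset
#'
#' Builds the true fluorescence impulse response h_true(n) at one emission
#' wavelength: mono- or bi-exponential kinetics whose discrete first-moment
#' average lifetime equals the discrete analog `dt*r/(1-r)`,
#' `r = exp(-dt/tau)`, of the preset lifetime at that wavelength plus the
#' specimen offset, peak-scaled to the preset's relative spectrum value.
#' For bi-exponential kinetics the fractional amplitudes are fixed at
#' 60/40, the fast component at 0.6 times the target lifetime, and the
#' slow component solved so the mixture's discrete average lifetime
#' matches the mono-exponential target.
#'
#' @param preset one element of [tissueClassPresets()].
#' @param wavelength emission wavelength (nm), on the measurement grid.
#' @param specimenOffset rigid lifetime offset for this specimen (ns).
#' @param grid a [TimeGrid-class].
#' @return Numeric vector h_true per time bin (arbitrary units).
#' @export
trueImpulseResponse <- function(preset, wavelength, specimenOffset = 0,
                                grid = timeGrid()) {
  if (!(wavelength %in% measurementWavelengths()))
    stop("wavelength ", wavelength, " nm is not on the measurement grid")
  tau <- presetLifetime(preset, wavelength) + specimenOffset
  if (tau <= 0)
    stop("requested lifetime is nonpositive (", signif(tau, 3),
         " ns) after specimen offset")
  amp <- presetSpectrum(preset, wavelength)
  t <- timePoints(grid)
  if (amp == 0) return(numeric(grid@nSamples))
  if (identical(preset$kinetics, "bi")) {
    dt <- grid@dt
    r <- exp(-dt / tau)
    target <- dt * r / (1 - r)   # infinite-grid discrete lifetime
    tau1 <- 0.6 * tau
    mixLifetime <- function(tau2) {
      r1 <- exp(-dt / tau1); r2 <- exp(-dt / tau2)
      s0 <- 0.6 / (1 - r1) + 0.4 / (1 - r2)
      s1 <- 0.6 * r1 / (1 - r1)^2 + 0.4 * r2 / (1 - r2)^2
      dt * s1 / s0 - target
    }
    tau2 <- stats::uniroot(mixLifetime, c(tau, 10 * tau), tol = 1e-12)$root
    h <- 0.6 * exp(-t / tau1) + 0.4 * exp(-t / tau2)
  } else {
    h <- exp(-t / tau)
  }
  amp * h / h[1]
}

#' Simulate one noisy, sweep-averaged decay recording
#'
#' Convolves the excitation pulse with a true impulse response (causal
#' discrete convolution scaled by dt), adds i.i.d. Gaussian noise with
#' standard deviation set so that the single-sweep peak-referenced SNR,
#' `20*log10(max(y0)/sigma)`, equals `snrDb`, and returns the mean of
#' `nSweeps` independent noisy sweeps. Uses the current R random number
#' stream; seed upstream for reproducibility.
#'
#' @param pulse an [ExcitationPulse-class].
#' @param hTrue numeric vector, true impulse response on the same grid.
#' @param snrDb single-sweep peak signal-to-noise ratio in dB; `Inf`
#'   yields a noiseless recording.
#' @param nSweeps number of sweeps averaged (default 10).
#' @param wavelength emission wavelength recorded in the returned curve.
#' @return A [DecayCurve-class].
#' @export
simulateDecay <- function(pulse, hTrue, snrDb, nSweeps = 10L,
                          wavelength = 455) {
  if (length(hTrue) != pulse@grid@nSamples)
    stop("hTrue and pulse grids do not match (", length(hTrue), " vs ",
         pulse@grid@nSamples, " samples)")
  if (is.na(snrDb) || identical(snrDb, -Inf))
    stop("snrDb must be a finite number of dB (or Inf for noiseless)")
  y0 <- convolveCausal(pulse@amplitude, hTrue, pulse@grid@dt)
  peak <- max(y0)
  sigma <- if (peak > 0 && is.finite(snrDb)) peak / 10^(snrDb / 20) else 0
  n <- length(y0)
  noise <- if (sigma > 0) {
    rowMeans(matrix(rnorm(n * nSweeps, sd = sigma), nrow = n))
  } else numeric(n)
  new("DecayCurve", wavelength = wavelength, samples = y0 + noise,
      nSweeps = as.integer(nSweeps))
}

#' Cohort specification for the synthetic study
#'
#' Defaults emulate the study cohort: 27 duodenum, 5 antrum, 19 stomach
#' body, 16 normal esophagus, 8 esophagitis and 3 dysplastic Barrett's
#' esophagus specimens (78 total); per-curve single-sweep SNR drawn
#' uniformly from 4-20 dB; 10 sweeps averaged per curve; 2000 time bins of
#' 0.025 ns; a 0.3 ns FWHM excitation pulse centered at 2 ns.
#'
#' @param classSizes named integer vector, specimens per tissue class.
#' @param snrRange length-2 numeric, uniform range of per-curve SNR (dB),
#'   within \[0, 40\].
#' @param nSweeps sweeps averaged per curve.
#' @param nSamples,dt time-grid parameters.
#' @param pulseFWHM,pulseT0 excitation-pulse parameters (ns).
#' @return A list with the validated specification.
#' @export
cohortSpec <- function(classSizes = c(duodenum = 27L, antrum = 5L,
                                      stomach_body = 19L,
                                      esophagus_normal = 16L,
                                      esophagitis = 8L, dysplastic_BE = 3L),
                       snrRange = c(4, 20), nSweeps = 10L,
                       nSamples = 2000L, dt = 0.025,
                       pulseFWHM = 0.3, pulseT0 = 2) {
  if (is.null(names(classSizes)) || any(!nzchar(names(classSizes))))
    stop("classSizes must be a named vector of tissue classes")
  if (any(classSizes < 1L))
    stop("every included class needs at least one specimen")
  if (length(snrRange) != 2L || snrRange[1] > snrRange[2] ||
      snrRange[1] < 0 || snrRange[2] > 40)
    stop("snrRange must be an increasing pair within [0, 40] dB")
  list(classSizes = classSizes, snrRange = as.numeric(snrRange),
       nSweeps = as.integer(nSweeps), nSamples = as.integer(nSamples),
       dt = dt, pulseFWHM = pulseFWHM, pulseT0 = pulseT0)
}

#' Simulate a labeled cohort of specimen measurements
#'
#' Generates the full synthetic study: one rigid lifetime-curve offset per
#' specimen drawn from Normal(0, preset SD), one SNR per curve drawn
#' uniformly from the spec range, and a noisy sweep-averaged decay per
#' wavelength on the 360-550 nm grid. The ground-truth table records every
#' drawn parameter (offset, per-curve SNR, true discrete average lifetime
#' and relative intensity per wavelength). Bit-reproducible given `seed`.
#'
#' @param spec a [cohortSpec()] list.
#' @param presets named list of tissue-class presets covering every class
#'   in `spec$classSizes`; default [tissueClassPresets()].
#' @param seed integer seed.
#' @return A [TRFCohort-class].
#' @examples
#' \donttest{
#' cohort <- simulateCohort(seed = 1)
#' cohort
#' }
#' @export
simulateCohort <- function(spec = cohortSpec(),
                           presets = tissueClassPresets(), seed = 1L) {
  missingPresets <- setdiff(names(spec$classSizes), names(presets))
  if (length(missingPresets))
    stop("no preset for class(es): ", paste(missingPresets, collapse = ", "))
  maxTau <- max(vapply(presets[names(spec$classSizes)], function(p)
    max(p$lifetime$anchorTau, p$lifetime$terminalTau), numeric(1)))
  grid <- timeGrid(spec$nSamples, spec$dt, maxLifetime = maxTau)
  pulse <- makeExcitationPulse(grid, spec$pulseFWHM, spec$pulseT0)
  wl <- measurementWavelengths()
  n <- grid@nSamples
  nfft <- 2^ceiling(log2(2 * n - 1))
  pulseFFT <- fft(c(pulse@amplitude, numeric(nfft - n)))
  dt <- grid@dt

  set.seed(as.integer(seed))
  specimensOut <- list()
  truthRows <- list()
  idx <- 0L
  for (cls in names(spec$classSizes)) {
    preset <- presets[[cls]]
    for (k in seq_len(spec$classSizes[[cls]])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", cls, k)
      offset <- rnorm(1, sd = preset$sdOffset)
      curves <- matrix(0, nrow = n, ncol = length(wl))
      snrs <- runif(length(wl), spec$snrRange[1], spec$snrRange[2])
      taus <- numeric(length(wl))
      amps <- numeric(length(wl))
      for (j in seq_along(wl)) {
        h <- trueImpulseResponse(preset, wl[j], offset, grid)
        taus[j] <- discreteLifetime(h, dt)
        amps[j] <- presetSpectrum(preset, wl[j])
        y0 <- convolveCausal(pulse@amplitude, h, dt,
                             pulseFFT = pulseFFT, nfft = nfft)
        peak <- max(y0)
        sigma <- if (peak > 0) peak / 10^(snrs[j] / 20) else 0
        noise <- if (sigma > 0) {
          rowMeans(matrix(rnorm(n * spec$nSweeps, sd = sigma), nrow = n))
        } else numeric(n)
        curves[, j] <- y0 + noise
      }
      specimensOut[[idx]] <- new("SpecimenMeasurement", specimenId = sid,
                                 tissueClass = cls, wavelengths = wl,
                                 curves = curves,
                                 nSweeps = spec$nSweeps)
      truthRows[[idx]] <- data.frame(
        specimen_id = sid, tissue_class = cls, wavelength_nm = wl,
        true_tau_ns = taus, true_intensity = amps,
        specimen_offset_ns = offset, snr_db = snrs,
        stringsAsFactors = FALSE)
    }
  }
  new("TRFCohort", specimens = specimensOut, pulse = pulse, grid = grid,
      truth = do.call(rbind, truthRows), seed = as.integer(seed),
      params = spec)
}
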