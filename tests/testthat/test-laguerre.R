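# Laguerre basis construction, least-squares deconvolution, and the
# moment estimators computed from the fitted impulse response.

test_that("basis matches the closed form and is orthonormal on the grid", {
  g <- timeGrid(2000L, 0.025)
  b <- laguerreBasis(g, order = 12L, alpha = 0.9)

  # zeroth function closed form sqrt(1-a) * a^(n/2)
  n <- seq_len(g@nSamples) - 1
  expect_equal(basisFunctions(b)[, 1], sqrt(0.1) * 0.9^(n / 2),
               tolerance = 1e-10)

  # Gram matrix = identity across the default alpha search grid
  for (a in c(0.80, 0.90, 0.98)) {
    B <- basisFunctions(laguerreBasis(g, 12L, a))
    expect_lt(max(abs(crossprod(B) - diag(12L))), 1e-8)
  }

  # each function decays out well before the end of the record
  B5 <- basisFunctions(laguerreBasis(g, 5L, 0.9))
  expect_true(all(abs(B5[g@nSamples, ]) < 1e-6))

  expect_error(laguerreBasis(g, 12L, alpha = 1.2), "alpha")
  expect_error(laguerreBasis(g, 0L, alpha = 0.9), "order")
})

test_that("deconvolution exactly recovers in-span truth and flags a
           degenerate system", {
  g <- testGrid()
  basis <- laguerreBasis(g, 8L, 0.9)
  p <- makeExcitationPulse(g, 0.3, 2)

  set.seed(31)
  cTrue <- rnorm(8)
  hTrue <- as.numeric(basisFunctions(basis) %*% cTrue)
  y <- simulateDecay(p, hTrue, snrDb = Inf)
  fit <- deconvolve(y, p, basis)
  relErr <- sqrt(sum((impulseResponse(fit) - hTrue)^2) / sum(hTrue^2))
  expect_lt(relErr, 1e-8)
  expect_equal(laguerreCoefficients(fit), cTrue, tolerance = 1e-8)

  # reconstruction identity h = B c
  expect_equal(impulseResponse(fit),
               as.numeric(basisFunctions(basis) %*%
                            laguerreCoefficients(fit)),
               tolerance = 1e-10)

  # rank-deficient pulse-convolved basis raises a singular-system error
  pZero <- p
  slot(pZero, "amplitude", check = FALSE) <- numeric(g@nSamples)
  expect_error(deconvolve(y, pZero, basis), "singular")

  expect_error(deconvolve(y@samples[-1], p, basis), "grid")
})

test_that("average lifetime evaluates Eq.-1 closed forms", {
  g <- timeGrid(2000L, 0.05)
  N <- g@nSamples

  h <- numeric(N); h[1] <- 1
  expect_equal(averageLifetime(h, g), 0)

  expect_equal(averageLifetime(rep(1, N), g), g@dt * (N - 1) / 2)

  r <- exp(-g@dt / 1)      # tau = 1 ns; tail r^N ~ e^-100 negligible
  hg <- r^(0:(N - 1))
  expect_equal(averageLifetime(hg, g), bruteLifetime(hg, g@dt),
               tolerance = 1e-12)
  expect_lt(abs(averageLifetime(hg, g) - g@dt * r / (1 - r)) /
              averageLifetime(hg, g), 1e-9)

  expect_error(averageLifetime(-hg, g), class = "trflab_degenerate_decay")
})

test_that("integrated intensity is the mean of h with linear scaling", {
  g <- timeGrid(500L, 0.05)
  expect_equal(integratedIntensity(numeric(500), g), 0)
  expect_equal(integratedIntensity(rep(2.5, 500), g), 2.5)
  r <- exp(-g@dt / 0.4)    # fast decay: geometric sum ~ 1/(1-r)
  hg <- r^(0:499)
  expect_equal(integratedIntensity(hg, g), sum(hg) / 500, tolerance = 1e-12)
  expect_lt(abs(integratedIntensity(hg, g) - 1 / (500 * (1 - r))) /
              integratedIntensity(hg, g), 1e-9)

  # linearity: scaling the curve scales intensity, leaves lifetime fixed
  k <- 7.3
  expect_equal(integratedIntensity(k * hg, g),
               k * integratedIntensity(hg, g), tolerance = 1e-12)
  expect_equal(averageLifetime(k * hg, g), averageLifetime(hg, g),
               tolerance = 1e-10)
})

test_that("alpha selection returns exact members and degenerates cleanly", {
  g <- testGrid()
  p <- makeExcitationPulse(g, 0.3, 2)
  basis <- laguerreBasis(g, 8L, 0.9)
  set.seed(32)
  hTrue <- as.numeric(basisFunctions(basis) %*% rnorm(8))
  y <- simulateDecay(p, hTrue, snrDb = Inf)

  # generating alpha in the grid, truth in span: selected fit is exact
  sel <- selectAlpha(y, p, g, order = 8L,
                     alphaGrid = c(0.8, 0.85, 0.9, 0.95))
  expect_lt(residualNorm(sel$fit), 1e-8)
  expect_equal(sel$alpha, 0.9)

  # single-element grid returns that alpha
  sel1 <- selectAlpha(y, p, g, order = 8L, alphaGrid = 0.85)
  expect_equal(sel1$alpha, 0.85)

  expect_error(selectAlpha(y, p, g, alphaGrid = numeric()), "nonempty")
  expect_error(selectAlpha(y, p, g, alphaGrid = c(0.5, 1.5)), "(0, 1)",
               fixed = TRUE)
})

test_that("noiseless mono-exponential lifetime is recovered through the
           pulse to better than 1 percent", {
  g <- timeGrid(2000L, 0.025)
  p <- makeExcitationPulse(g, 0.3, 2)
  h <- trueImpulseResponse(tissueClassPresets()$duodenum, 455, 0, g)
  tauTrue <- averageLifetime(h, g)
  y <- simulateDecay(p, h, snrDb = Inf)
  sel <- selectAlpha(y, p, g)
  expect_lt(abs(averageLifetime(sel$fit) - tauTrue) / tauTrue, 0.01)

  # 60 dB closed-form limit: within 0.2%
  set.seed(33)
  y60 <- simulateDecay(p, h, 60, nSweeps = 1)
  sel60 <- selectAlpha(y60, p, g)
  expect_lt(abs(averageLifetime(sel60$fit) - tauTrue) / tauTrue, 0.002)
})

test_that("pure-noise input yields zero-mean coefficients", {
  g <- timeGrid(300L, 0.05)
  p <- makeExcitationPulse(g, 0.3, 1.5)
  basis <- laguerreBasis(g, 6L, 0.9)
  set.seed(34)
  C <- replicate(200, {
    y <- rnorm(300)
    laguerreCoefficients(deconvolve(y, p, basis))
  })
  m <- rowMeans(C)
  se <- apply(C, 1, sd) / sqrt(ncol(C))
  expect_true(all(abs(m) < 3 * se + 1e-12))
})

test_that("delta-pulse deconvolution reproduces direct Eq.-1 evaluation", {
  g <- testGrid()
  basis <- laguerreBasis(g, 10L, 0.88)
  dp <- deltaPulse(g)
  set.seed(35)
  for (rep in 1:5) {
    cTrue <- rnorm(10)
    hTrue <- as.numeric(basisFunctions(basis) %*% cTrue)
    if (sum(hTrue) <= 0) hTrue <- -hTrue
    y <- simulateDecay(dp, hTrue, snrDb = Inf)
    tauFit <- averageLifetime(deconvolve(y, dp, basis))
    tauDirect <- averageLifetime(y@samples / g@dt, g)
    expect_lt(abs(tauFit - tauDirect), 1e-9)
  }
})

test_that("specimen processing recovers truth per wavelength and flags
           unfittable curves", {
  spec <- cohortSpec(classSizes = c(stomach_body = 1L), nSamples = 2000L,
                     dt = 0.025, snrRange = c(20, 20))
  co <- simulateCohort(spec, seed = 41)
  sp <- specimens(co)[[1]]

  # noiseless version of the same specimen: rebuild curves without noise
  tr <- groundTruth(co)
  p <- co@pulse
  noiseless <- sp
  for (j in seq_along(sp@wavelengths)) {
    h <- trueImpulseResponse(tissueClassPresets()$stomach_body,
                             sp@wavelengths[j], tr$specimen_offset_ns[1],
                             co@grid)
    noiseless@curves[, j] <- simulateDecay(p, h, snrDb = Inf)@samples
  }
  res <- processSpecimen(noiseless, p)
  truthTau <- tr$true_tau_ns[match(res$wavelength_nm, tr$wavelength_nm)]
  expect_true(all(res$flag == "ok"))
  expect_true(all(abs(res$tau_avg_ns - truthTau) / truthTau < 0.01))

  # all-zero curves: every wavelength flagged, none dropped
  zero <- sp
  zero@curves[] <- 0
  resZero <- processSpecimen(zero, p)
  expect_equal(nrow(resZero), length(sp@wavelengths))
  expect_true(all(resZero$flag == "unfittable"))
  expect_true(all(is.na(resZero$tau_avg_ns)))
})
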