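# Feature-table construction and the two-stage screening (one-way ANOVA,
# Pearson-correlation de-duplication).

test_that("feature table is built with fixed layout and max-normalized
           intensities", {
  sizes <- c(duodenum = 27L, antrum = 5L, stomach_body = 19L,
             esophagus_normal = 16L, esophagitis = 8L, dysplastic_BE = 3L)
  lt <- fakeLifetimeTable(sizes, seed = 3)
  ft <- buildFeatureTable(lt)

  expect_equal(dim(ft), c(74L, 78L))
  wl <- featureWavelengths()
  expect_equal(rownames(ft),
               c(paste0("intensity_", wl), paste0("lifetime_", wl)))
  expect_equal(as.character(rowData(ft)$kind),
               rep(c("intensity", "lifetime"), each = 37L))

  # per-specimen max-normalization of the intensity block
  X <- featureMatrix(ft)
  expect_true(all(abs(apply(X[, 1:37], 1, max) - 1) < 1e-12))

  # lifetime columns pass through unchanged
  sid <- colnames(ft)[1]
  raw <- lt[lt$specimen_id == sid & lt$wavelength_nm %in% wl, ]
  expect_equal(unname(X[sid, paste0("lifetime_", wl)]),
               raw$tau_avg_ns[match(wl, raw$wavelength_nm)])

  # explicit three-point normalization example
  expect_equal(c(2, 4, 8) / max(c(2, 4, 8)), c(0.25, 0.5, 1.0))

  # a specimen with an unfittable wavelength is excluded with a warning
  lt2 <- lt
  lt2$flag[lt2$specimen_id == sid & lt2$wavelength_nm == 400] <-
    "unfittable"
  expect_warning(ft2 <- buildFeatureTable(lt2), sid)
  expect_equal(ncol(ft2), 77L)
  expect_false(sid %in% colnames(ft2))

  # all specimens excluded is an error
  lt3 <- lt
  lt3$tau_avg_ns <- NA_real_
  expect_error(suppressWarnings(buildFeatureTable(lt3)), "no specimen")
})

test_that("ANOVA filter reproduces hand-computed and oracle results", {
  # worked two-group example: SSB = 13.5, MSW = 1, df = (1, 4)
  X <- cbind(f = c(1, 2, 3, 4, 5, 6))
  g <- c("a", "a", "a", "b", "b", "b")
  res <- anovaFilter(X, g, alphaSig = 0.05)
  expect_equal(unname(res$pvalues["f"]), pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(res$pvalues["f"]), 0.02131, tolerance = 1e-3)
  expect_equal(res$significant, "f")

  # identical groups: F = 0, p = 1, not significant
  X0 <- cbind(f = c(1, 2, 3, 1, 2, 3))
  expect_equal(unname(anovaFilter(X0, g)$pvalues["f"]), 1)

  # constant feature: defined as not significant
  Xc <- cbind(f = rep(2, 6))
  expect_equal(unname(anovaFilter(Xc, g)$pvalues["f"]), 1)

  # group with < 2 specimens is refused by name
  expect_error(anovaFilter(X, c("a", "a", "a", "a", "a", "b")), "b")

  # F = t^2 equivalence against the pooled-variance t-test oracle
  set.seed(51)
  for (rep in 1:8) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1 + n2)
    gg <- rep(c("a", "b"), c(n1, n2))
    pAnova <- unname(anovaFilter(cbind(f = x), gg)$pvalues["f"])
    tt <- t.test(x ~ gg, var.equal = TRUE)
    expect_equal(pAnova, tt$p.value, tolerance = 1e-9)
  }
})

test_that("correlation de-duplication follows the greedy smaller-p rule", {
  # perfect redundancy: keep the smaller-p feature only
  z <- c(1, 4, 2, 8, 5, 7, 3, 6)
  X <- cbind(A = z, B = 2 * z + 1)
  keep <- correlationDedup(X, c("A", "B"), c(A = 0.01, B = 0.02))
  expect_equal(keep, "A")

  # uncorrelated features are both retained
  set.seed(52)
  w <- c(2, 1, 4, 3, 8, 6, 5, 7)[order(rnorm(8))]
  X2 <- cbind(A = z, C = w)
  r <- abs(pearsonCor(z, w))
  if (r < 0.5)
    expect_setequal(correlationDedup(X2, c("A", "C"),
                                     c(A = 0.01, C = 0.03)), c("A", "C"))

  # three-feature greedy trace: |r(A,B)| high, C independent -> {A, C}
  set.seed(53)
  a <- rnorm(40)
  b <- a + 0.1 * rnorm(40)     # |r| ~ 0.99
  cc <- rnorm(40)              # |r| small with both
  X3 <- cbind(A = a, B = b, C = cc)
  stopifnot(abs(cor(a, b)) > 0.9, abs(cor(a, cc)) < 0.4,
            abs(cor(b, cc)) < 0.4)
  keep3 <- correlationDedup(X3, c("A", "B", "C"),
                            c(A = 0.001, B = 0.002, C = 0.003))
  expect_equal(sort(keep3), c("A", "C"))

  expect_error(correlationDedup(X3, character(), c(A = 1)), "nonempty")
})

test_that("Pearson correlation handles hand cases and degenerate input", {
  expect_equal(pearsonCor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)),
               class = "trflab_undefined_correlation")
  expect_error(pearsonCor(c(1, 2), c(1, 2)), "at least 3")
})

test_that("screening is invariant to specimen order and monotone in
           alphaSig", {
  sizes <- c(esophagus_normal = 10L, dysplastic_BE = 10L)
  lt <- fakeLifetimeTable(sizes, seed = 6)
  # inject a class difference into a few lifetime columns
  sel <- lt$tissue_class == "dysplastic_BE" &
    lt$wavelength_nm %in% c(390, 395, 400)
  lt$tau_avg_ns[sel] <- lt$tau_avg_ns[sel] + 0.4
  ft <- buildFeatureTable(lt)
  X <- featureMatrix(ft)
  labs <- featureLabels(ft)

  scr <- screenFeatures(X, labs)
  set.seed(54)
  perm <- sample(nrow(X))
  scrP <- screenFeatures(X[perm, ], labs[perm])
  expect_equal(featurePValues(scrP), featurePValues(scr))
  expect_identical(retainedFeatures(scrP), retainedFeatures(scr))

  sig05 <- anovaFilter(X, labs, alphaSig = 0.05)$significant
  sig01 <- anovaFilter(X, labs, alphaSig = 0.01)$significant
  expect_true(all(sig01 %in% sig05))
})

test_that("lifetime features dominate screening when classes differ only
           in lifetime", {
  # identical spectra and flat lifetime curves 3.3 vs 2.7 ns: normalized
  # intensities carry no class signal by construction, so intensity
  # features can enter the retained set only as p<0.05 false positives
  spec <- cohortSpec(classSizes = c(esophagus_normal = 10L,
                                    dysplastic_BE = 10L),
                     nSamples = 720L, dt = 0.05)
  co <- simulateCohort(spec, lifetimeOnlyPresets(), seed = 55)
  lt <- processCohort(co)
  ft <- buildFeatureTable(lt)
  scr <- screenFeatures(ft)
  keep <- retainedFeatures(scr)
  pv <- featurePValues(scr)
  expect_true(any(grepl("^lifetime_", keep)))
  # the top-ranked retained feature carries the true signal
  expect_match(keep[which.min(pv[keep])], "^lifetime_")
  # every retained intensity feature is a null false positive: weaker p
  # than every retained lifetime feature, and no more than expected at
  # the 5% screening rate over 37 null features
  iKeep <- keep[grepl("^intensity_", keep)]
  if (length(iKeep))
    expect_gt(min(pv[iKeep]), max(pv[keep[grepl("^lifetime_", keep)]]))
  expect_lte(length(iKeep), 5L)
})
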