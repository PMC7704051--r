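test_that("simulation is deterministic and panels are consistent", {
  cfg <- SimConfig(regionBp = 1e5, nRefSamples = 30L, nTargetSamples = 3L,
                   chipMarkers = 20L, seed = 9L)
  a <- simulatePanels(cfg, method = "mosaic")
  b <- simulatePanels(cfg, method = "mosaic")
  expect_identical(alleles(a$reference), alleles(b$reference))
  expect_identical(alleles(a$targetTruth), alleles(b$targetTruth))

  # shared marker list; targets are not part of the reference
  expect_identical(markers(a$reference), markers(a$targetTruth))
  expect_equal(nHaplotypes(a$reference), 60L)
  expect_equal(nHaplotypes(a$targetTruth), 6L)
  expect_length(intersect(hapIds(a$reference), hapIds(a$targetTruth)), 0L)
  # no monomorphic site in the reference
  af <- altFreq(a$reference)
  expect_true(all(af > 0 & af < 1))
})

test_that("the coalescent backend is reproducible when present", {
  skip_if_not(hasCoalescentBackend(), "no python/msprime available")
  cfg <- SimConfig(regionBp = 1e5, nRefSamples = 25L, nTargetSamples = 2L,
                   seed = 10L)
  a <- simulatePanels(cfg, method = "coalescent")
  b <- simulatePanels(cfg, method = "coalescent")
  expect_identical(alleles(a$reference), alleles(b$reference))
  expect_identical(markers(a$reference)$pos, markers(b$reference)$pos)
})

test_that("the site frequency spectrum is rare-skewed", {
  cfg <- SimConfig(regionBp = 5e5, nRefSamples = 150L, nTargetSamples = 2L,
                   seed = 12L)
  sim <- simulatePanels(cfg)
  maf <- panelMaf(sim$reference)
  counts <- table(cut(maf, seq(0, 0.5, by = 0.1)))
  expect_true(all(diff(as.vector(counts)) <= 0))
})

test_that("chip masking draws among common markers and fails when it cannot", {
  set.seed(61)
  sim <- ldPanels(40, 4, regionBp = 2e5, seed = 13, chipMarkers = 50L)
  cfg <- SimConfig(regionBp = 2e5, nRefSamples = 40L, nTargetSamples = 4L,
                   chipMarkers = 50L, seed = 13L)
  msk <- maskToChip(sim$targetTruth, sim$reference, cfg)
  expect_equal(nMarkers(msk$targetObserved), 50L)
  chipPos <- markers(msk$targetObserved)$pos
  expect_true(all(panelMaf(sim$reference)[match(
    chipPos, markers(sim$reference)$pos)] > 0.05))
  expect_equal(sort(c(match(chipPos, markers(sim$reference)$pos),
                      msk$maskIdx)), seq_len(nMarkers(sim$reference)))

  tooMany <- SimConfig(regionBp = 2e5, nRefSamples = 40L,
                       nTargetSamples = 4L, chipMarkers = 100000L)
  expect_error(maskToChip(sim$targetTruth, sim$reference, tooMany),
               "chip sites")
})

test_that("switch-error injection has the requested rate", {
  set.seed(62)
  sim <- ldPanels(30, 20, regionBp = 2e5, seed = 14)
  tgt <- sim$targetTruth

  same <- injectSwitchErrors(tgt, 0, seed = 1L)
  expect_identical(alleles(same), alleles(tgt))
  expect_equal(attr(same, "realizedRate"), 0)

  full <- injectSwitchErrors(tgt, 1, seed = 1L)
  expect_equal(attr(full, "realizedRate"), 1)
  # genotypes are preserved: switching never changes the unphased dosage
  expect_equal(
    alleles(full)[seq(1, 39, 2), ] + alleles(full)[seq(2, 40, 2), ],
    alleles(tgt)[seq(1, 39, 2), ] + alleles(tgt)[seq(2, 40, 2), ],
    ignore_attr = TRUE)

  some <- injectSwitchErrors(tgt, 0.02, seed = 3L)
  r <- attr(some, "realizedRate")
  nHet <- sum(vapply(seq_len(20), function(s) {
    h <- alleles(tgt)[c(2 * s - 1, 2 * s), ]
    max(0L, sum(h[1, ] != h[2, ]) - 1L)
  }, 0L))
  ci <- qbinom(c(0.0005, 0.9995), nHet, 0.02) / nHet
  expect_gte(r, ci[1]); expect_lte(r, ci[2])
})

test_that("r2 scoring matches hand computation and its invariances", {
  truth <- matrix(c(0, 0, 1, 0, 1, 1), 1)
  probs <- matrix(c(0.1, 0.2, 0.8, 0.0, 0.9, 0.7), 1)
  tab <- scoreR2ByMaf(truth, probs, rep(0.3, 6), bins = c(0, 0.5))
  expect_equal(tab$r2, 0.9483871, tolerance = 1e-6)
  expect_equal(tab$n_alleles, 6L)

  # perfect imputation scores 1 in every populated bin
  set.seed(63)
  tr <- matrix(rbinom(200, 1L, 0.3), 4)
  maf <- runif(50, 0.001, 0.5)
  tab2 <- scoreR2ByMaf(tr, tr, maf)
  ok <- tab2$n_markers > 0 & !is.na(tab2$r2)
  expect_equal(tab2$r2[ok], rep(1, sum(ok)), tolerance = 1e-12)
  # anti-perfect probabilities also score 1 (squared correlation)
  tab3 <- scoreR2ByMaf(tr, 1 - tr, maf)
  expect_equal(tab3$r2, tab2$r2)
  # constant vectors are flagged undefined
  tab4 <- scoreR2ByMaf(matrix(0L, 2, 3), matrix(0.5, 2, 3), rep(0.3, 3))
  expect_true(is.na(tab4$r2[tab4$n_markers > 0]))

  expect_error(scoreR2ByMaf(tr, tr[, -1], maf), "shape")
  expect_error(scoreR2ByMaf(tr, tr, maf[-1]), "length")
})
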