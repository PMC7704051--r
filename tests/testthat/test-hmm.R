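test_that("the switch probability follows the closed form", {
  par <- HmmParameters()
  expect_equal(recombProb(0, 8, par), par@minRho)          # floored at zero gap
  expect_equal(recombProb(0.001, 8, par), 1 - exp(-0.1))   # 4*2e4*1e-5/8 = 0.1
  # monotone decreasing in the number of states
  r <- recombProb(0.01, c(2, 4, 8, 64, 1024), par)
  expect_true(all(diff(r) < 0))
  expect_true(all(diff(recombProb(c(0, .001, .01, .1), 8, par)) > 0))
})

test_that("degenerate chains give trivial posteriors", {
  cm <- c(0, 0.01, 0.02)
  ref1 <- matrix(c(1L, 0L, 1L), 1, 3)
  ps <- forwardBackward(c(1L, 1L, 0L), 0L, ref1, cm)
  expect_equal(as.vector(ps@P), rep(1, 3))
  expect_true(all(ps@stored))   # the argmax state is always retained

  # two identical reference states share the mass evenly
  ref2 <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L))
  ps2 <- forwardBackward(c(1L, 0L, 1L), c(0L, 1L), ref2, cm)
  expect_equal(as.vector(ps2@P), rep(0.5, 6))
  expect_error(forwardBackward(c(1L), integer(0), ref1, 0), "empty")
})

test_that("posteriors equal the dense unscaled forward-backward oracle", {
  set.seed(31)
  for (rep in 1:30) {
    S <- sample(2:16, 1); MT <- sample(2:50, 1)
    ref <- randomPanelMatrix(S, MT)
    tgt <- rbinom(MT, 1L, 0.5)
    cm <- cumsum(runif(MT, 0, 0.02))
    ps <- forwardBackward(tgt, 0:(S - 1), ref, cm, sparsify = FALSE)
    expect_equal(max(abs(colSums(ps@P) - 1)), 0, tolerance = 1e-9)
    po <- oracleForwardBackward(ref, tgt, cm)
    expect_equal(ps@P, po, tolerance = 1e-10)
  }
})

test_that("interpolation is linear in genetic distance", {
  # endpoint: dosage from the left posteriors alone
  expect_equal(interpolateDosage(c(0.7, 0.3), c(0.2, 0.8), 0, c(TRUE, FALSE)),
               0.7)
  # all stored states carry alt: total mass after renormalisation
  expect_equal(interpolateDosage(c(0.2, 0.1), c(0.3, 0.3), 0.4,
                                 c(TRUE, TRUE)), 1)
  # hand case: mass moves from s1 to s2 across the interval
  expect_equal(interpolateDosage(c(1, 0), c(0, 1), 0.5, c(FALSE, TRUE)), 0.5)
})

test_that("diploid conversion multiplies independent haploid probabilities", {
  expect_equal(toDiploid(0, 0), list(DS = 0, GP = cbind(1, 0, 0)))
  expect_equal(toDiploid(1, 1), list(DS = 2, GP = cbind(0, 0, 1)))
  d <- toDiploid(0.5, 0.5)
  expect_equal(d$DS, 1)
  expect_equal(as.vector(d$GP), c(0.25, 0.5, 0.25))
  expect_equal(rowSums(toDiploid(runif(5), runif(5))$GP), rep(1, 5))
})

test_that("the lazy path is exactly the full computation", {
  set.seed(33)
  sim <- ldPanels(60, 2, regionBp = 1e5, seed = 17, chipMarkers = 30L)
  ref <- sim$reference
  chip <- sort(sample(which(panelMaf(ref) > 0.05), 30L))
  refT <- ref[, chip]
  un <- setdiff(seq_len(nMarkers(ref)), chip)
  tgt <- alleles(sim$targetTruth)[1, chip]

  sel <- runSelection(refT, sim$targetTruth[1, chip],
                      SelectionConfig(L = 4L, I = 0.005))
  ps <- forwardBackward(tgt, sel$stateLists[[1]], refT, markers(refT)$cm)
  store <- imp5Records(ref, un)
  af <- altFreq(ref)[un]
  meta <- data.frame(pos = markers(ref)$pos[un], cm = markers(ref)$cm[un],
                     altFreq = af)
  dLazy <- lazyImputeWindow(ps, store, meta, markers(refT)$pos,
                            markers(refT)$cm, lazy = TRUE)
  dFull <- lazyImputeWindow(ps, store, meta, markers(refT)$pos,
                            markers(refT)$cm, lazy = FALSE)
  expect_identical(dLazy, dFull)

  # untyped marker whose carriers are disjoint from every stored state:
  # exactly zero through the fast path
  rare <- which(af < 1 / 256)
  if (length(rare)) {
    stored <- ps@states[rowSums(ps@stored) > 0]
    disjoint <- rare[vapply(rare, function(u)
      length(carriersAt(store, u, stored)) == 0L, TRUE)]
    expect_true(all(dLazy[disjoint] == 0))
  }

  badMeta <- meta[rev(seq_len(nrow(meta))), ]
  expect_error(lazyImputeWindow(ps, store, badMeta, markers(refT)$pos,
                                markers(refT)$cm), "out of order")
})

test_that("sparsification changes dosages by at most the dropped flank mass", {
  set.seed(34)
  S <- 12; MT <- 25
  ref <- randomPanelMatrix(S, MT, 0.3)
  tgt <- rbinom(MT, 1L, 0.3)
  cm <- cumsum(runif(MT, 0, 0.01))
  psDense <- forwardBackward(tgt, 0:(S - 1), ref, cm, sparsify = FALSE)
  psSparse <- forwardBackward(tgt, 0:(S - 1), ref, cm, sparsify = TRUE)
  for (m in seq_len(MT - 1)) {
    keep <- psSparse@stored[, m] | psSparse@stored[, m + 1]
    for (w in c(0.25, 0.75)) {
      carriers <- ref[, m] == 1L   # any carrier pattern over the states
      dDense <- sum(((1 - w) * psDense@P[, m] + w * psDense@P[, m + 1])[carriers])
      dSparse <- interpolateDosage(psSparse@P[keep, m],
                                   psSparse@P[keep, m + 1], w,
                                   carriers[keep])
      dropped <- (1 - w) * (1 - sum(psSparse@P[keep, m])) +
        w * (1 - sum(psSparse@P[keep, m + 1]))
      expect_lte(abs(dSparse - dDense), dropped + 1e-12)
    }
  }
})
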