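# build the final PBWT column of a panel and insert a target, returning
# everything a selection event needs
selectionContext <- function(H, tgt) {
  N <- nrow(H); M <- ncol(H)
  col <- pbwtInit(N); f <- 0L
  for (m in seq_len(M)) {
    col <- pbwtAdvance(col, H[, m])
    f <- insertTarget(f, col, tgt[m])
  }
  dup <- if (f > 0) prefixMatchStart(H[col@A[f] + 1L, ], tgt, M - 1L)
         else M + 1L
  ddn <- if (f < N) prefixMatchStart(H[col@A[f + 1L] + 1L, ], tgt, M - 1L)
         else M + 1L
  list(col = col, f = f, dup = dup, ddn = ddn)
}

test_that("selection markers follow the greedy interval rule", {
  expect_equal(selectionMarkers(c(0, 0.01, 0.02, 0.03, 0.05), 0.02),
               c(1L, 3L, 5L))
  expect_equal(selectionMarkers(0.3, 0.02), 1L)
  # interval larger than the window span: endpoints only
  expect_equal(selectionMarkers(seq(0, 0.05, by = 0.01), 1), c(1L, 6L))
})

test_that("divergence selection finds the longest-match state", {
  set.seed(11)
  # L >= N selects everything
  H <- randomPanelMatrix(6, 15)
  ctx <- selectionContext(H, rbinom(15, 1L, 0.5))
  sel <- divergenceSelect(ctx$f, ctx$col@A, ctx$col@D, ctx$dup, ctx$ddn, 10L)
  expect_setequal(sel, 0:5)

  # a target equal to one reference haplotype selects it with L = 1
  k <- 2L
  ctx <- selectionContext(H, H[k + 1L, ])
  sel1 <- divergenceSelect(ctx$f, ctx$col@A, ctx$col@D, ctx$dup, ctx$ddn, 1L)
  expect_equal(sel1, k)

  # random panels: the selected set contains a longest-match haplotype
  for (rep in 1:20) {
    N <- sample(6:32, 1); M <- sample(10:64, 1)
    H <- randomPanelMatrix(N, M)
    tgt <- rbinom(M, 1L, 0.5)
    ctx <- selectionContext(H, tgt)
    sel <- divergenceSelect(ctx$f, ctx$col@A, ctx$col@D, ctx$dup, ctx$ddn, 4L)
    lens <- vapply(seq_len(N), function(h)
      M - oracleMatchStart(H[h, ], tgt, M), 0)
    expect_true(any(which(lens == max(lens)) - 1L %in% sel))
    expect_true(all(sel %in% 0:(N - 1)))
    expect_false(any(duplicated(sel)))
  }
})

test_that("neighbour selection clips at borders and respects quotas", {
  A <- 0:9
  expect_equal(sort(neighbourSelect(0L, A, 4L)), c(0L, 1L))  # border: < L states
  expect_equal(sort(neighbourSelect(10L, A, 4L)), c(8L, 9L)) # other border
  expect_setequal(neighbourSelect(2L, 0:3, 8L), 0:3)         # clamped to panel
  expect_equal(sort(neighbourSelect(5L, A, 4L)), c(3L, 4L, 5L, 6L))

  # the two A-adjacent haplotypes around f include the longest match
  set.seed(12)
  for (rep in 1:10) {
    N <- sample(6:24, 1); M <- sample(10:40, 1)
    H <- randomPanelMatrix(N, M)
    tgt <- rbinom(M, 1L, 0.5)
    ctx <- selectionContext(H, tgt)
    sel <- neighbourSelect(ctx$f, ctx$col@A, 2L)
    lens <- vapply(seq_len(N), function(h)
      M - oracleMatchStart(H[h, ], tgt, M), 0)
    expect_true(any(which(lens == max(lens)) - 1L %in% sel))
  }
})

test_that("the mismatch guard extends the matching side", {
  # A-order around slot f = 2: up candidates A[1]=3, A[0]=5; down A[2]=8
  A <- c(5L, 3L, 8L, 1L, 4L)
  # allele of haplotype h at the selection marker is colAll[h + 1]
  colAll <- c(0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L)  # h3=1, h5=1, h8=1
  s <- neighbourSelect(2L, A, 2L, guard = TRUE, columnAlleles = colAll,
                       tAllele = 1L)
  expect_setequal(s, c(3L, 8L))  # both sides match: plain L/2 each way
  # down candidate 8 now mismatches while the up side still matches:
  # the mismatch position is skipped and the up side extended to A[0]=5
  colAll2 <- colAll; colAll2[9] <- 0L
  s2 <- neighbourSelect(2L, A, 2L, guard = TRUE, columnAlleles = colAll2,
                        tAllele = 1L)
  expect_setequal(s2, c(3L, 5L))
})

test_that("one streaming pass selects states for all targets at once", {
  set.seed(13)
  sim <- ldPanels(30, 3, regionBp = 1e5, seed = 5, chipMarkers = 40L)
  ref <- sim$reference
  chip <- sort(sample(which(panelMaf(ref) > 0.05), 40L))
  refT <- ref[, chip]
  tgtT <- sim$targetTruth[, chip]

  # K=1, L >= N recovers the full reference panel
  res <- runSelection(refT, tgtT[1, ], SelectionConfig(L = 1000L, I = 0.01))
  expect_equal(res$stateLists[[1]]@states, 0:(nHaplotypes(refT) - 1L))

  # a target that is an exact copy of reference haplotype k stays adjacent
  # to it: k is picked at (almost) every event; near the window start a
  # reverse-prefix tie with another haplotype may legitimately displace it
  k <- 7L
  copyTgt <- refT[k + 1L, ]
  copyTgt@hapIds <- "copy_1"
  res2 <- runSelection(refT, copyTgt, SelectionConfig(L = 2L, I = 0.01))
  sl <- res2$stateLists[[1]]
  expect_true(k %in% sl@states)
  expect_gte(sl@eventCounts[match(k, sl@states)],
             length(res2$selIdx) - 2L)

  # merged lists are sorted, duplicate-free subsets of the panel
  res3 <- runSelection(refT, tgtT, SelectionConfig(L = 4L, I = 0.005))
  for (sl in res3$stateLists) {
    expect_false(is.unsorted(sl@states, strictly = TRUE))
    expect_true(all(sl@states >= 0 & sl@states < nHaplotypes(refT)))
    expect_true(all(sl@eventCounts >= 1))
  }
  # insertion trace is within bounds at every selection marker
  expect_true(all(res3$fTrace >= 0 & res3$fTrace <= nHaplotypes(refT)))
})

test_that("the compiled sweep agrees with composed single-marker operations", {
  set.seed(14)
  for (method in c("neighbour", "divergence")) {
    N <- 20; M <- 50; K <- 3
    H <- randomPanelMatrix(N, M, 0.4)
    Tg <- randomPanelMatrix(K, M, 0.4)
    cm <- cumsum(runif(M, 0, 0.01))
    refT <- panelFromMatrix(H, cm = cm)
    tgtT <- panelFromMatrix(Tg, cm = cm)
    cfg <- SelectionConfig(L = 4L, I = 0.02, method = method,
                           mismatchGuard = FALSE)
    swept <- runSelection(refT, tgtT, cfg)

    sel <- selectionMarkers(cm, cfg@I)
    for (t in seq_len(K)) {
      col <- pbwtInit(N); f <- 0L
      picked <- integer(0)
      for (m in seq_len(M)) {
        col <- pbwtAdvance(col, H[, m])
        f <- insertTarget(f, col, Tg[t, m])
        if (m %in% sel) {
          if (method == "divergence") {
            dup <- if (f > 0)
              prefixMatchStart(H[col@A[f] + 1L, ], Tg[t, ], m - 1L)
            else m + 1L
            ddn <- if (f < N)
              prefixMatchStart(H[col@A[f + 1L] + 1L, ], Tg[t, ], m - 1L)
            else m + 1L
            picked <- c(picked, divergenceSelect(f, col@A, col@D, dup, ddn,
                                                 cfg@L))
          } else {
            picked <- c(picked, neighbourSelect(f, col@A, cfg@L))
          }
        }
      }
      expect_identical(swept$stateLists[[t]]@states, sort(unique(picked)))
    }
  }
})
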