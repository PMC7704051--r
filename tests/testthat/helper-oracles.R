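# Independent brute-force oracles. These deliberately avoid the package's
# own PBWT/HMM code paths: sorting is done on reverse-prefix strings, the
# forward-backward uses explicit dense transition matrices, interpolation
# is recomputed from first principles.

randomPanelMatrix <- function(N, M, p = 0.5) {
  matrix(rbinom(N * M, 1L, p), N, M)
}

# reverse-prefix sort keys after marker m (1-based), built incrementally
oracleKeys <- function(H) {
  keys <- rep("", nrow(H))
  out <- vector("list", ncol(H))
  for (m in seq_len(ncol(H))) {
    keys <- paste0(H[, m], keys)
    out[[m]] <- keys
  }
  out
}

oraclePrefixArray <- function(keys) order(keys, method = "radix") - 1L

oracleTargetKey <- function(tgt, m) paste(rev(tgt[seq_len(m)]), collapse = "")

# start of the maximal common reverse prefix of rows x, y ending at m (1-based
# marker count m; returns 0-based start)
oracleMatchStart <- function(x, y, m) {
  s <- m
  for (k in m:1) {
    if (x[k] != y[k]) break
    s <- k - 1L
  }
  s
}

# dense O(S^2 M) forward-backward with explicit transition matrices and no
# rescaling (small instances only)
oracleForwardBackward <- function(ref, tgt, cm, Ne = 20000, minRho = 1e-9,
                                  eMatch = 0.9999, eMismatch = 1e-4) {
  S <- nrow(ref); MT <- ncol(ref)
  em <- ifelse(ref == matrix(tgt, S, MT, byrow = TRUE), eMatch, eMismatch)
  rho <- function(gap) max(minRho, 1 - exp(-4 * Ne * (gap / 100) / S))
  f <- matrix(0, S, MT); b <- matrix(0, S, MT)
  f[, 1] <- em[, 1] / S
  if (MT > 1) {
    for (m in 2:MT) {
      r <- rho(cm[m] - cm[m - 1])
      Tm <- matrix(r / S, S, S); diag(Tm) <- (1 - r) + r / S
      f[, m] <- em[, m] * as.vector(t(Tm) %*% f[, m - 1])
    }
  }
  b[, MT] <- 1
  if (MT > 1) {
    for (m in (MT - 1):1) {
      r <- rho(cm[m + 1] - cm[m])
      Tm <- matrix(r / S, S, S); diag(Tm) <- (1 - r) + r / S
      b[, m] <- as.vector(Tm %*% (em[, m + 1] * b[, m + 1]))
    }
  }
  P <- f * b
  sweep(P, 2, colSums(P), "/")
}

# first-principles interpolation of haploid dosages at untyped markers from
# a full (unthresholded) posterior matrix
oracleInterpolate <- function(P, refAll, typedIdx, cm) {
  M <- ncol(refAll)
  untyped <- setdiff(seq_len(M), typedIdx)
  tcm <- cm[typedIdx]
  out <- numeric(length(untyped))
  for (i in seq_along(untyped)) {
    u <- untyped[i]
    l <- findInterval(u, typedIdx)   # typed markers left of u (positions)
    carriers <- refAll[, u] == 1L
    if (l == 0L) {
      p <- P[, 1]
    } else if (l == length(typedIdx)) {
      p <- P[, l]
    } else {
      gap <- tcm[l + 1] - tcm[l]
      w <- if (gap > 0) (cm[u] - tcm[l]) / gap else 0.5
      p <- (1 - w) * P[, l] + w * P[, l + 1]
    }
    out[i] <- sum(p[carriers])
  }
  out
}

countRuns <- function(x) 1L + sum(x[-1] != x[-length(x)])

# small LD-structured panel via the package's mosaic generator
ldPanels <- function(nRef, nTgt, regionBp = 2e5, seed = 1L,
                     chipMarkers = 60L) {
  cfg <- SimConfig(regionBp = regionBp, nRefSamples = nRef,
                   nTargetSamples = nTgt, chipMarkers = chipMarkers,
                   seed = seed)
  simulatePanels(cfg, method = "mosaic")
}
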