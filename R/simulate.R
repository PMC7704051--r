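#' Simulation configuration
#'
#' Study conditions for the synthetic experiment: a coalescent-like
#' haplotype panel over a region, chip-site masking among common markers,
#' and switch-error injection in the targets. Defaults follow a
#' human-like parameterisation: \code{Ne = 10000}, mutation rate
#' \code{mu = 1.25e-8}/bp, recombination \code{rec = 1e-8}/bp (1 cM/Mb),
#' one chip marker per 3 kb among markers with reference MAF above 5%, and
#' a 2% switch-error rate.
#'
#' @param regionBp region length in bp (default 2e6).
#' @param nRefSamples,nTargetSamples diploid sample counts.
#' @param chipMafBound minimum reference MAF of chip sites (default 0.05).
#' @param chipMarkers number of chip markers (default \code{NA}: one per
#'   3 kb of region).
#' @param switchErrorRate per-het-site switch probability (default 0.02).
#' @param Ne,mu,rec generator population parameters (see above).
#' @param n0,growth present-day size and growth rate of the coalescent
#'   demography. The defaults (1.5e6, 0.03/generation, decaying back to
#'   the ancestral size ~167 generations ago) emulate the recent explosive
#'   growth of European-ancestry cohorts; they reproduce both the marker
#'   density of modern sequencing panels (~22 segregating sites per kb in
#'   a 10,000-sample panel) and its scaling with panel size (x3.3 from a
#'   10,000- to a 100,000-sample panel).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SimConfig}}
#' @export
SimConfig <- function(regionBp = 2e6, nRefSamples = 100L,
                      nTargetSamples = 10L, chipMafBound = 0.05,
                      chipMarkers = NA_integer_, switchErrorRate = 0.02,
                      Ne = 10000, n0 = 1.5e6, growth = 0.03,
                      mu = 1.25e-8, rec = 1e-8, seed = 1L) {
  if (is.na(chipMarkers)) chipMarkers <- as.integer(round(regionBp / 3000))
  new("SimConfig", regionBp = regionBp,
      nRefSamples = as.integer(nRefSamples),
      nTargetSamples = as.integer(nTargetSamples),
      chipMafBound = chipMafBound, chipMarkers = as.integer(chipMarkers),
      switchErrorRate = switchErrorRate, Ne = Ne, n0 = n0, growth = growth,
      mu = mu, rec = rec, seed = as.integer(seed))
}

simEnv <- new.env(parent = emptyenv())

#' Is the coalescent simulation backend available?
#'
#' True when a \code{python} with the \code{msprime} module can be invoked;
#' the result is cached for the session.
#' @return logical
#' @export
hasCoalescentBackend <- function() {
  if (!is.null(simEnv$hasMsprime)) return(simEnv$hasMsprime)
  py <- Sys.which("python")
  ok <- nzchar(py) && {
    st <- try(suppressWarnings(system2(
      py, c("-c", shQuote("import msprime")),
      stdout = FALSE, stderr = FALSE)), silent = TRUE)
    identical(st, 0L)
  }
  simEnv$hasMsprime <- isTRUE(ok)
  simEnv$hasMsprime
}

coalescentPanel <- function(cfg, nHap) {
  py <- Sys.which("python")
  script <- system.file("python", "coalescent_sim.py",
                        package = "pbwtimpute")
  out <- tempfile("coalsim")
  on.exit(unlink(paste0(out, c(".pos", ".mat"))), add = TRUE)
  pySeed <- sample.int(2147483645L, 1L)
  status <- system2(py, c(shQuote(script),
                          "--n-samples", nHap %/% 2L,
                          "--region-bp", format(cfg@regionBp, scientific = FALSE),
                          "--mu", cfg@mu, "--rec", cfg@rec,
                          "--ne-ancestral", cfg@Ne,
                          "--n0", cfg@n0, "--growth", cfg@growth,
                          "--seed", pySeed,
                          "--out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("coalescent simulation backend failed")
  pos <- as.integer(readLines(paste0(out, ".pos")))
  M <- length(pos)
  H <- readBin(paste0(out, ".mat"), "raw", as.numeric(nHap) * M)
  dim(H) <- c(nHap, M)  # in place; avoids duplicating a large panel
  list(H = H, pos = pos)
}

mosaicPanel <- function(cfg, nHap) {
  theta <- 4 * cfg@Ne * cfg@mu * cfg@regionBp
  # mutation counts per haplotype ~ Poisson(theta / k); haplotype 1 gets
  # the theta "oldest" mutations so the spectrum has a common tail
  lam <- theta / c(1, seq_len(nHap - 1L))
  nMut <- stats::rpois(nHap, lam)
  M <- sum(nMut)
  if (M < 2L) stop("degenerate simulation: fewer than two segregating sites")
  pos <- sort(sample.int(cfg@regionBp, M))
  birth <- rep(seq_len(nHap) - 1L, nMut)
  birth <- birth[sample.int(M)]  # mutation age is independent of position
  list(H = cpp_mosaic_panel(nHap, as.numeric(pos), birth, cfg@Ne, cfg@rec),
       pos = pos)
}

#' Simulate reference and target haplotype panels
#'
#' Draws one coalescent-like sample of \code{2*(nRefSamples +
#' nTargetSamples)} haplotypes over the region, then assigns a random
#' subset of samples as targets and removes them from the reference; sites
#' monomorphic in the reference are dropped. Genetic positions are
#' assigned at the generator's own constant rate (\code{rec} per bp).
#'
#' Two backends implement the draw. The preferred \code{"coalescent"}
#' backend runs msprime (via python) under a single-population
#' exponential-growth demography (ancestral size \code{Ne}, present size
#' \code{n0}, growth rate \code{growth}); it produces a realistic
#' rare-skewed site frequency spectrum with the marker density of modern
#' sequencing panels. The \code{"mosaic"} fallback is a sequential
#' conditional-sampling generator (a Li & Stephens mosaic with mutation):
#' haplotype k is an imperfect mosaic of the k-1 haplotypes generated
#' before it, with segment switches at rate \code{4*Ne*rec/k} per bp and
#' new mutations assigned to haplotype k with probability proportional to
#' \code{1/k}; it needs no external tools but approximates a constant-size
#' coalescent, so it carries fewer rare variants. \code{"auto"} uses the
#' coalescent backend when available.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param method \code{"auto"}, \code{"coalescent"} or \code{"mosaic"}.
#' @return list with \code{reference} and \code{targetTruth} panels sharing
#'   one marker list; attribute \code{"backend"} names the generator used.
#' @export
simulatePanels <- function(cfg, method = c("auto", "coalescent", "mosaic")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (hasCoalescentBackend()) "coalescent" else "mosaic"
  if (method == "coalescent" && !hasCoalescentBackend())
    stop("coalescent backend requested but python/msprime is not available")
  set.seed(cfg@seed)
  nHap <- 2L * (cfg@nRefSamples + cfg@nTargetSamples)
  gen <- if (method == "coalescent") coalescentPanel(cfg, nHap)
         else mosaicPanel(cfg, nHap)
  H <- gen$H
  pos <- gen$pos

  # random sample-to-role assignment (samples = consecutive hap pairs)
  nSamp <- nHap %/% 2L
  perm <- sample.int(nSamp)
  tgtSamp <- perm[seq_len(cfg@nTargetSamples)]
  refSamp <- perm[-seq_len(cfg@nTargetSamples)]
  hapsOf <- function(s) as.vector(rbind(2L * s - 1L, 2L * s))
  refRows <- hapsOf(sort(refSamp))
  tgtRows <- hapsOf(sort(tgtSamp))

  cmv <- (pos - pos[1]) * cfg@rec * 1e8 * 1e-6  # rec per bp -> cM
  mk <- data.frame(chrom = "1", pos = as.integer(pos),
                   ref = "A", alt = "C", cm = cmv,
                   stringsAsFactors = FALSE)
  refAltN <- cpp_alt_counts(H, refRows - 1L)
  poly <- which(refAltN > 0L & refAltN < length(refRows))
  mk <- mk[poly, , drop = FALSE]
  refIds <- as.vector(rbind(paste0("ref", sort(refSamp), "_1"),
                            paste0("ref", sort(refSamp), "_2")))
  tgtIds <- as.vector(rbind(paste0("tgt", sort(tgtSamp), "_1"),
                            paste0("tgt", sort(tgtSamp), "_2")))
  # subset rows and polymorphic columns in one pass each, then release H
  refH <- H[refRows, poly, drop = FALSE]
  tgtH <- H[tgtRows, poly, drop = FALSE]
  rm(H)
  out <- list(reference = HaplotypePanel(refH, mk, refIds),
              targetTruth = HaplotypePanel(tgtH, mk, tgtIds))
  attr(out, "backend") <- method
  out
}

#' Mask target markers down to a chip
#'
#' Retains a random subset of markers with reference MAF above the chip
#' bound (the simulated genotyping array); all other markers form the
#' evaluation mask.
#'
#' @param targetTruth target panel at all markers.
#' @param reference reference panel (MAFs are measured here).
#' @param cfg a \code{\linkS4class{SimConfig}} (\code{chipMarkers},
#'   \code{chipMafBound}).
#' @return list with \code{targetObserved} (panel at chip markers) and
#'   \code{maskIdx} (1-based indices of masked markers).
#' @export
maskToChip <- function(targetTruth, reference, cfg) {
  maf <- panelMaf(reference)
  eligible <- which(maf > cfg@chipMafBound)
  if (length(eligible) < cfg@chipMarkers)
    stop(sprintf("only %d markers exceed MAF %g; cannot place %d chip sites",
                 length(eligible), cfg@chipMafBound, cfg@chipMarkers))
  chip <- sort(sample(eligible, cfg@chipMarkers))
  list(targetObserved = targetTruth[, chip],
       maskIdx = setdiff(seq_len(nMarkers(targetTruth)), chip))
}

#' Inject switch errors into phased targets
#'
#' Emulates phasing error: per sample, at every heterozygous site after the
#' first, the remainder of the two haplotypes is swapped with the given
#' probability. The realised switch-error rate (switches per het-site
#' opportunity) is attached as attribute \code{"realizedRate"}.
#'
#' @param panel target panel (haplotype pairs).
#' @param rate switch probability per heterozygous site.
#' @param seed RNG seed.
#' @return the panel with errors injected.
#' @export
injectSwitchErrors <- function(panel, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  N <- nHaplotypes(panel)
  if (N %% 2L != 0L) stop("panel must contain haplotype pairs")
  a <- panel@alleles
  nSwitch <- 0L; nOpp <- 0L
  for (s in seq_len(N %/% 2L)) {
    h1 <- a[2L * s - 1L, ]; h2 <- a[2L * s, ]
    het <- which(h1 != h2)
    if (length(het) < 2L) next
    opp <- het[-1L]
    flips <- stats::runif(length(opp)) < rate
    nSwitch <- nSwitch + sum(flips)
    nOpp <- nOpp + length(opp)
    if (!any(flips)) next
    # cumulative parity: swapped from each flipped het site onward
    parity <- cumsum(c(0L, as.integer(flips))) %% 2L
    swapState <- integer(ncol(a))
    swapState[het[1L]:ncol(a)] <- parity[findInterval(
      het[1L]:ncol(a), het)]
    swap <- swapState == 1L
    tmp <- h1[swap]
    h1[swap] <- h2[swap]
    h2[swap] <- tmp
    a[2L * s - 1L, ] <- h1
    a[2L * s, ] <- h2
  }
  out <- new("HaplotypePanel", alleles = a, markers = panel@markers,
             hapIds = panel@hapIds)
  attr(out, "realizedRate") <- if (nOpp > 0L) nSwitch / nOpp else 0
  out
}

#' Default MAF bin edges for accuracy scoring
#'
#' Log-spaced edges partitioning (0, 0.5]; bins are left-open/right-closed,
#' so the bin containing frequency 1e-4 is (5e-5, 2e-4].
#'
#' @return numeric vector of bin edges.
#' @export
mafBins <- function() {
  c(0, 5e-5, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 2e-2, 5e-2, 0.1, 0.2, 0.5)
}

#' MAF-binned imputation accuracy (aggregate r-squared)
#'
#' Markers are binned by their reference-panel minor allele frequency;
#' within each bin all (true allele, imputed probability) pairs across
#' markers and target haplotypes are concatenated and the squared Pearson
#' correlation of the two vectors is reported. Bins where either vector is
#' constant are flagged undefined (\code{NA}).
#'
#' @param truth integer matrix (target haplotypes x masked markers) of true
#'   alleles.
#' @param imputed numeric matrix of the same shape: haploid alt
#'   probabilities.
#' @param refMaf per-masked-marker reference MAF.
#' @param bins bin edges (default \code{\link{mafBins}}).
#' @return data.frame with bin_low, bin_high, n_alleles, n_markers, r2.
#' @export
scoreR2ByMaf <- function(truth, imputed, refMaf, bins = mafBins()) {
  if (!all(dim(truth) == dim(imputed)))
    stop("truth and imputed must have identical shape")
  if (length(refMaf) != ncol(truth))
    stop("refMaf length must equal the number of masked markers")
  bin <- findInterval(refMaf, bins, left.open = TRUE)
  out <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                    n_alleles = 0L, n_markers = 0L, r2 = NA_real_)
  for (b in seq_len(nrow(out))) {
    cols <- which(bin == b)
    if (!length(cols)) next
    tv <- as.vector(truth[, cols])
    pv <- as.vector(imputed[, cols])
    out$n_alleles[b] <- length(tv)
    out$n_markers[b] <- length(cols)
    if (stats::sd(tv) > 0 && stats::sd(pv) > 0)
      out$r2[b] <- stats::cor(tv, pv)^2
  }
  out
}
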