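#' Imputation window plan
#'
#' A core region (1-based, inclusive) plus a flanking buffer: typed markers
#' inside the buffered region condition the HMM, but only core-region
#' markers are emitted, so adjacent windows concatenate exactly.
#'
#' @slot chrom character.
#' @slot start,end integer, core region bounds.
#' @slot buffer numeric, buffer size in bp on each side (default 1 Mb).
#' @exportClass WindowPlan
setClass("WindowPlan",
  representation(chrom = "character", start = "integer", end = "integer",
                 buffer = "numeric"))

#' @rdname WindowPlan-class
#' @param region \code{"chrom:start-end"} core region string.
#' @param bufferBp buffer in bp on each side.
#' @return a \code{WindowPlan}
#' @export
WindowPlan <- function(region, bufferBp = 1e6) {
  r <- parseRegion(region)
  stopifnot(bufferBp >= 0)
  new("WindowPlan", chrom = r$chrom, start = r$start, end = r$end,
      buffer = as.numeric(bufferBp))
}

#' @rdname WindowPlan-class
#' @param plan a \code{WindowPlan}
#' @export
effectiveRegion <- function(plan) {
  sprintf("%s:%d-%d", plan@chrom,
          max(1, plan@start - as.integer(plan@buffer)),
          min(.Machine$integer.max, plan@end + as.integer(plan@buffer)))
}

loadPanel <- function(x, region = NULL) {
  if (is(x, "HaplotypePanel")) {
    if (!is.null(region)) {
      r <- parseRegion(region)
      keep <- which(x@markers$chrom == r$chrom &
                    x@markers$pos >= r$start & x@markers$pos <= r$end)
      return(x[, keep])
    }
    return(x)
  }
  if (!is.character(x)) stop("expected a HaplotypePanel or a file path")
  magic <- readBin(x, "raw", 8L)
  if (identical(magic, IMP5_MAGIC)) readImp5(x, region)
  else readVcfPanel(x, region)
}

#' Impute target haplotypes in one window
#'
#' The full per-window pipeline: load the reference and target panels over
#' the buffered region, attach genetic positions, partition markers into
#' typed and untyped sets, select copying states per target with the
#' streaming PBWT, run the haploid copying HMM over the selected states at
#' typed markers, interpolate sparsified posteriors to untyped markers
#' (with the delayed lazy path for rare variants), and return per-haplotype
#' alt-allele probabilities for the core-region markers. The computation is
#' deterministic: no randomness is involved.
#'
#' @param reference reference panel: \code{\linkS4class{HaplotypePanel}},
#'   VCF path, or IMP5LITE path.
#' @param targets phased target panel at the chip markers: panel or VCF
#'   path.
#' @param map a \code{\linkS4class{GeneticMap}}, a map file path, or
#'   \code{NULL} for the constant 1 cM/Mb fallback (logged).
#' @param plan a \code{\linkS4class{WindowPlan}} or region string;
#'   \code{NULL} imputes the panels' full extent with no buffer.
#' @param selection a \code{\linkS4class{SelectionConfig}}.
#' @param params an \code{\linkS4class{HmmParameters}}.
#' @param lazy use delayed lazy imputation for rare untyped variants.
#' @param sparsify apply the posterior storage threshold.
#' @param verbose emit a structured log via \code{message()}.
#' @return an \code{\linkS4class{ImputationResult}} restricted to the core
#'   region.
#' @export
imputeWindow <- function(reference, targets, map = NULL, plan = NULL,
                         selection = SelectionConfig(),
                         params = HmmParameters(), lazy = TRUE,
                         sparsify = TRUE, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(plan)) plan <- WindowPlan(plan, bufferBp = 0)
  eff <- if (is.null(plan)) NULL else effectiveRegion(plan)
  ref <- loadPanel(reference, eff)
  tgt <- loadPanel(targets, eff)
  if (nMarkers(ref) == 0L) stop("no reference markers in window")
  if (nMarkers(tgt) == 0L) stop("no target markers in window")
  if (ref@markers$chrom[1] != tgt@markers$chrom[1])
    stop("reference and target are on different chromosomes")

  if (is.character(map)) map <- readGeneticMap(map)
  if (!is.null(map)) {
    ref <- attachGeneticMap(ref, map)
  } else if (anyNA(ref@markers$cm)) {
    if (verbose)
      message("impute: no genetic map; constant 1 cM/Mb fallback applied")
    ref <- attachGeneticMap(ref, NULL)
  }

  part <- partitionMarkers(ref, tgt)
  refTyped <- ref[, part@typedIdx]
  tgtTyped <- tgt[, part@targetCols]
  selRes <- runSelection(refTyped, tgtTyped, selection)
  K <- nHaplotypes(tgtTyped)
  M <- nMarkers(ref)
  MT <- length(part@typedIdx)

  untyped <- part@untypedIdx
  store <- imp5Records(ref, untyped)
  af <- altFreq(ref)[untyped]
  rare <- pmin(af, 1 - af) < SPARSE_BOUND
  iv <- untypedIntervals(refTyped@markers$pos, refTyped@markers$cm,
                         ref@markers$pos[untyped], ref@markers$cm[untyped])

  dosage <- matrix(0, nrow = K, ncol = M)
  tgtA <- alleles(tgtTyped)
  for (t in seq_len(K)) {
    res <- cpp_impute_target(refTyped@alleles,
                             selRes$stateLists[[t]]@states,
                             tgtA[t, ], refTyped@markers$cm,
                             params@Ne, params@minRho,
                             params@eMatch, params@eMismatch, sparsify,
                             store$data, store$tag,
                             iv$leftFlank, iv$weight, rare, lazy, FALSE)
    dosage[t, part@typedIdx] <- res$dosTyped
    dosage[t, untyped] <- res$dosUntyped
  }

  mk <- ref@markers
  mk$typed <- seq_len(M) %in% part@typedIdx
  core <- if (is.null(plan)) seq_len(M)
          else which(mk$pos >= plan@start & mk$pos <= plan@end)
  typedCore <- match(part@typedIdx[part@typedIdx %in% core],
                     part@typedIdx)
  elapsed <- proc.time()[["elapsed"]] - t0
  stats <- list(meanStates = selRes$meanStates,
                nTyped = MT, nUntyped = length(untyped),
                nSelectionMarkers = length(selRes$selIdx),
                elapsed = elapsed)
  if (verbose) {
    message(sprintf(
      "impute: K=%d N=%d markers=%d typed=%d selection=%s L=%d I=%g meanStates=%.1f elapsed=%.1fs",
      K, nHaplotypes(ref), M, MT, selection@method, selection@L,
      selection@I, selRes$meanStates, elapsed))
  }
  new("ImputationResult",
      markers = mk[core, , drop = FALSE],
      dosage = dosage[, core, drop = FALSE],
      typedAlleles = tgtTyped@alleles[, typedCore, drop = FALSE],
      hapIds = tgt@hapIds,
      stats = stats)
}

#' Write an imputation result as VCF 4.2
#'
#' One sample per target haplotype pair. INFO carries \code{TYPED} or
#' \code{IMP}; FORMAT is \code{GT:DS:GP:AP}: phased genotype (observed at
#' typed markers, per-haplotype hard call at imputed ones), diploid dosage
#' (3 decimals), genotype probabilities (3 decimals), and the two haploid
#' alt probabilities. Output is byte-deterministic given the result.
#'
#' @param result an \code{\linkS4class{ImputationResult}}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeImputedVcf <- function(result, path) {
  mk <- result@markers
  dos <- result@dosage
  K <- nrow(dos)
  if (K %% 2L != 0L) stop("target haplotypes must come in pairs")
  samples <- sub("_1$", "", result@hapIds[seq(1L, K, by = 2L)])
  i1 <- seq(1L, K, by = 2L); i2 <- seq(2L, K, by = 2L)
  M <- nrow(mk)
  p1 <- t(dos[i1, , drop = FALSE])  # markers x samples
  p2 <- t(dos[i2, , drop = FALSE])
  ds <- p1 + p2
  gpRR <- (1 - p1) * (1 - p2)
  gpRA <- p1 * (1 - p2) + p2 * (1 - p1)
  gpAA <- p1 * p2
  a1 <- matrix(as.integer(p1 > 0.5), nrow = M)
  a2 <- matrix(as.integer(p2 > 0.5), nrow = M)
  if (any(mk$typed)) {
    ta <- matrix(as.integer(result@typedAlleles), nrow = K)
    a1[mk$typed, ] <- t(ta[i1, , drop = FALSE])
    a2[mk$typed, ] <- t(ta[i2, , drop = FALSE])
  }
  cells <- matrix(sprintf("%d|%d:%.3f:%.3f,%.3f,%.3f:%.3f,%.3f",
                          a1, a2, ds, gpRR, gpRA, gpAA, p1, p2),
                  nrow = M)
  hdr <- c("##fileformat=VCFv4.2",
    "##source=pbwtimpute",
    sprintf("##contig=<ID=%s>", unique(mk$chrom)),
    "##INFO=<ID=IMP,Number=0,Type=Flag,Description=\"Imputed marker\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Genotyped marker\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Diploid dosage\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities\">",
    "##FORMAT=<ID=AP,Number=2,Type=Float,Description=\"Haploid alt probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  info <- ifelse(mk$typed, "TYPED", "IMP")
  body <- paste(mk$chrom, mk$pos, ".", mk$ref, mk$alt, ".", "PASS", info,
                "GT:DS:GP:AP", apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read haploid alt probabilities back from an imputed VCF
#'
#' Companion to \code{\link{writeImputedVcf}}: parses the AP field into a
#' haplotypes x markers matrix (used by the scoring tools).
#'
#' @param path VCF written by \code{\link{writeImputedVcf}}.
#' @return list with \code{markers} (data.frame incl. \code{typed}) and
#'   \code{ap} (haplotypes x markers matrix).
#' @export
readImputedVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ap <- vcfR::extract.gt(v, element = "AP")
  parts <- strsplit(as.vector(ap), ",", fixed = TRUE)
  p1 <- matrix(as.numeric(vapply(parts, `[`, "", 1L)), nrow = nrow(fix))
  p2 <- matrix(as.numeric(vapply(parts, `[`, "", 2L)), nrow = nrow(fix))
  K <- 2L * ncol(ap)
  hap <- matrix(0, nrow = K, ncol = nrow(fix))
  hap[seq(1L, K, by = 2L), ] <- t(p1)
  hap[seq(2L, K, by = 2L), ] <- t(p2)
  mk <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   typed = grepl("TYPED", fix$INFO),
                   stringsAsFactors = FALSE)
  list(markers = mk, ap = hap)
}
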