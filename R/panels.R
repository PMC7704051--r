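#' Construct a haplotype panel
#'
#' @param alleles integer/raw matrix (haplotypes x markers) of 0/1 alleles.
#' @param markers data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{cm} (filled with \code{NA}
#'   if absent; see \code{\link{attachGeneticMap}}).
#' @param hapIds optional haplotype labels (default \code{hap1..hapN}).
#' @return a \code{\linkS4class{HaplotypePanel}}
#' @examples
#' mk <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
#' HaplotypePanel(rbind(c(0, 1), c(1, 0)), mk)
#' @export
HaplotypePanel <- function(alleles, markers, hapIds = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  if (!is.raw(alleles)) {
    stor <- matrix(as.raw(alleles), nrow = nrow(alleles))
    alleles <- stor
  }
  if (is.null(markers$cm)) markers$cm <- NA_real_
  markers <- markers[, c("chrom", "pos", "ref", "alt", "cm")]
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  markers$ref <- as.character(markers$ref)
  markers$alt <- as.character(markers$alt)
  rownames(markers) <- NULL
  if (is.null(hapIds)) hapIds <- paste0("hap", seq_len(nrow(alleles)))
  new("HaplotypePanel", alleles = alleles, markers = markers,
      hapIds = as.character(hapIds))
}

#' Construct a genetic map
#'
#' @param pos anchor positions (bp), strictly increasing.
#' @param cm cumulative genetic position (cM) at each anchor, non-decreasing.
#' @return a \code{\linkS4class{GeneticMap}}
#' @export
GeneticMap <- function(pos, cm) {
  new("GeneticMap", pos = as.numeric(pos), cm = as.numeric(cm))
}

#' Read a genetic map file
#'
#' Accepts the 3-column HapMap-style format (\code{position rate(cM/Mb) cM},
#' with a header line) or the 4-column PLINK map
#' (\code{chrom id cM position}). The format is detected from the number of
#' columns.
#'
#' @param path path to a whitespace-delimited map file.
#' @return a \code{\linkS4class{GeneticMap}}
#' @export
readGeneticMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\s*-?[0-9]", first)
  tab <- utils::read.table(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 3L) {
    GeneticMap(tab[[1]], tab[[3]])
  } else if (ncol(tab) == 4L) {
    GeneticMap(tab[[4]], tab[[3]])
  } else stop("unrecognised genetic map format (need 3 or 4 columns)")
}

#' Interpolate genetic positions onto a panel
#'
#' Sets each marker's \code{cm} by linear interpolation between the flanking
#' map anchors; positions before the first or after the last anchor are
#' extrapolated at the nearest interval's rate. With \code{map = NULL} a
#' constant 1 cM/Mb fallback is applied from the first marker of the window
#' (the human genome-wide average rate).
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}
#' @param map a \code{\linkS4class{GeneticMap}} or \code{NULL}
#' @return the panel with \code{markers()$cm} filled in
#' @export
attachGeneticMap <- function(panel, map = NULL) {
  pos <- panel@markers$pos
  if (is.null(map)) {
    panel@markers$cm <- (pos - pos[1]) * 1e-6
    return(panel)
  }
  stopifnot(is(map, "GeneticMap"))
  panel@markers$cm <- interpolateCm(map, pos)
  panel
}

#' @rdname attachGeneticMap
#' @param queryPos physical positions (bp) to map to cM
#' @export
interpolateCm <- function(map, queryPos) {
  ap <- map@pos; ac <- map@cm
  n <- length(ap)
  if (n == 1L) return(rep(ac, length(queryPos)))
  cm <- stats::approx(ap, ac, xout = queryPos, rule = 1)$y
  # extrapolate at the nearest interval's rate
  loRate <- (ac[2] - ac[1]) / (ap[2] - ap[1])
  hiRate <- (ac[n] - ac[n - 1]) / (ap[n] - ap[n - 1])
  lo <- queryPos < ap[1]
  hi <- queryPos > ap[n]
  cm[lo] <- ac[1] + (queryPos[lo] - ap[1]) * loRate
  cm[hi] <- ac[n] + (queryPos[hi] - ap[n]) * hiRate
  cm
}

#' Parse a region string
#'
#' @param region \code{"chrom:start-end"} (1-based, inclusive) or
#'   \code{"chrom"} for a whole chromosome.
#' @return list with \code{chrom}, \code{start}, \code{end}
#' @export
parseRegion <- function(region) {
  if (!grepl(":", region))
    return(list(chrom = region, start = 1L, end = .Machine$integer.max))
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("bad region string: ", region)
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$start > out$end) stop("bad region string: ", region)
  out
}

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic SNV/indel records only; multiallelic records are skipped with a
#' warning. All genotypes must be phased (\code{|}-separated) and complete:
#' an unphased or missing genotype is a hard error naming the offending
#' record, since the model assumes fully phased panels with no missing
#' alleles. Haplotype order is sample order times (first, second) allele.
#'
#' @param path VCF file (plain or gzipped).
#' @param region optional \code{"chrom:start-end"} restriction (1-based,
#'   inclusive).
#' @return a \code{\linkS4class{HaplotypePanel}}
#' @export
readVcfPanel <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gtField <- v@gt
  if (nrow(fix) == 0L) stop("no records in ", path)
  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    keep <- keep & !multi
  }
  if (!is.null(region)) {
    r <- parseRegion(region)
    keep <- keep & fix$CHROM == r$chrom &
      as.integer(fix$POS) >= r$start & as.integer(fix$POS) <= r$end
  }
  if (!any(keep)) stop("no biallelic records in region")
  fix <- fix[keep, , drop = FALSE]
  gtField <- gtField[keep, , drop = FALSE]

  sampleNames <- colnames(gtField)[-1]
  gt <- gtField[, -1, drop = FALSE]
  gt[] <- sub(":.*", "", gt)   # keep the matrix shape
  badMiss <- which(is.na(gt) | grepl(".", gt, fixed = TRUE))
  if (length(badMiss)) {
    i <- arrayInd(badMiss[1], dim(gt))
    stop(sprintf("missing genotype at %s:%s sample %s (panels must be complete)",
                 fix$CHROM[i[1]], fix$POS[i[1]], sampleNames[i[2]]))
  }
  badPhase <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(badPhase)) {
    i <- arrayInd(badPhase[1], dim(gt))
    stop(sprintf("unphased or invalid genotype '%s' at %s:%s sample %s",
                 gt[i[1], i[2]], fix$CHROM[i[1]], fix$POS[i[1]],
                 sampleNames[i[2]]))
  }
  M <- nrow(fix); nS <- length(sampleNames)
  h1 <- matrix(as.integer(substr(gt, 1, 1) == "1"), nrow = M)
  h2 <- matrix(as.integer(substr(gt, 3, 3) == "1"), nrow = M)
  alle <- matrix(raw(1), nrow = 2L * nS, ncol = M)
  alle[seq(1L, 2L * nS, by = 2L), ] <- as.raw(t(h1))
  alle[seq(2L, 2L * nS, by = 2L), ] <- as.raw(t(h2))
  hapIds <- as.vector(rbind(paste0(sampleNames, "_1"),
                            paste0(sampleNames, "_2")))
  mk <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, cm = NA_real_,
                   stringsAsFactors = FALSE)
  ord <- order(mk$pos)
  HaplotypePanel(alle[, ord, drop = FALSE], mk[ord, , drop = FALSE], hapIds)
}

#' Write a haplotype panel as phased VCF
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}} (haplotype count must
#'   be even; consecutive haplotype pairs are written as one sample).
#' @param path output path (plain text; compress externally if needed).
#' @return \code{path}, invisibly
#' @export
writeVcfPanel <- function(panel, path) {
  N <- nHaplotypes(panel)
  if (N %% 2L != 0L) stop("panel must contain haplotype pairs")
  mk <- panel@markers
  samples <- sub("_1$", "", panel@hapIds[seq(1L, N, by = 2L)])
  a <- alleles(panel)
  gt <- matrix(paste0(t(a[seq(1L, N, by = 2L), , drop = FALSE]), "|",
                      t(a[seq(2L, N, by = 2L), , drop = FALSE])),
               nrow = nMarkers(panel))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pbwtimpute",
           sprintf("##contig=<ID=%s>", unique(mk$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, ".", mk$ref, mk$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Partition reference markers into typed and untyped sets
#'
#' A reference marker is typed when the target panel has a marker with
#' exactly the same (chrom, pos, ref, alt); matching is exact string
#' equality with no allele flipping or strand resolution. Target markers
#' absent from the reference are dropped with a logged count.
#'
#' @param reference,target \code{\linkS4class{HaplotypePanel}}s on the same
#'   chromosome, sorted by position.
#' @return a \code{\linkS4class{MarkerPartition}}
#' @export
partitionMarkers <- function(reference, target) {
  rk <- reference@markers; tk <- target@markers
  if (length(unique(rk$chrom)) != 1L || length(unique(tk$chrom)) != 1L ||
      rk$chrom[1] != tk$chrom[1])
    stop("panels must be on the same single chromosome")
  key <- function(m) paste(m$chrom, m$pos, m$ref, m$alt, sep = "\r")
  idx <- match(key(tk), key(rk))
  dropped <- sum(is.na(idx))
  if (dropped > 0L)
    message(dropped, " target marker(s) absent from the reference; dropped")
  tcols <- which(!is.na(idx))
  typed <- idx[tcols]
  ord <- order(typed)
  typed <- typed[ord]; tcols <- tcols[ord]
  if (length(typed) == 0L)
    stop("no typed markers in window: imputation model undefined")
  new("MarkerPartition",
      typedIdx = as.integer(typed),
      untypedIdx = setdiff(seq_len(nrow(rk)), typed),
      targetCols = as.integer(tcols))
}
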