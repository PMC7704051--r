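#' @rdname HaplotypePanel-class
#' @param x a \code{HaplotypePanel}
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("altFreq", function(x) standardGeneric("altFreq"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("panelMaf", function(x) standardGeneric("panelMaf"))

#' @rdname ImputationResult-class
#' @param object an object
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))
setMethod("nMarkers", "HaplotypePanel", function(x) ncol(x@alleles))
setMethod("markers", "HaplotypePanel", function(x) x@markers)
setMethod("hapIds", "HaplotypePanel", function(x) x@hapIds)

#' @describeIn HaplotypePanel-class integer view of the allele matrix
setMethod("alleles", "HaplotypePanel", function(x) {
  a <- matrix(as.integer(x@alleles), nrow = nrow(x@alleles))
  rownames(a) <- x@hapIds
  a
})

#' @describeIn HaplotypePanel-class per-marker alternate-allele frequency
setMethod("altFreq", "HaplotypePanel", function(x) {
  cpp_alt_counts(x@alleles, NULL) / nHaplotypes(x)
})

#' @describeIn HaplotypePanel-class per-marker minor allele frequency
setMethod("panelMaf", "HaplotypePanel", function(x) {
  f <- altFreq(x)
  pmin(f, 1 - f)
})

#' @describeIn ImputationResult-class haploid dosage matrix (targets x markers)
setMethod("dosages", "ImputationResult", function(object) object@dosage)

#' Subset a panel by haplotypes and/or markers
#'
#' @param x a \code{HaplotypePanel}
#' @param i haplotype indices (or logical/character on hapIds)
#' @param j marker indices (or logical)
#' @param ... ignored
#' @param drop ignored; always returns a panel
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nHaplotypes(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  if (is.character(i)) i <- match(i, x@hapIds)
  new("HaplotypePanel",
      alleles = x@alleles[i, j, drop = FALSE],
      markers = x@markers[j, , drop = FALSE],
      hapIds = x@hapIds[i])
})

#' @export
setMethod("as.matrix", "HaplotypePanel", function(x, ...) alleles(x))

setMethod("show", "HaplotypePanel", function(object) {
  mk <- object@markers
  cat(sprintf("HaplotypePanel: %d haplotypes x %d markers\n",
              nHaplotypes(object), nMarkers(object)))
  if (nrow(mk)) {
    cat(sprintf("  %s:%d-%d", mk$chrom[1], mk$pos[1], mk$pos[nrow(mk)]))
    if (!all(is.na(mk$cm)))
      cat(sprintf("  (%.3f-%.3f cM)", mk$cm[1], mk$cm[nrow(mk)]))
    cat("\n")
  }
})

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf("SelectionConfig: method=%s, L=%d, I=%g cM, mismatchGuard=%s\n",
              object@method, object@L, object@I, object@mismatchGuard))
})

setMethod("show", "HmmParameters", function(object) {
  cat(sprintf(
    "HmmParameters: Ne=%g, emission=%g/%g, minRho=%g\n",
    object@Ne, object@eMatch, object@eMismatch, object@minRho))
})

setMethod("show", "Imp5File", function(object) {
  cat(sprintf("Imp5File: %s\n  %d haplotypes, %d markers on %s (%d sparse, %d bitset)\n",
              object@path, object@nHap, nrow(object@directory), object@chrom,
              sum(object@directory$tag == "sparse"),
              sum(object@directory$tag == "bitset")))
})

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf(
    "ImputationResult: %d target haplotypes x %d markers (%d typed, %d imputed)\n",
    nrow(object@dosage), ncol(object@dosage),
    sum(object@markers$typed), sum(!object@markers$typed)))
  if (!is.null(object@stats$meanStates))
    cat(sprintf("  mean copying states per target: %.1f\n",
                object@stats$meanStates))
})

setMethod("show", "StateList", function(object) {
  cat(sprintf("StateList: target %d, %d states (events per state: %s)\n",
              object@targetId, length(object@states),
              paste(utils::head(object@eventCounts, 8), collapse = ",")))
})

setMethod("show", "PbwtColumn", function(object) {
  cat(sprintf("PbwtColumn: m=%d, N=%d, c=%d\n",
              object@m, length(object@A), object@c))
})
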