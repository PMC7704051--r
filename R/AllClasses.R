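#' @import methods
NULL

#' Phased haplotype panel
#'
#' An \code{N x M} binary matrix of phased haplotypes (rows) at biallelic
#' markers (columns), together with marker metadata. Alleles are stored as a
#' \code{raw} matrix (one byte per allele) so that large panels fit in
#' memory; use \code{\link{alleles}} (or \code{as.matrix}) to obtain an
#' integer view. Panels must be fully phased with no missing alleles: every
#' entry is 0 or 1.
#'
#' The \code{markers} slot is a \code{data.frame} with columns \code{chrom},
#' \code{pos} (1-based bp), \code{ref}, \code{alt} and \code{cm} (genetic
#' position, centimorgans). Positions are strictly increasing and \code{cm}
#' is non-decreasing.
#'
#' @slot alleles raw matrix, haplotypes x markers, entries 0x00/0x01.
#' @slot markers data.frame of marker metadata (see above).
#' @slot hapIds character vector of haplotype labels, two per sample
#'   (\code{<sample>_1}, \code{<sample>_2}).
#'
#' @seealso \code{\link{HaplotypePanel}}, \code{\link{readVcfPanel}}
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(alleles = "matrix", markers = "data.frame",
                 hapIds = "character"))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (!is.raw(object@alleles))
    msg <- c(msg, "alleles must be a raw matrix")
  if (nrow(object@alleles) < 1L)
    msg <- c(msg, "panel must have at least one haplotype")
  if (length(object@hapIds) != nrow(object@alleles))
    msg <- c(msg, "hapIds length must equal the number of haplotypes")
  mk <- object@markers
  need <- c("chrom", "pos", "ref", "alt", "cm")
  if (!all(need %in% names(mk))) {
    msg <- c(msg, sprintf("markers must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (nrow(mk) != ncol(object@alleles))
      msg <- c(msg, "markers rows must equal the number of marker columns")
    if (nrow(mk) > 0) {
      if (any(mk$pos < 1L)) msg <- c(msg, "positions must be >= 1")
      if (is.unsorted(mk$pos, strictly = TRUE))
        msg <- c(msg, "marker positions must be strictly increasing")
      if (any(!nzchar(mk$ref)) || any(!nzchar(mk$alt)))
        msg <- c(msg, "alleles must be non-empty strings")
      if (!all(is.na(mk$cm)) && is.unsorted(mk$cm[!is.na(mk$cm)]))
        msg <- c(msg, "cm must be non-decreasing")
    }
  }
  if (is.raw(object@alleles) && !cpp_is_binary(object@alleles))
    msg <- c(msg, "alleles must be 0/1 with no missing values")
  if (length(msg)) msg else TRUE
})

#' Genetic map
#'
#' Piecewise-linear map from physical position (bp) to cumulative genetic
#' position (cM). Anchor positions are strictly increasing, cM values
#' non-decreasing.
#'
#' @slot pos numeric, anchor positions in bp.
#' @slot cm numeric, cumulative cM at each anchor.
#' @seealso \code{\link{GeneticMap}}, \code{\link{attachGeneticMap}}
#' @exportClass GeneticMap
setClass("GeneticMap", representation(pos = "numeric", cm = "numeric"))

setValidity("GeneticMap", function(object) {
  if (length(object@pos) < 1L) return("map must have at least one anchor")
  if (length(object@pos) != length(object@cm))
    return("pos and cm must have equal length")
  if (is.unsorted(object@pos, strictly = TRUE))
    return("anchor positions must be strictly increasing")
  if (is.unsorted(object@cm)) return("cM values must be non-decreasing")
  TRUE
})

#' Typed/untyped marker partition
#'
#' Indices (1-based, into the reference panel's markers) of markers present
#' in both panels (typed, the HMM's observation sites) and markers present
#' only in the reference (untyped, to be imputed). \code{targetCols} maps
#' each typed reference marker to the corresponding target-panel column.
#'
#' @slot typedIdx integer, typed marker indices in the reference panel.
#' @slot untypedIdx integer, untyped marker indices.
#' @slot targetCols integer, target-panel column for each typed marker.
#' @seealso \code{\link{partitionMarkers}}
#' @exportClass MarkerPartition
setClass("MarkerPartition",
  representation(typedIdx = "integer", untypedIdx = "integer",
                 targetCols = "integer"))

#' PBWT column state
#'
#' The positional Burrows-Wheeler transform state at one typed marker
#' (0-based index \code{m}): positional prefix array \code{A} (haplotypes in
#' reverse-prefix lexicographic order, 0-based indices), transformed column
#' \code{Y}, zero count \code{c}, inclusive rank vectors \code{U}/\code{V}
#' (so \code{U[n] + V[n] = n + 1} with 1-based R indexing of position
#' \code{n-1}), and divergence array \code{D} with sentinel
#' \code{D[1] = m + 1}.
#'
#' @slot m integer, 0-based typed-marker index (-1 for the initial state).
#' @slot A integer, permutation of 0..N-1.
#' @slot Y integer, PBWT column (empty for the initial state).
#' @slot c integer, number of 0 symbols in Y.
#' @slot U,V integer, inclusive cumulative ranks of 0/1 symbols.
#' @slot D integer, divergence (match-start) array.
#' @seealso \code{\link{pbwtInit}}, \code{\link{pbwtAdvance}}
#' @exportClass PbwtColumn
setClass("PbwtColumn",
  representation(m = "integer", A = "integer", Y = "integer", c = "integer",
                 U = "integer", V = "integer", D = "integer"))

#' Target insertion trace
#'
#' Tracks a target haplotype's insertion slot \code{f} (0..N) in the PBWT
#' ordering as markers are processed, with snapshots at selection markers.
#'
#' @slot targetId integer, target haplotype index (1-based).
#' @slot f integer, current insertion slot.
#' @slot snapshots integer, recorded f values.
#' @exportClass TargetTrace
setClass("TargetTrace",
  representation(targetId = "integer", f = "integer", snapshots = "integer"))

#' Copying-state selection configuration
#'
#' @slot L integer, states harvested per selection event (>= 1).
#' @slot I numeric, selection interval in cM (> 0).
#' @slot method character, "neighbour" or "divergence".
#' @slot mismatchGuard logical, neighbour selection's mismatch-avoidance rule.
#' @seealso \code{\link{SelectionConfig}}
#' @exportClass SelectionConfig
setClass("SelectionConfig",
  representation(L = "integer", I = "numeric", method = "character",
                 mismatchGuard = "logical"))

setValidity("SelectionConfig", function(object) {
  if (object@L < 1L) return("L must be >= 1")
  if (object@I <= 0) return("I must be > 0")
  if (!object@method %in% c("neighbour", "divergence"))
    return("method must be 'neighbour' or 'divergence'")
  TRUE
})

#' Copying-state list for one target haplotype
#'
#' Sorted, duplicate-free reference haplotype indices (0-based) selected for
#' a target across all selection events, with per-state event counts.
#'
#' @slot targetId integer, target haplotype index (1-based).
#' @slot states integer, selected reference haplotypes (0-based, sorted).
#' @slot eventCounts integer, number of selection events that picked each.
#' @exportClass StateList
setClass("StateList",
  representation(targetId = "integer", states = "integer",
                 eventCounts = "integer"))

#' HMM parameters of the haploid copying model
#'
#' @slot Ne numeric, effective diploid population size (default 20000).
#' @slot eMatch,eMismatch numeric, emission probabilities (0.9999/0.0001).
#' @slot minRho numeric, floor on the per-interval switch probability.
#' @seealso \code{\link{HmmParameters}}, \code{\link{recombProb}}
#' @exportClass HmmParameters
setClass("HmmParameters",
  representation(Ne = "numeric", eMatch = "numeric", eMismatch = "numeric",
                 minRho = "numeric"))

setValidity("HmmParameters", function(object) {
  if (abs(object@eMatch + object@eMismatch - 1) > 1e-12)
    return("emission probabilities must sum to 1")
  if (object@minRho <= 0 || object@minRho >= 1)
    return("minRho must be in (0, 1)")
  if (object@Ne <= 0) return("Ne must be positive")
  TRUE
})

#' Sparse thresholded posteriors at typed markers
#'
#' Posterior copying probabilities of the selected states at every typed
#' marker, plus the storage mask used for interpolation: a state is stored
#' for a typed-marker interval when its posterior exceeds 1/S (S = number of
#' states) at either flank; the per-marker argmax state is always retained.
#'
#' @slot states integer, selected reference haplotypes (0-based).
#' @slot P numeric matrix, S x (typed markers) posteriors (pre-threshold).
#' @slot stored logical matrix, same shape, the storage mask.
#' @slot threshold numeric, 1/S (0 when sparsification is disabled).
#' @seealso \code{\link{forwardBackward}}
#' @exportClass PosteriorSet
setClass("PosteriorSet",
  representation(states = "integer", P = "matrix", stored = "matrix",
                 threshold = "numeric"))

#' Indexed binary reference container
#'
#' Handle onto an "IMP5LITE" file: header fields plus the marker directory
#' (position, alleles, encoding tag, record offset). Records are read lazily
#' by \code{\link{readImp5}}.
#'
#' @slot path character, file path.
#' @slot nHap integer, number of haplotypes.
#' @slot hapIds character.
#' @slot chrom character.
#' @slot directory data.frame with columns pos, ref, alt, cm, tag
#'   ("sparse"/"bitset"), nAlt, offset, size.
#' @seealso \code{\link{writeImp5}}, \code{\link{readImp5}}
#' @exportClass Imp5File
setClass("Imp5File",
  representation(path = "character", nHap = "integer", hapIds = "character",
                 chrom = "character", directory = "data.frame"))

#' Simulation configuration
#'
#' Study-condition parameters for the synthetic reference/target experiment:
#' a coalescent-like panel over a region, chip-site masking among common
#' markers, and switch-error injection in the targets.
#'
#' @slot regionBp numeric, region length in bp.
#' @slot nRefSamples,nTargetSamples integer, diploid sample counts.
#' @slot chipMafBound numeric, chip sites drawn among markers with reference
#'   MAF above this bound (default 0.05).
#' @slot chipMarkers integer, number of chip markers (NA = density-derived,
#'   one per 3 kb).
#' @slot switchErrorRate numeric, per-het-site switch probability.
#' @slot Ne numeric, ancestral effective population size of the generator.
#' @slot n0,growth numeric, present-day population size and exponential
#'   growth rate of the coalescent demography (recent-growth European-like
#'   history; see \code{\link{simulatePanels}}).
#' @slot mu,rec numeric, per-bp mutation and recombination rates.
#' @slot seed integer.
#' @seealso \code{\link{SimConfig}}, \code{\link{simulatePanels}}
#' @exportClass SimConfig
setClass("SimConfig",
  representation(regionBp = "numeric", nRefSamples = "integer",
                 nTargetSamples = "integer", chipMafBound = "numeric",
                 chipMarkers = "integer", switchErrorRate = "numeric",
                 Ne = "numeric", n0 = "numeric", growth = "numeric",
                 mu = "numeric", rec = "numeric", seed = "integer"))

#' Imputation result for one window
#'
#' @slot markers data.frame: chrom, pos, ref, alt, cm, typed (logical).
#' @slot dosage numeric matrix, target haplotypes x markers: posterior
#'   alt-allele probability of each target haplotype.
#' @slot typedAlleles raw matrix of observed target alleles at typed markers.
#' @slot hapIds character, target haplotype labels.
#' @slot stats list: mean selected states, counts, timing.
#' @exportClass ImputationResult
setClass("ImputationResult",
  representation(markers = "data.frame", dosage = "matrix",
                 typedAlleles = "matrix", hapIds = "character",
                 stats = "list"))
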