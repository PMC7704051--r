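#' HMM parameters
#'
#' Parameters of the haploid copying model. The per-interval switch
#' probability between typed markers is
#' \code{rho = 1 - exp(-4 * Ne * g / S)} with \code{g} the genetic gap in
#' Morgans and \code{S} the number of copying states, floored at
#' \code{minRho}. Emissions are a fixed match/mismatch pair.
#'
#' @param Ne effective diploid population size (default 20000, the
#'   conventional human value for this model family).
#' @param eMatch,eMismatch emission probabilities (defaults 0.9999/0.0001).
#' @param minRho floor on the switch probability so the chain never freezes
#'   across zero genetic distance (default 1e-9).
#' @return an \code{\linkS4class{HmmParameters}}
#' @export
HmmParameters <- function(Ne = 20000, eMatch = 0.9999, eMismatch = 1e-4,
                          minRho = 1e-9) {
  new("HmmParameters", Ne = Ne, eMatch = eMatch, eMismatch = eMismatch,
      minRho = minRho)
}

#' Per-interval switch probability
#'
#' @param cmGap genetic distance between consecutive typed markers, in cM.
#' @param nStates number of copying states in the HMM.
#' @param params an \code{\linkS4class{HmmParameters}}.
#' @return probability, monotone increasing in \code{cmGap} and decreasing
#'   in \code{nStates}, floored at \code{params@minRho}.
#' @examples
#' recombProb(0.001, 8, HmmParameters(Ne = 20000))  # 1 - exp(-0.1)
#' @export
recombProb <- function(cmGap, nStates, params = HmmParameters()) {
  stopifnot(all(cmGap >= 0), nStates >= 1)
  pmax(params@minRho,
       1 - exp(-4 * params@Ne * (cmGap / 100) / nStates))
}

asStateVector <- function(states) {
  if (is(states, "StateList")) states@states else as.integer(states)
}

asRawAlleles <- function(x) {
  if (is(x, "HaplotypePanel")) return(x@alleles)
  if (is.raw(x)) return(x)
  matrix(as.raw(x), nrow = nrow(x))
}

#' Forward-backward posteriors over the selected states
#'
#' Scaled forward-backward pass of the haploid copying HMM restricted to
#' the selected states (uniform initial distribution, switch probabilities
#' from \code{\link{recombProb}} with \code{S = } number of selected
#' states, fixed match/mismatch emissions). Posteriors sum to one at every
#' typed marker before sparsification. The storage mask keeps, for each
#' typed marker, states whose posterior exceeds \code{1/S}; the argmax
#' state is always retained so the mask is never empty.
#'
#' @param targetAlleles integer 0/1 vector over the typed markers.
#' @param states a \code{\linkS4class{StateList}} or 0-based integer vector
#'   of selected reference haplotypes.
#' @param refTyped reference panel at the typed markers
#'   (\code{\linkS4class{HaplotypePanel}} or 0/1 matrix, haplotypes x
#'   markers).
#' @param cm genetic positions (cM) of the typed markers.
#' @param params an \code{\linkS4class{HmmParameters}}.
#' @param sparsify apply the storage threshold (default TRUE).
#' @return a \code{\linkS4class{PosteriorSet}}
#' @export
forwardBackward <- function(targetAlleles, states, refTyped, cm,
                            params = HmmParameters(), sparsify = TRUE) {
  st <- asStateVector(states)
  if (length(st) < 1L) stop("empty copying-state list")
  raws <- asRawAlleles(refTyped)
  res <- cpp_impute_target(raws, st, as.integer(targetAlleles),
                           as.numeric(cm), params@Ne, params@minRho,
                           params@eMatch, params@eMismatch, sparsify,
                           list(), integer(0), integer(0), numeric(0),
                           logical(0), FALSE, TRUE)
  P <- res$P
  S <- length(st)
  thr <- if (sparsify) 1 / S else 0
  stored <- P > thr
  # never drop every state: retain the per-marker argmax
  top <- max.col(t(P), ties.method = "first")
  stored[cbind(top, seq_len(ncol(P)))] <- TRUE
  if (!sparsify) stored[] <- TRUE
  new("PosteriorSet", states = st, P = P, stored = stored, threshold = thr)
}

#' Linear interpolation of a haploid alt-allele probability
#'
#' State probabilities at an untyped marker are interpolated linearly (in
#' genetic distance) between the renormalised stored posteriors at the two
#' flanking typed markers; the alt probability is the interpolated mass on
#' the states carrying the alternate allele.
#'
#' @param pLeft,pRight posterior vectors over the same stored states at the
#'   left/right flanking typed markers (renormalised internally).
#' @param weight position of the untyped marker between the flanks in
#'   genetic distance, in [0, 1] (0 = at the left flank).
#' @param altCarriers logical vector over the stored states: carries alt.
#' @return haploid alt-allele probability in [0, 1]
#' @examples
#' interpolateDosage(c(1, 0), c(0, 1), 0.5, c(FALSE, TRUE))  # 0.5
#' @export
interpolateDosage <- function(pLeft, pRight, weight, altCarriers) {
  stopifnot(weight >= 0, weight <= 1,
            length(pLeft) == length(pRight),
            length(altCarriers) == length(pLeft))
  pl <- pLeft / sum(pLeft)
  pr <- pRight / sum(pRight)
  d <- sum(((1 - weight) * pl + weight * pr)[altCarriers])
  min(1, max(0, d))
}

#' Map untyped markers onto typed intervals
#'
#' For each untyped marker: the 0-based index of the left flanking typed
#' marker (-1 before the first, \code{MT - 1} after the last) and the
#' interpolation weight in genetic distance (0.5 when the flanks are
#' co-sited in cM).
#'
#' @param typedPos,typedCm positions (bp) and cM of the typed markers.
#' @param untypedPos,untypedCm positions and cM of the untyped markers.
#' @return list with integer \code{leftFlank} and numeric \code{weight}
#' @export
untypedIntervals <- function(typedPos, typedCm, untypedPos, untypedCm) {
  MT <- length(typedPos)
  iv <- findInterval(untypedPos, typedPos)
  leftFlank <- ifelse(iv == 0L, -1L, ifelse(iv >= MT, MT - 1L, iv - 1L))
  weight <- numeric(length(untypedPos))
  mid <- iv >= 1L & iv < MT
  if (any(mid)) {
    l <- iv[mid]
    gap <- typedCm[l + 1L] - typedCm[l]
    weight[mid] <- ifelse(gap > 0, (untypedCm[mid] - typedCm[l]) / gap, 0.5)
  }
  weight[iv >= MT] <- 1
  weight <- pmin(1, pmax(0, weight))
  list(leftFlank = as.integer(leftFlank), weight = weight)
}

#' Impute untyped markers from stored posteriors (reference streamed)
#'
#' Walks the untyped markers in position order, fetching each marker's
#' alternate-allele carriers from the binary reference records (see
#' \code{\link{imp5Records}}) rather than a decoded allele matrix. For a
#' rare variant (reference MAF below \code{rareBound}) the delayed lazy
#' path first tests whether any stored state at the flanks carries the
#' alternate allele, and emits an exactly-zero probability without
#' interpolation when none does; this equals the full computation, whose
#' sum over an empty carrier set is zero.
#'
#' @param post a \code{\linkS4class{PosteriorSet}} at the typed markers.
#' @param records per-untyped-marker binary records
#'   (\code{\link{imp5Records}} output, or an \code{\linkS4class{Imp5File}}
#'   restricted to the untyped markers).
#' @param untypedMeta data.frame with \code{pos}, \code{cm} and
#'   \code{altFreq} of the untyped markers, in position order.
#' @param typedPos,typedCm positions and cM of the typed markers.
#' @param lazy use the lazy path (default TRUE).
#' @param rareBound rarity bound for the lazy test (default 1/256, aligned
#'   with the sparse-record encoding bound so the carrier test is an index
#'   lookup).
#' @return numeric vector of haploid alt probabilities, one per untyped
#'   marker.
#' @export
lazyImputeWindow <- function(post, records, untypedMeta, typedPos, typedCm,
                             lazy = TRUE, rareBound = 1 / 256) {
  if (is.unsorted(untypedMeta$pos, strictly = TRUE))
    stop("untyped marker stream out of order")
  iv <- untypedIntervals(typedPos, typedCm, untypedMeta$pos, untypedMeta$cm)
  MT <- length(typedPos)
  st <- post@states
  out <- numeric(nrow(untypedMeta))
  rare <- pmin(untypedMeta$altFreq, 1 - untypedMeta$altFreq) < rareBound
  for (u in seq_len(nrow(untypedMeta))) {
    lf <- iv$leftFlank[u]
    ml <- max(lf, 0L) + 1L
    mr <- if (lf < 0L) 1L else min(lf + 2L, MT)
    sel <- post@stored[, ml] | post@stored[, mr]
    carriers <- carriersAt(records, u, st[sel])
    if (lazy && rare[u] && length(carriers) == 0L) {
      out[u] <- 0
      next
    }
    out[u] <- interpolateDosage(post@P[sel, ml], post@P[sel, mr],
                                iv$weight[u], st[sel] %in% carriers)
  }
  out
}

#' Combine two haploid alt probabilities into diploid output
#'
#' @param hap1Prob,hap2Prob haploid alt probabilities in [0, 1] (vectors
#'   allowed).
#' @return list with \code{DS} (dosage, \code{p1 + p2}) and \code{GP}
#'   (matrix of genotype probabilities RR/RA/AA under independence of the
#'   two haplotypes; rows sum to 1).
#' @examples
#' toDiploid(0.5, 0.5)  # DS 1, GP (0.25, 0.5, 0.25)
#' @export
toDiploid <- function(hap1Prob, hap2Prob) {
  stopifnot(all(hap1Prob >= 0 & hap1Prob <= 1),
            all(hap2Prob >= 0 & hap2Prob <= 1))
  p1 <- hap1Prob; p2 <- hap2Prob
  list(DS = p1 + p2,
       GP = cbind((1 - p1) * (1 - p2),
                  p1 * (1 - p2) + p2 * (1 - p1),
                  p1 * p2))
}
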