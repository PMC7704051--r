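#' Initial PBWT state
#'
#' The state before any marker has been processed: identity prefix array
#' (empty reverse prefixes, stable order) and all-zero divergence.
#'
#' @param N number of haplotypes.
#' @return a \code{\linkS4class{PbwtColumn}} with \code{m = -1}.
#' @export
pbwtInit <- function(N) {
  new("PbwtColumn", m = -1L, A = seq_len(N) - 1L, Y = integer(0),
      c = NA_integer_, U = integer(0), V = integer(0),
      D = integer(N))
}

#' Advance the PBWT by one marker column
#'
#' Applies the stable counting mapping
#' \code{phi_m(n) = c_m(Y[n]) + rank_m(Y[n], n)} so that the new prefix
#' array satisfies \code{A[phi_m(n)] = A_prev[n]}, and updates the
#' divergence array with the one-pass recursion (running maxima of match
#' starts swept per symbol class). After the call, \code{A} orders the
#' haplotypes by their reverse prefixes up to this marker, with stable
#' tie-break, and running maxima of \code{D} give maximal-match starts
#' (see \code{\link{maxMatchStart}}).
#'
#' @param prev the previous \code{\linkS4class{PbwtColumn}} (or
#'   \code{\link{pbwtInit}} output).
#' @param columnAlleles integer 0/1 vector: the panel column at this marker,
#'   in original haplotype order.
#' @return a \code{\linkS4class{PbwtColumn}} at marker \code{prev@m + 1}.
#' @examples
#' col <- pbwtAdvance(pbwtInit(3), c(0L, 1L, 0L))
#' col@A  # zeros first, stable: 0, 2, 1
#' @export
pbwtAdvance <- function(prev, columnAlleles) {
  m <- prev@m + 1L
  res <- cpp_pbwt_advance(prev@A, prev@D, as.integer(columnAlleles), m)
  new("PbwtColumn", m = m, A = res$A, Y = res$Y, c = res$c,
      U = res$U, V = res$V, D = res$D)
}

#' Rank query on a PBWT column
#'
#' Number of \code{b} symbols in \code{Y} at positions \code{0..n}
#' (0-based, inclusive). The inclusive convention makes the identity
#' \code{pbwtRank(col, 0, n) + pbwtRank(col, 1, n) == n + 1} hold at every
#' position, and \code{pbwtRank(col, 0, N-1) == col@c}.
#'
#' @param col a \code{\linkS4class{PbwtColumn}}.
#' @param b symbol, 0 or 1.
#' @param n 0-based position, \code{0 <= n < N}.
#' @return integer count
#' @export
pbwtRank <- function(col, b, n) {
  stopifnot(n >= 0, n < length(col@A), b %in% c(0L, 1L))
  if (b == 0L) col@U[n + 1L] else col@V[n + 1L]
}

#' Create an insertion trace for a target haplotype
#'
#' @param targetId integer label.
#' @return a \code{\linkS4class{TargetTrace}} with starting slot
#'   \code{f = 0} (empty reverse prefix sorts first among equals).
#' @export
TargetTrace <- function(targetId = 1L) {
  new("TargetTrace", targetId = as.integer(targetId), f = 0L,
      snapshots = integer(0))
}

#' Insert a target haplotype one marker deeper into the PBWT
#'
#' O(1) update of the insertion slot using the rank structures:
#' \code{f' = U-count of zeros above f} when the target allele is 0, else
#' \code{c + V-count of ones above f}; at the boundary \code{f = N} the
#' column totals are used. The resulting \code{f} equals the number of
#' reference reverse prefixes lexicographically smaller than the target's
#' reverse prefix at this marker (ties are not counted).
#'
#' @param trace a \code{\linkS4class{TargetTrace}} (or an integer slot f).
#' @param col the \code{\linkS4class{PbwtColumn}} at the current marker.
#' @param tAllele the target allele, 0 or 1.
#' @return the updated trace (or integer f when an integer was supplied).
#' @export
insertTarget <- function(trace, col, tAllele) {
  f <- if (is(trace, "TargetTrace")) trace@f else as.integer(trace)
  stopifnot(f >= 0, f <= length(col@A), tAllele %in% c(0L, 1L))
  nz <- if (f == 0L) 0L else col@U[f]   # zeros strictly above slot f
  no <- if (f == 0L) 0L else col@V[f]   # ones strictly above slot f
  fNew <- if (tAllele == 0L) nz else col@c + no
  if (is(trace, "TargetTrace")) {
    trace@f <- as.integer(fNew)
    trace
  } else as.integer(fNew)
}

#' Start of the maximal match between two ranked haplotypes
#'
#' For A-ranks \code{i < j} (0-based) at the column's marker \code{m},
#' returns \code{max(D[n]) over i < n <= j}: the first marker of the
#' maximal reverse-prefix match ending at \code{m} between haplotypes
#' \code{A[i]} and \code{A[j]}. 0 means the match extends to the first
#' marker; \code{m + 1} means no match at \code{m} itself.
#'
#' @param col a \code{\linkS4class{PbwtColumn}}.
#' @param i,j 0-based A-ranks with \code{i < j}.
#' @return integer match start (0-based marker index)
#' @export
maxMatchStart <- function(col, i, j) {
  if (i >= j) stop("need i < j")
  stopifnot(i >= 0, j < length(col@A))
  max(col@D[(i + 2L):(j + 1L)])
}
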