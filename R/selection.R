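#' Selection configuration
#'
#' @param L states harvested per selection event (default 4, where
#'   accuracy saturates).
#' @param I selection interval in cM (default 0.02; 0.002 is recommended
#'   when only a crude or constant-rate map is available, e.g. simulated
#'   data).
#' @param method \code{"neighbour"} (default) or \code{"divergence"}.
#' @param mismatchGuard for neighbour selection, skip a candidate whose
#'   allele at the selection marker mismatches the target when the opposite
#'   side's candidate matches (default TRUE).
#' @return a \code{\linkS4class{SelectionConfig}}
#' @export
SelectionConfig <- function(L = 4L, I = 0.02, method = c("neighbour",
                            "divergence"), mismatchGuard = TRUE) {
  method <- match.arg(method)
  new("SelectionConfig", L = as.integer(L), I = as.numeric(I),
      method = method, mismatchGuard = isTRUE(mismatchGuard))
}

#' Choose selection markers along the typed map
#'
#' Greedy left-to-right rule: the first typed marker is a selection marker;
#' thereafter the first typed marker at least \code{I} cM beyond the
#' previous selection marker. The last typed marker is always included so
#' the window end is covered.
#'
#' @param cm genetic positions (cM) of the typed markers, non-decreasing.
#' @param I selection interval in cM.
#' @return integer vector of 1-based indices into the typed markers.
#' @examples
#' selectionMarkers(c(0, 0.01, 0.02, 0.03, 0.05), 0.02)  # 1, 3, 5
#' @export
selectionMarkers <- function(cm, I) {
  stopifnot(I > 0, length(cm) >= 1L)
  sel <- 1L
  last <- cm[1]
  for (i in seq_along(cm)[-1]) {
    if (cm[i] >= last + I) {
      sel <- c(sel, i)
      last <- cm[i]
    }
  }
  if (sel[length(sel)] != length(cm)) sel <- c(sel, length(cm))
  sel
}

#' Match start of two haplotypes' reverse prefixes
#'
#' Backward scan from 0-based marker \code{m}: the smallest marker index
#' \code{s} such that \code{x[s..m] == y[s..m]}; \code{m + 1} if the
#' haplotypes differ at \code{m} itself.
#'
#' @param x,y integer 0/1 allele vectors over the typed markers.
#' @param m 0-based marker index.
#' @return integer match start
#' @export
prefixMatchStart <- function(x, y, m) {
  start <- m + 1L
  for (k in seq(m, 0L)) {
    if (x[k + 1L] != y[k + 1L]) break
    start <- k
  }
  as.integer(start)
}

#' Divergence selection around an insertion slot
#'
#' Two-pointer expansion from the slots adjacent to the target's insertion
#' point: repeatedly take the side whose running match start with the
#' target is smaller (i.e. the longer reverse-prefix match), the upper side
#' on ties. Running match starts are maintained as prefix maxima of the
#' divergence array. An exhausted side drains the other, so \code{L >= N}
#' returns the full panel.
#'
#' @param f insertion slot (0..N).
#' @param A positional prefix array (0-based haplotype indices).
#' @param D divergence array at the same marker.
#' @param dup match start between the target and \code{A[f-1]} (the
#'   haplotype just above the slot); ignored when \code{f == 0}.
#' @param ddn match start between the target and \code{A[f]}; ignored when
#'   \code{f == N}.
#' @param L number of states to select.
#' @return integer vector of at most \code{L} reference haplotype indices
#'   (0-based), in pick order.
#' @export
divergenceSelect <- function(f, A, D, dup, ddn, L) {
  N <- length(A)
  i <- f - 1L; j <- f
  out <- integer(0)
  while (length(out) < L && (i >= 0L || j < N)) {
    takeUp <- if (i < 0L) FALSE else if (j >= N) TRUE else dup <= ddn
    if (takeUp) {
      out <- c(out, A[i + 1L])
      if (i > 0L) dup <- max(dup, D[i + 1L])
      i <- i - 1L
    } else {
      out <- c(out, A[j + 1L])
      if (j + 1L < N) ddn <- max(ddn, D[j + 2L])
      j <- j + 1L
    }
  }
  out
}

#' Neighbour selection around an insertion slot
#'
#' Takes the \code{ceiling(L/2)} A-ranks above the slot and
#' \code{floor(L/2)} below, clipped at the panel borders (near a border
#' fewer than \code{L} states are returned; the other side is not
#' extended). With the mismatch guard, a candidate whose allele at the
#' selection marker mismatches the target is skipped in favour of extending
#' the matching side, the skip being charged to the mismatching side's
#' budget.
#'
#' @param f insertion slot (0..N).
#' @param A positional prefix array (0-based haplotype indices).
#' @param L number of states to select.
#' @param guard apply the mismatch guard (needs \code{columnAlleles} and
#'   \code{tAllele}).
#' @param columnAlleles panel column at the selection marker, in original
#'   haplotype order (only used by the guard).
#' @param tAllele the target allele at the selection marker.
#' @return integer vector of at most \code{L} reference haplotype indices
#'   (0-based), in pick order.
#' @export
neighbourSelect <- function(f, A, L, guard = FALSE, columnAlleles = NULL,
                            tAllele = NULL) {
  N <- length(A)
  upLeft <- (L + 1L) %/% 2L
  dnLeft <- L %/% 2L
  i <- f - 1L; j <- f
  sideUp <- TRUE
  out <- integer(0)
  while (length(out) < L) {
    upPtr <- i >= 0L
    dnPtr <- j < N
    canUp <- upLeft > 0L && upPtr
    canDn <- dnLeft > 0L && dnPtr
    if (!canUp && !canDn) break
    up <- canUp && (!canDn || sideUp)
    if (guard) {
      upMatch <- upPtr && columnAlleles[A[i + 1L] + 1L] == tAllele
      dnMatch <- dnPtr && columnAlleles[A[j + 1L] + 1L] == tAllele
      if (up && !upMatch && dnMatch) {
        out <- c(out, A[j + 1L]); j <- j + 1L
        upLeft <- upLeft - 1L; sideUp <- TRUE
        next
      }
      if (!up && !dnMatch && upMatch) {
        out <- c(out, A[i + 1L]); i <- i - 1L
        dnLeft <- dnLeft - 1L; sideUp <- FALSE
        next
      }
    }
    if (up) {
      out <- c(out, A[i + 1L]); i <- i - 1L
      upLeft <- upLeft - 1L; sideUp <- FALSE
    } else {
      out <- c(out, A[j + 1L]); j <- j + 1L
      dnLeft <- dnLeft - 1L; sideUp <- TRUE
    }
  }
  out
}

#' Run copying-state selection for all targets
#'
#' One left-to-right streaming pass over the typed markers: at each marker
#' the PBWT column of the reference is advanced and every target's
#' insertion slot is updated in O(1); at selection markers (every \code{I}
#' cM, see \code{\link{selectionMarkers}}) the configured selector harvests
#' up to \code{L} states per target. Events are merged per target into a
#' duplicate-free sorted state list covering the window. Only one PBWT
#' column is live at any time.
#'
#' @param refTyped \code{\linkS4class{HaplotypePanel}} restricted to the
#'   typed markers (with \code{cm} set).
#' @param targets \code{\linkS4class{HaplotypePanel}} of target haplotypes
#'   over the same typed markers.
#' @param cfg a \code{\linkS4class{SelectionConfig}}.
#' @return list with \code{stateLists} (list of
#'   \code{\linkS4class{StateList}}), \code{selIdx} (1-based selection
#'   marker indices), \code{fTrace} (targets x selection markers insertion
#'   slots) and \code{meanStates}.
#' @export
runSelection <- function(refTyped, targets, cfg = SelectionConfig()) {
  if (nMarkers(refTyped) != nMarkers(targets))
    stop("reference and target panels must share the typed markers")
  if (nMarkers(refTyped) < 1L) stop("no typed markers")
  cm <- refTyped@markers$cm
  if (all(is.na(cm))) stop("typed markers carry no cm values; attach a map")
  sel <- selectionMarkers(cm, cfg@I)
  res <- cpp_selection_sweep(refTyped@alleles, targets@alleles,
                             sel - 1L, cfg@L,
                             if (cfg@method == "divergence") 1L else 0L,
                             cfg@mismatchGuard)
  K <- nHaplotypes(targets)
  stateLists <- vector("list", K)
  for (t in seq_len(K)) {
    stateLists[[t]] <- new("StateList", targetId = t,
                           states = res$states[[t]],
                           eventCounts = res$eventCounts[[t]])
  }
  list(stateLists = stateLists, selIdx = sel, fTrace = res$fTrace,
       meanStates = mean(vapply(stateLists,
                                function(s) length(s@states), 1L)))
}
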