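IMP5_MAGIC <- charToRaw("IMP5LITE")
IMP5_VERSION <- 1L
SPARSE_BOUND <- 1 / 256

#' Encode one marker column as a binary record
#'
#' When the alternate allele is rare (alt frequency strictly below 1/256)
#' the sorted 0-based carrier indices are stored as 4-byte little-endian
#' integers; otherwise the alleles are packed as a bitset, haplotype
#' \code{n} at byte \code{n \%/\% 8}, bit \code{n \%\% 8}. A frequency of
#' exactly 1/256 is encoded as a bitset.
#'
#' @param alleles integer 0/1 vector of length N.
#' @param N panel haplotype count (defaults to \code{length(alleles)}).
#' @return list with \code{tag} (0 sparse, 1 bitset), \code{nAlt} and
#'   \code{data} (integer carriers or raw bitset).
#' @export
encodeMarkerRecord <- function(alleles, N = length(alleles)) {
  if (length(alleles) != N) stop("allele vector length mismatch")
  alleles <- as.integer(alleles)
  carriers <- which(alleles == 1L) - 1L
  nAlt <- length(carriers)
  if (nAlt / N < SPARSE_BOUND) {
    list(tag = 0L, nAlt = nAlt, data = carriers)
  } else {
    pad <- (-N) %% 8L
    list(tag = 1L, nAlt = nAlt,
         data = packBits(c(alleles == 1L, rep(FALSE, pad)), type = "raw"))
  }
}

#' @rdname encodeMarkerRecord
#' @param record an encoded record (list with tag/data).
#' @return \code{decodeMarkerRecord}: the integer 0/1 allele vector.
#' @export
decodeMarkerRecord <- function(record, N) {
  if (record$tag == 0L) {
    out <- integer(N)
    out[record$data + 1L] <- 1L
    out
  } else {
    as.integer(rawToBits(record$data))[seq_len(N)]
  }
}

#' In-memory binary record store for a panel
#'
#' The same per-marker sparse/bitset encoding as the on-disk container,
#' kept in memory; used by the imputation engine to stream untyped markers
#' and answer carrier queries without a decoded allele matrix.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param markerIdx optional marker subset (1-based).
#' @return list with \code{N}, \code{tag} (integer vector) and \code{data}
#'   (list of carrier vectors / bitsets).
#' @export
imp5Records <- function(panel, markerIdx = NULL) {
  if (is.null(markerIdx)) markerIdx <- seq_len(nMarkers(panel))
  N <- nHaplotypes(panel)
  tag <- integer(length(markerIdx))
  data <- vector("list", length(markerIdx))
  for (i in seq_along(markerIdx)) {
    rec <- encodeMarkerRecord(as.integer(panel@alleles[, markerIdx[i]]), N)
    tag[i] <- rec$tag
    data[[i]] <- rec$data
  }
  list(N = N, tag = tag, data = data)
}

#' Alt carriers among a subset of selected states
#'
#' For sparse records the shorter of (carrier list, state subset) is
#' iterated against a membership structure on the longer; for bitset
#' records each selected state's bit is tested directly.
#'
#' @param store an \code{\link{imp5Records}} store.
#' @param markerIdx 1-based marker index within the store.
#' @param states 0-based haplotype indices to test.
#' @return sorted 0-based indices of the states carrying alt.
#' @export
carriersAt <- function(store, markerIdx, states) {
  states <- as.integer(states)
  if (store$tag[markerIdx] == 0L) {
    carriers <- store$data[[markerIdx]]
    if (length(carriers) <= length(states)) {
      out <- carriers[carriers %in% states]
    } else {
      out <- states[states %in% carriers]
    }
    sort(out)
  } else {
    b <- store$data[[markerIdx]]
    byte <- as.integer(b[states %/% 8L + 1L])
    hit <- bitwAnd(byte, bitwShiftL(1L, states %% 8L)) > 0L
    sort(states[hit])
  }
}

writeString <- function(con, s) {
  r <- charToRaw(s)
  writeBin(length(r), con, size = 4L, endian = "little")
  writeBin(r, con)
}

readString <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' Write a panel as an indexed binary reference file
#'
#' Writes the "IMP5LITE" container: a header (magic, version, haplotype
#' count, chromosome, haplotype ids), a flat marker directory (positions,
#' cM, alleles, encoding tag, alt count, absolute record offset) and the
#' per-marker records. The directory is columnar and read in one pass;
#' region extraction then seeks directly to in-region records. Files are
#' little-endian and uncompressed (the encoding is already compact; record
#' offsets are 32-bit, so a single file is limited to 4 GiB).
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}} (sorted by position).
#' @param path output path.
#' @return an \code{\linkS4class{Imp5File}} handle, invisibly.
#' @export
writeImp5 <- function(panel, path) {
  N <- nHaplotypes(panel)
  mk <- panel@markers
  M <- nrow(mk)
  store <- imp5Records(panel)
  sizes <- ifelse(store$tag == 0L,
                  4L * vapply(store$data, length, 1L),
                  as.integer((N + 7L) %/% 8L))
  refBlob <- charToRaw(paste(mk$ref, collapse = "\n"))
  altBlob <- charToRaw(paste(mk$alt, collapse = "\n"))
  idBlob <- charToRaw(paste(panel@hapIds, collapse = "\n"))
  headerLen <- 8L + 1L + 4L + (4L + nchar(mk$chrom[1])) +
    (4L + length(idBlob)) + 4L +
    4L * M + 8L * M + M + 4L * M + 4L * M +
    (4L + length(refBlob)) + (4L + length(altBlob))
  offsets <- headerLen + cumsum(c(0L, sizes[-M]))

  con <- file(path, "wb")
  ok <- FALSE
  on.exit(if (!ok) close(con))
  writeBin(IMP5_MAGIC, con)
  writeBin(as.raw(IMP5_VERSION), con)
  writeBin(N, con, size = 4L, endian = "little")
  writeString(con, mk$chrom[1])
  writeBin(length(idBlob), con, size = 4L, endian = "little")
  writeBin(idBlob, con)
  writeBin(M, con, size = 4L, endian = "little")
  writeBin(as.integer(mk$pos), con, size = 4L, endian = "little")
  cmOut <- mk$cm
  cmOut[is.na(cmOut)] <- -1
  writeBin(as.numeric(cmOut), con, size = 8L, endian = "little")
  writeBin(as.raw(store$tag), con)
  writeBin(cpp_alt_counts(panel@alleles, NULL), con, size = 4L,
           endian = "little")
  writeBin(as.integer(offsets), con, size = 4L, endian = "little")
  writeBin(length(refBlob), con, size = 4L, endian = "little")
  writeBin(refBlob, con)
  writeBin(length(altBlob), con, size = 4L, endian = "little")
  writeBin(altBlob, con)
  for (j in seq_len(M)) {
    if (store$tag[j] == 0L) {
      writeBin(store$data[[j]], con, size = 4L, endian = "little")
    } else {
      writeBin(store$data[[j]], con)
    }
  }
  close(con)
  ok <- TRUE
  invisible(readImp5Header(path))
}

#' @rdname writeImp5
#' @return \code{readImp5Header}: an \code{\linkS4class{Imp5File}} handle
#'   with the parsed directory (no records read).
#' @export
readImp5Header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, IMP5_MAGIC))
    stop("not an IMP5LITE file (bad magic): ", path)
  ver <- as.integer(readBin(con, "raw", 1L))
  if (ver != IMP5_VERSION) stop("unsupported IMP5LITE version: ", ver)
  N <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  chrom <- readString(con)
  hapIds <- strsplit(readString(con), "\n", fixed = TRUE)[[1]]
  M <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  pos <- readBin(con, "integer", M, size = 4L, endian = "little")
  cm <- readBin(con, "numeric", M, size = 8L, endian = "little")
  cm[cm < 0] <- NA_real_
  tag <- as.integer(readBin(con, "raw", M))
  nAlt <- readBin(con, "integer", M, size = 4L, endian = "little")
  offset <- readBin(con, "integer", M, size = 4L, endian = "little")
  ref <- strsplit(readString(con), "\n", fixed = TRUE)[[1]]
  alt <- strsplit(readString(con), "\n", fixed = TRUE)[[1]]
  headerBytes <- seek(con)
  dir <- data.frame(pos = pos, ref = ref, alt = alt, cm = cm,
                    tag = ifelse(tag == 0L, "sparse", "bitset"),
                    nAlt = nAlt, offset = offset,
                    size = ifelse(tag == 0L, 4L * nAlt, (N + 7L) %/% 8L),
                    stringsAsFactors = FALSE)
  out <- new("Imp5File", path = path, nHap = N, hapIds = hapIds,
             chrom = chrom, directory = dir)
  attr(out, "headerBytes") <- as.integer(headerBytes)
  out
}

#' Read a region from an indexed binary reference file
#'
#' Parses the header and directory, then seeks to and decodes only the
#' records whose position falls inside the region; bytes outside the
#' directory and the in-region records are never read. The number of bytes
#' actually read is attached as attribute \code{"bytesRead"}.
#'
#' @param path an IMP5LITE file (or an \code{\linkS4class{Imp5File}}).
#' @param region optional \code{"chrom:start-end"}.
#' @return a \code{\linkS4class{HaplotypePanel}} (zero markers allowed for
#'   an empty region, returned as a 0-column panel).
#' @export
readImp5 <- function(path, region = NULL) {
  hdr <- if (is(path, "Imp5File")) path else readImp5Header(path)
  dir <- hdr@directory
  keep <- seq_len(nrow(dir))
  if (!is.null(region)) {
    r <- parseRegion(region)
    if (r$chrom != hdr@chrom) keep <- integer(0)
    else keep <- which(dir$pos >= r$start & dir$pos <= r$end)
  }
  N <- hdr@nHap
  alle <- matrix(raw(1), nrow = N, ncol = length(keep))
  bytes <- attr(hdr, "headerBytes")
  if (is.null(bytes)) bytes <- 0L
  con <- file(hdr@path, "rb")
  on.exit(close(con))
  for (i in seq_along(keep)) {
    j <- keep[i]
    seek(con, dir$offset[j])
    if (dir$tag[j] == "sparse") {
      carriers <- readBin(con, "integer", dir$nAlt[j], size = 4L,
                          endian = "little")
      col <- raw(N)
      col[carriers + 1L] <- as.raw(1L)
    } else {
      b <- readBin(con, "raw", dir$size[j])
      col <- as.raw(rawToBits(b)[seq_len(N)] == as.raw(1L))
    }
    alle[, i] <- col
    bytes <- bytes + dir$size[j]
  }
  mk <- data.frame(chrom = rep(hdr@chrom, length(keep)), pos = dir$pos[keep],
                   ref = dir$ref[keep], alt = dir$alt[keep],
                   cm = dir$cm[keep], stringsAsFactors = FALSE)
  out <- HaplotypePanel(alle, mk, hdr@hapIds)
  attr(out, "bytesRead") <- bytes
  out
}
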