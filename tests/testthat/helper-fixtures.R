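# Plain-text fixture builders (everything is generated at test time).

writeTestVcf <- function(path, pos, ref, alt, gt, chrom = "20",
                         samples = paste0("S", seq_len(ncol(gt)))) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

panelFromMatrix <- function(H, pos = NULL, chrom = "20", cm = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(H)) * 100L
  mk <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  if (!is.null(cm)) mk$cm <- cm
  HaplotypePanel(H, mk)
}
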