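engineFixture <- function(seed = 71L) {
  cfg <- SimConfig(regionBp = 4e5, nRefSamples = 120L, nTargetSamples = 6L,
                   chipMarkers = 120L, seed = seed)
  sim <- simulatePanels(cfg, method = "mosaic")
  msk <- maskToChip(sim$targetTruth, sim$reference, cfg)
  list(cfg = cfg, sim = sim, msk = msk)
}

test_that("window plans parse regions and apply buffers", {
  p <- WindowPlan("1:2000001-3000000", bufferBp = 1e6)
  expect_equal(p@chrom, "1")
  expect_equal(effectiveRegion(p), "1:1000001-4000000")
  expect_equal(effectiveRegion(WindowPlan("1:100-200", bufferBp = 500)),
               "1:1-700")
  expect_error(parseRegion("1:300-100"), "bad region")
  expect_error(parseRegion("1:abc"), "bad region")
})

test_that("windowed runs concatenate to the whole-region marker inventory", {
  fx <- engineFixture()
  ref <- fx$sim$reference; obs <- fx$msk$targetObserved
  sel <- SelectionConfig(L = 4L, I = 0.002)

  whole <- imputeWindow(ref, obs, selection = sel)
  mid <- markers(ref)$pos[nMarkers(ref) %/% 2]
  w1 <- imputeWindow(ref, obs, selection = sel,
                     plan = WindowPlan(sprintf("1:1-%d", mid), 1e5))
  w2 <- imputeWindow(ref, obs, selection = sel,
                     plan = WindowPlan(sprintf("1:%d-400000", mid + 1L), 1e5))
  # core-only emission: adjacent windows partition the marker inventory
  expect_equal(c(w1@markers$pos, w2@markers$pos), whole@markers$pos)

  # buffer sufficiency, isolated from per-window state selection by using
  # the exhaustive state space (the copying chain mixes over ~S/(4*Ne)
  # Morgans, so the buffer must exceed that scale): dosages at core
  # markers match the whole-region run
  cfg2 <- SimConfig(regionBp = 1.6e6, nRefSamples = 25L,
                    nTargetSamples = 4L, chipMarkers = 400L, seed = 71L)
  sim2 <- simulatePanels(cfg2, method = "mosaic")
  msk2 <- maskToChip(sim2$targetTruth, sim2$reference, cfg2)
  exh <- SelectionConfig(L = 10000L, I = 0.002)
  wholeE <- imputeWindow(sim2$reference, msk2$targetObserved,
                         selection = exh)
  mid2 <- markers(sim2$reference)$pos[nMarkers(sim2$reference) %/% 2]
  w1E <- imputeWindow(sim2$reference, msk2$targetObserved, selection = exh,
                      plan = WindowPlan(sprintf("1:1-%d", mid2), 6e5))
  w2E <- imputeWindow(sim2$reference, msk2$targetObserved, selection = exh,
                      plan = WindowPlan(sprintf("1:%d-1600000", mid2 + 1L),
                                        6e5))
  expect_equal(cbind(dosages(w1E), dosages(w2E)), dosages(wholeE),
               tolerance = 1e-3)
})

test_that("imputation output is deterministic and typed markers echo alleles", {
  fx <- engineFixture(72L)
  ref <- fx$sim$reference; obs <- fx$msk$targetObserved
  res <- imputeWindow(ref, obs, selection = SelectionConfig(L = 4L, I = 0.002))

  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeImputedVcf(res, f1)
  res2 <- imputeWindow(ref, obs,
                       selection = SelectionConfig(L = 4L, I = 0.002))
  writeImputedVcf(res2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # typed markers carry the observed GT and an IMP/TYPED INFO flag
  lines <- readLines(f1)
  body <- lines[!startsWith(lines, "#")]
  info <- vapply(strsplit(body, "\t"), `[`, "", 8)
  expect_equal(sum(info == "TYPED"), nMarkers(obs))
  expect_equal(sum(info == "IMP"), nMarkers(ref) - nMarkers(obs))
  typedRows <- which(info == "TYPED")
  gt1 <- vapply(strsplit(body[typedRows[1]], "\t")[[1]][-(1:9)],
                function(x) sub(":.*", "", x), "")
  obsA <- alleles(obs)[, 1]
  expect_equal(unname(gt1),
               paste0(obsA[c(TRUE, FALSE)], "|", obsA[c(FALSE, TRUE)]))

  # haploid probabilities survive the VCF round trip at 3 decimals
  back <- readImputedVcf(f1)
  expect_equal(back$ap, unname(round(dosages(res), 3)), tolerance = 5e-4)
  expect_equal(back$markers$typed, res@markers$typed)
})

test_that("engine accepts files in both formats and validates inputs", {
  fx <- engineFixture(73L)
  ref <- fx$sim$reference; obs <- fx$msk$targetObserved
  sel <- SelectionConfig(L = 4L, I = 0.002)
  inMem <- imputeWindow(ref, obs, selection = sel)

  vcfRef <- tempfile(fileext = ".vcf"); writeVcfPanel(ref, vcfRef)
  vcfTgt <- tempfile(fileext = ".vcf"); writeVcfPanel(obs, vcfTgt)
  i5Ref <- tempfile(fileext = ".imp5"); writeImp5(ref, i5Ref)

  fromVcf <- imputeWindow(vcfRef, vcfTgt, selection = sel)
  expect_equal(dosages(fromVcf), dosages(inMem))
  fromImp5 <- imputeWindow(i5Ref, vcfTgt, selection = sel)
  expect_equal(dosages(fromImp5), dosages(inMem))

  # chromosome mismatch and empty windows are hard errors
  mk <- markers(obs); mk$chrom <- "9"
  other <- HaplotypePanel(alleles(obs), mk, hapIds(obs))
  expect_error(imputeWindow(ref, other, selection = sel), "chromosome")
  expect_error(imputeWindow(ref, obs, selection = sel,
                            plan = WindowPlan("1:999000000-999900000", 0)),
               "no reference markers")
})

test_that("the command-line interface drives the pipeline end to end", {
  cli <- system.file("cli", "pbwtimpute.R", package = "pbwtimpute")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  td <- tempfile("cli"); dir.create(td)

  fx <- engineFixture(74L)
  refV <- file.path(td, "ref.vcf"); writeVcfPanel(fx$sim$reference, refV)
  tgtV <- file.path(td, "chip.vcf"); writeVcfPanel(fx$msk$targetObserved, tgtV)
  truV <- file.path(td, "truth.vcf"); writeVcfPanel(fx$sim$targetTruth, truV)
  outV <- file.path(td, "imputed.vcf")

  st <- system2(rscript, c(cli, "impute", "--h", refV, "--g", tgtV,
                           "--o", outV, "--pbwt-depth", "4",
                           "--pbwt-cm", "0.002",
                           "--selection", "neighbour"),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  expect_true(file.exists(outV))

  tabF <- file.path(td, "r2.tsv")
  st2 <- system2(rscript, c(cli, "score", "--truth", truV,
                            "--imputed", outV, "--reference", refV,
                            "--o", tabF), stdout = FALSE, stderr = FALSE)
  expect_equal(st2, 0L)
  tab <- read.delim(tabF)
  expect_equal(nrow(tab), 12L)
  expect_true(any(tab$n_markers > 0))

  # unknown flags exit non-zero
  st3 <- system2(rscript, c(cli, "impute", "--bogus"), stdout = FALSE,
                 stderr = FALSE)
  expect_false(st3 == 0L)
})
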