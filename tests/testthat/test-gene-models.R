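test_that("longest variant per gene is kept and short genes are dropped", {
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "GENEA", tx = "NM_1", chrom = "chr1", strand = "+",
         txStart = 1000, txEnd = 31000,
         exonStarts = c(1000, 30000), exonEnds = c(1500, 31000)),
    list(gene = "GENEA", tx = "NM_2", chrom = "chr1", strand = "+",
         txStart = 1000, txEnd = 41000,
         exonStarts = c(1000, 40000), exonEnds = c(1500, 41000)),
    list(gene = "GENEB", tx = "NM_3", chrom = "chr2", strand = "+",
         txStart = 0, txEnd = 20000,
         exonStarts = c(0, 19000), exonEnds = c(500, 20000))))
  gm <- readGeneModels(f, format = "refflat", minLengthKb = 25)
  expect_equal(geneIds(gm), "GENEA")
  expect_equal(unname(geneLengthsKb(gm)["GENEA"]), 40)
})

test_that("minus-strand TSS is the high-coordinate transcript end", {
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "GENEM", tx = "NM_4", chrom = "chr1", strand = "-",
         txStart = 1000, txEnd = 31000,
         exonStarts = c(1000, 30500), exonEnds = c(1500, 31000))))
  gm <- readGeneModels(f, format = "refflat")
  expect_equal(unname(tssPositions(gm)["GENEM"]), 31000)
})

test_that("single-exon gene has an empty intron set", {
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "MONO", tx = "NM_5", chrom = "chr1", strand = "+",
         txStart = 0, txEnd = 30000,
         exonStarts = 0, exonEnds = 30000)))
  gm <- readGeneModels(f, format = "refflat")
  expect_equal(length(intronRanges(gm)[["MONO"]]), 0)
  expect_equal(nrow(intronBins(gm, "MONO")), 0)
})

test_that("conflicting chromosomes for one gene id are an error", {
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "DUP", tx = "NM_6", chrom = "chr1", strand = "+",
         txStart = 0, txEnd = 30000, exonStarts = 0, exonEnds = 30000),
    list(gene = "DUP", tx = "NM_7", chrom = "chr2", strand = "+",
         txStart = 0, txEnd = 30000, exonStarts = 0, exonEnds = 30000)))
  expect_error(readGeneModels(f, format = "refflat"), "multiple chromosomes")
})

test_that("malformed records are rejected with a line reference", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(paste(c("G", "T", "chr1", "+", "x", "100", "0", "100", "1",
                       "0,", "100,"), collapse = "\t")), f)
  expect_error(readGeneModels(f, format = "refflat"), "line 1")
})

test_that("BED12 round-trips the models written by the simulator", {
  we <- simulateCohort(nGenes = 4, seed = 3)
  d <- tempfile()
  writeCohort(we, d, bedGraph = FALSE)
  gm <- readGeneModels(file.path(d, "genes.bed"), format = "bed12")
  orig <- geneModels(we)
  expect_setequal(geneIds(gm), geneIds(orig))
  for (g in geneIds(orig)) {
    expect_equal(unname(geneLengthsKb(gm)[g]), unname(geneLengthsKb(orig)[g]))
    expect_equal(unname(tssPositions(gm)[g]), unname(tssPositions(orig)[g]))
    expect_equal(intronBins(gm, g), intronBins(orig, g))
  }
})

test_that("eligibility needs length > 25 kb and >= 20 positive intron bins", {
  mk <- function(id, lenKb, nPos) {
    vals <- c(rep(1, nPos), rep(0, 60 - nPos))
    new("IntronSignal", geneId = id,
        offsetsKb = seq(0, by = 0.1, length.out = 60), values = vals)
  }
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "OK", tx = "t1", chrom = "chr1", strand = "+",
         txStart = 0, txEnd = 30000, exonStarts = c(0, 29000),
         exonEnds = c(100, 30000)),
    list(gene = "FEWPOS", tx = "t2", chrom = "chr1", strand = "+",
         txStart = 40000, txEnd = 70000, exonStarts = c(40000, 69000),
         exonEnds = c(40100, 70000)),
    list(gene = "SHORT", tx = "t3", chrom = "chr1", strand = "+",
         txStart = 80000, txEnd = 104000, exonStarts = c(80000, 103000),
         exonEnds = c(80100, 104000))))
  gm <- readGeneModels(f, format = "refflat")
  sigs <- list(OK = mk("OK", 30, 25), FEWPOS = mk("FEWPOS", 30, 19),
               SHORT = mk("SHORT", 24, 50))
  expect_equal(eligibleGenes(gm, sigs), "OK")
})
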