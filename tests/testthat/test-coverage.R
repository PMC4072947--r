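test_that("5'-end binning counts each retained read once", {
  sam <- writeSam(tempfile(fileext = ".sam"), list(
    list(chrom = "chr1", pos1 = 301, len = 50),      # fully inside bin 4
    list(chrom = "chr1", pos1 = 951, len = 50),      # 5' end in bin 10
    list(chrom = "chr1", pos1 = 951, len = 50, flag = 16L),  # minus: 5' end 1000, bin 10
    list(chrom = "chr1", pos1 = 101, len = 50, mapq = 3L),   # multi-mapper
    list(chrom = "chr1", pos1 = 101, len = 50, flag = 256L), # secondary
    list(chrom = "chrUn_gl000220", pos1 = 101, len = 50)))   # rRNA contig
  cov <- binCoverage(sam, format = "sam")
  v <- coverageValues(cov)$chr1
  expect_equal(v[4], 1)
  expect_equal(v[10], 2)
  expect_equal(sum(v), 3)  # mass conservation: one count per retained read
  expect_null(coverageValues(cov)$chrUn_gl000220)
})

test_that("bedGraph intervals are rebinned by length-weighted averaging", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t300\t6", "chr1\t350\t400\t4"), f)
  cov <- binCoverage(f, format = "bedgraph")
  v <- coverageValues(cov)$chr1
  expect_equal(v[1:3], c(6, 6, 6))   # constant rebinning
  expect_equal(v[4], 4 * 50 / 100)   # half-bin overlap
})

test_that("normalization scales to 1e6, is idempotent and rejects empties", {
  mk <- function(vals) new("BinnedCoverage", values = list(chr1 = vals),
                           binSize = 100L, totalRaw = sum(vals),
                           normalized = FALSE, excludedContigs = character(0))
  cov <- normalizeCoverage(mk(rep(2, 1e3)))          # sums to 2000
  expect_equal(sum(coverageValues(cov)$chr1), 1e6)
  twice <- normalizeCoverage(cov)
  expect_equal(coverageValues(twice), coverageValues(cov))
  single <- normalizeCoverage(mk(c(rep(0, 9), 5)))
  expect_equal(coverageValues(single)$chr1[10], 1e6)
  expect_error(normalizeCoverage(mk(rep(0, 10))), "empty experiment")
})

test_that("intron signal drops exonic bins and orients offsets from the TSS", {
  f <- writeRefFlat(tempfile(fileext = ".txt"), list(
    list(gene = "P", tx = "t", chrom = "chr1", strand = "+",
         txStart = 0, txEnd = 2000, exonStarts = 0, exonEnds = 500)))
  gm <- readGeneModels(f, format = "refflat")
  cov <- new("BinnedCoverage", values = list(chr1 = as.numeric(1:40)),
             binSize = 100L, totalRaw = sum(1:40), normalized = FALSE,
             excludedContigs = character(0))
  s <- extractIntronSignal(gm, "P", cov)
  expect_equal(offsetsKb(s), seq(0.5, 1.9, by = 0.1))
  expect_equal(signalValues(s), as.numeric(6:20))
})

test_that("strand flip reverses values but keeps the offset grid", {
  mk <- function(strand) {
    f <- writeRefFlat(tempfile(fileext = ".txt"), list(
      list(gene = "G", tx = "t", chrom = "chr1", strand = strand,
           txStart = 1000, txEnd = 4000,
           exonStarts = c(1000, 3900), exonEnds = c(1100, 4000))))
    readGeneModels(f, format = "refflat")
  }
  cov <- new("BinnedCoverage", values = list(chr1 = as.numeric(1:50)),
             binSize = 100L, totalRaw = sum(1:50), normalized = FALSE,
             excludedContigs = character(0))
  sp <- extractIntronSignal(mk("+"), "G", cov)
  sm <- extractIntronSignal(mk("-"), "G", cov)
  expect_equal(offsetsKb(sp), offsetsKb(sm))
  expect_equal(signalValues(sm), rev(signalValues(sp)))
})

test_that("intron and exon-overlapping bins partition the transcript bins", {
  we <- simulateCohort(nGenes = 3, seed = 5)
  gm <- geneModels(we)
  for (g in geneIds(gm)) {
    gr <- gm@genes[g]
    s0 <- GenomicRanges::start(gr) - 1L; e0 <- GenomicRanges::end(gr)
    allBins <- seq(ceiling(s0 / 100), e0 %/% 100 - 1) * 100
    ib <- intronBins(gm, g)$binStart
    ex <- gm@exons[[g]]
    exonic <- vapply(allBins, function(b)
      any(b < GenomicRanges::end(ex) & b + 100 > GenomicRanges::start(ex) - 1),
      logical(1))
    expect_setequal(c(ib, allBins[exonic]), allBins)
    expect_length(intersect(ib, allBins[exonic]), 0)
  }
})

test_that("bedGraph written by the simulator round-trips the intron signal", {
  we <- simulateCohort(nGenes = 3, seed = 9)
  d <- tempfile()
  writeCohort(we, d, bedGraph = TRUE)
  gm <- geneModels(we)
  cov <- binCoverage(file.path(d, "t8_r1.bedgraph"), format = "bedgraph")
  for (g in geneIds(gm)) {
    direct <- intronSignal(we, "t8_r1", g)
    back <- extractIntronSignal(gm, g, cov)
    expect_equal(offsetsKb(back), offsetsKb(direct))
    expect_equal(signalValues(back), signalValues(direct), tolerance = 1e-8)
  }
})

test_that("normalized coverage exports and re-imports through bedGraph", {
  we <- simulateCohort(nGenes = 2, seed = 13)
  d <- tempfile()
  writeCohort(we, d, bedGraph = TRUE)
  cov <- normalizeCoverage(binCoverage(file.path(d, "t0_r1.bedgraph"),
                                       format = "bedgraph"))
  out <- tempfile(fileext = ".bedgraph")
  exportBedGraph(cov, out)
  cov2 <- binCoverage(out, format = "bedgraph")
  expect_equal(sum(coverageValues(cov2)$chrSim), 1e6, tolerance = 1e-6)
})
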