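#' Bin aligned reads or a bedGraph track onto a fixed 100-bp grid
#'
#' Builds the genome-wide per-sample profile in disjoint adjacent bins.
#' For SAM/BAM input only uniquely mapped reads are counted: records
#' without secondary/supplementary flags and with MAPQ >= \code{minMapq}
#' (multi-mappers receive low MAPQ from bowtie2-like aligners). In the
#' default \code{mode = "five_prime"} each read increments by 1 the bin
#' containing its 5' end, so total signal equals read count; in
#' \code{mode = "overlap"} each read distributes weight across the bins it
#' overlaps, proportional to the overlap. bedGraph intervals are rebinned
#' by length-weighted averaging onto the grid. Reads or intervals on
#' \code{excludeContigs} (default the rRNA contig \code{chrUn_gl000220})
#' contribute nothing.
#'
#' @param path SAM, BAM or bedGraph file. SAM files are converted on the
#'   fly with \code{Rsamtools::asBam}.
#' @param format "auto" (by extension), "bam", "sam" or "bedgraph".
#' @param binSize bin width in bp, default 100.
#' @param excludeContigs contig names to discard.
#' @param mode read-to-bin assignment for alignments.
#' @param minMapq minimum mapping quality for "uniquely mapped".
#' @return a raw (unnormalized) \linkS4class{BinnedCoverage}.
#' @export
binCoverage <- function(path, format = c("auto", "bam", "sam", "bedgraph"),
                        binSize = 100L,
                        excludeContigs = "chrUn_gl000220",
                        mode = c("five_prime", "overlap"),
                        minMapq = 10L) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  binSize <- as.integer(binSize)
  stopifnot(binSize > 0L)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bam = "bam", sam = "sam",
                     bedgraph = "bedgraph", bg = "bedgraph",
                     stop("cannot infer format from extension: ", ext))
  }
  if (format %in% c("bam", "sam")) {
    bam <- path
    if (format == "sam")
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = TRUE)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    ga <- ga[!is.na(S4Vectors::mcols(ga)$mapq) &
             S4Vectors::mcols(ga)$mapq >= minMapq]
    gr <- GenomicRanges::granges(ga)
    gr <- gr[!(as.character(GenomicRanges::seqnames(gr)) %in% excludeContigs)]
    vals <- .binAlignments(gr, binSize, mode)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    gr <- gr[!(as.character(GenomicRanges::seqnames(gr)) %in% excludeContigs)]
    vals <- .binBedGraph(gr, binSize)
  }
  new("BinnedCoverage", values = vals, binSize = binSize,
      totalRaw = sum(vapply(vals, sum, numeric(1))), normalized = FALSE,
      excludedContigs = as.character(excludeContigs))
}

.binAlignments <- function(gr, binSize, mode) {
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  vals <- list()
  for (ch in chroms) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    nbin <- as.integer(max(GenomicRanges::end(g)) %/% binSize + 1L)
    if (mode == "five_prime") {
      minus <- as.character(GenomicRanges::strand(g)) == "-"
      p5 <- ifelse(minus, GenomicRanges::end(g), GenomicRanges::start(g))
      idx <- (p5 - 1L) %/% binSize + 1L
      vals[[ch]] <- as.numeric(tabulate(idx, nbins = nbin))
    } else {
      v <- numeric(nbin)
      s0 <- GenomicRanges::start(g) - 1L
      e0 <- GenomicRanges::end(g)
      w <- e0 - s0
      for (k in seq_along(g)) {
        b0 <- s0[k] %/% binSize
        b1 <- (e0[k] - 1L) %/% binSize
        for (b in b0:b1) {
          ov <- min(e0[k], (b + 1L) * binSize) - max(s0[k], b * binSize)
          v[b + 1L] <- v[b + 1L] + ov / w[k]
        }
      }
      vals[[ch]] <- v
    }
  }
  vals
}

.binBedGraph <- function(gr, binSize) {
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  vals <- list()
  for (ch in chroms) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    nbin <- as.integer(max(GenomicRanges::end(g)) %/% binSize + 1L)
    v <- numeric(nbin)
    s0 <- GenomicRanges::start(g) - 1L
    e0 <- GenomicRanges::end(g)
    sc <- g$score
    for (k in seq_along(g)) {
      b0 <- s0[k] %/% binSize
      b1 <- (e0[k] - 1L) %/% binSize
      for (b in b0:b1) {
        ov <- min(e0[k], (b + 1L) * binSize) - max(s0[k], b * binSize)
        v[b + 1L] <- v[b + 1L] + sc[k] * ov / binSize
      }
    }
    vals[[ch]] <- v
  }
  vals
}

#' Normalize binned coverage to a fixed library total
#'
#' Scales every bin by \code{1e6 / sum(raw)} so the experiment total over
#' all retained contigs is 1e6. Idempotent; the raw total is retained in
#' the object metadata. An all-zero profile is an error ("empty
#' experiment").
#'
#' @rdname BinnedCoverage-class
#' @export
setMethod("normalizeCoverage", "BinnedCoverage", function(cov) {
  tot <- sum(vapply(cov@values, sum, numeric(1)))
  if (tot <= 0) stop("empty experiment: all-zero coverage")
  f <- 1e6 / tot
  new("BinnedCoverage", values = lapply(cov@values, function(v) v * f),
      binSize = cov@binSize, totalRaw = cov@totalRaw,
      normalized = TRUE, excludedContigs = cov@excludedContigs)
})

#' Extract the strand-oriented intronic signal of one gene
#'
#' Retains bins that lie fully within the transcript span and overlap no
#' exon (a bin overlapping both exon and intron counts as exonic, which is
#' conservative against mature-mRNA leakage). Offsets are the genomic
#' distance of each bin from the TSS in kb, strand-oriented: for minus
#' strand genes the vector is reversed so offset 0 is the TSS side. A gene
#' with no intronic bins yields an empty signal rather than an error.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param gene a gene id present in \code{genes}.
#' @param cov a \linkS4class{BinnedCoverage} containing the gene's
#'   chromosome.
#' @return an \linkS4class{IntronSignal}.
#' @export
extractIntronSignal <- function(genes, gene, cov) {
  gm <- genes[gene]
  g <- gm@genes
  ch <- as.character(GenomicRanges::seqnames(g))
  v <- cov@values[[ch]]
  if (is.null(v)) stop("chromosome ", ch, " absent from coverage")
  ib <- intronBins(genes, gene, binSize = cov@binSize)
  if (!nrow(ib))
    return(new("IntronSignal", geneId = gene, offsetsKb = numeric(0),
               values = numeric(0)))
  bins <- ib$binStart %/% cov@binSize
  vv <- numeric(length(bins))
  inside <- bins + 1L <= length(v)
  vv[inside] <- v[bins[inside] + 1L]
  new("IntronSignal", geneId = gene, offsetsKb = ib$offsetKb, values = vv)
}

#' Intron-bin geometry of one gene
#'
#' The fixed-width bins (grid anchored at genomic position 0) that lie
#' fully within the transcript span and overlap no exon, with their
#' strand-oriented offsets from the TSS. Rows are ordered by increasing
#' offset; \code{binStart} is the 0-based genomic start of each bin.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param gene a gene id.
#' @param binSize bin width, bp.
#' @return data.frame(binStart, offsetKb), possibly zero rows.
#' @export
intronBins <- function(genes, gene, binSize = 100L) {
  gm <- genes[gene]
  g <- gm@genes
  bs <- as.integer(binSize)
  s0 <- GenomicRanges::start(g) - 1L   # 0-based transcript span [s0, e0)
  e0 <- GenomicRanges::end(g)
  b0 <- as.integer(ceiling(s0 / bs))
  b1 <- as.integer(e0 %/% bs - 1L)
  empty <- data.frame(binStart = integer(0), offsetKb = numeric(0))
  if (b1 < b0) return(empty)
  bins <- b0:b1
  binStart <- bins * bs
  binEnd <- binStart + bs
  ex <- gm@exons[[1]]
  exonic <- rep(FALSE, length(bins))
  for (k in seq_along(ex)) {
    es <- GenomicRanges::start(ex)[k] - 1L
    ee <- GenomicRanges::end(ex)[k]
    exonic <- exonic | (binStart < ee & binEnd > es)
  }
  binStart <- binStart[!exonic]
  if (!length(binStart)) return(empty)
  tss0 <- tssPositions(gm)[[1]]
  if (as.character(GenomicRanges::strand(g)) == "-") {
    off <- (tss0 - (binStart + bs)) / 1000
    ord <- order(off)
    data.frame(binStart = binStart[ord], offsetKb = off[ord])
  } else {
    data.frame(binStart = binStart, offsetKb = (binStart - tss0) / 1000)
  }
}

#' Write binned coverage as bedGraph
#'
#' One line per bin with nonzero value, 0-based half-open intervals, sorted
#' by contig then start; deterministic output.
#'
#' @param cov a \linkS4class{BinnedCoverage}.
#' @param path output file.
#' @export
exportBedGraph <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- cov@binSize
  for (ch in sort(names(cov@values))) {
    v <- cov@values[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, (nz - 1L) * bs, nz * bs,
                       formatC(v[nz], digits = 10, format = "g")), con)
  }
  invisible(path)
}
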