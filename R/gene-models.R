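#' Read gene models from refFlat/genePred or BED12 annotation
#'
#' Parses transcript annotations and keeps, for each gene identifier, the
#' single variant with the longest primary transcript. Genes shorter than
#' \code{minLengthKb} are dropped. The TSS is the transcript 5' end on the
#' annotated strand (so for minus-strand transcripts the TSS is the higher
#' genomic coordinate).
#'
#' refFlat (11 columns, leading gene symbol) and genePred (10 columns) are
#' parsed directly; BED12 is read through \pkg{rtracklayer}. refFlat/genePred
#' coordinates are 0-based half-open as in the UCSC tables. A gene symbol
#' mapping to transcripts on different chromosomes is an error.
#'
#' @param path annotation file (tab-separated refFlat/genePred, or BED12).
#' @param format one of "auto", "refflat", "genepred", "bed12".
#' @param minLengthKb minimum transcript length retained, kb.
#' @return a \linkS4class{GeneModels}.
#' @export
readGeneModels <- function(path, format = c("auto", "refflat", "genepred",
                                            "bed12"), minLengthKb = 0) {
  format <- match.arg(format)
  stopifnot(minLengthKb >= 0)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    format <- if (length(first) >= 12 && !is.na(suppressWarnings(
                  as.integer(first[2])))) "bed12"
              else if (length(first) == 11) "refflat"
              else if (length(first) == 10) "genepred"
              else stop("cannot determine annotation format of ", path)
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks))
      stop("BED input lacks the 12-column block structure")
    ids <- gr$name
    chrom <- as.character(GenomicRanges::seqnames(gr))
    strand <- as.character(GenomicRanges::strand(gr))
    txStart <- GenomicRanges::start(gr) - 1L  # back to 0-based
    txEnd <- GenomicRanges::end(gr)
    exonStarts <- lapply(seq_along(gr), function(i)
      txStart[i] + GenomicRanges::start(gr$blocks[[i]]) - 1L)
    exonEnds <- lapply(seq_along(gr), function(i)
      txStart[i] + GenomicRanges::end(gr$blocks[[i]]))
  } else {
    ncol <- if (format == "refflat") 11L else 10L
    tab <- tryCatch(
      read.table(path, sep = "\t", stringsAsFactors = FALSE,
                 comment.char = "#", colClasses = "character"),
      error = function(e) stop("malformed annotation: ", conditionMessage(e)))
    if (ncol(tab) != ncol)
      stop("expected ", ncol, " columns for ", format, ", got ", ncol(tab))
    off <- if (format == "refflat") 1L else 0L
    bad <- which(is.na(suppressWarnings(as.integer(tab[[off + 4L]]))))
    if (length(bad))
      stop("malformed record at line ", bad[1], " of ", path)
    ids <- tab[[1L]]  # gene symbol (refflat) or transcript name (genepred)
    chrom <- tab[[off + 2L]]
    strand <- tab[[off + 3L]]
    txStart <- as.integer(tab[[off + 4L]])
    txEnd <- as.integer(tab[[off + 5L]])
    exonStarts <- lapply(strsplit(tab[[off + 9L]], ","), as.integer)
    exonEnds <- lapply(strsplit(tab[[off + 10L]], ","), as.integer)
  }
  if (!all(strand %in% c("+", "-")))
    stop("malformed strand field in ", path)
  len <- txEnd - txStart
  if (any(len <= 0)) stop("transcript with non-positive length in ", path)

  # longest variant per gene id; conflicting chromosomes are an error
  keep <- integer(0)
  for (id in unique(ids)) {
    idx <- which(ids == id)
    if (length(unique(chrom[idx])) > 1L)
      stop("gene ", id, " maps to multiple chromosomes")
    keep <- c(keep, idx[which.max(len[idx])])
  }
  keep <- keep[len[keep] / 1000 >= minLengthKb]
  if (!length(keep))
    return(new("GeneModels",
               genes = GenomicRanges::GRanges(),
               exons = GenomicRanges::GRangesList()))

  genes <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = txStart[keep] + 1L, end = txEnd[keep]),
    strand = strand[keep])
  names(genes) <- ids[keep]
  exons <- GenomicRanges::GRangesList(lapply(keep, function(i) {
    GenomicRanges::GRanges(
      seqnames = chrom[i],
      ranges = IRanges::IRanges(start = exonStarts[[i]] + 1L,
                                end = exonEnds[[i]]),
      strand = strand[i])
  }))
  names(exons) <- ids[keep]
  new("GeneModels", genes = genes, exons = exons)
}

#' Gene eligibility for boundary detection
#'
#' A gene enters the boundary-detection algorithm only if it is longer than
#' \code{minGeneKb} (strictly) and its reference intron signal has at least
#' \code{minPositiveBins} bins with positive values. The reference signal is
#' the averaged 0-min profile.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param signals named list of \linkS4class{IntronSignal}, one per gene,
#'   computed from the reference (averaged 0-min) sample.
#' @param minGeneKb minimum gene length, kb (default 25).
#' @param minPositiveBins minimum positive intron bins (default 20).
#' @return character vector of retained gene ids.
#' @export
eligibleGenes <- function(genes, signals, minGeneKb = 25,
                          minPositiveBins = 20L) {
  lk <- geneLengthsKb(genes)
  ok <- vapply(geneIds(genes), function(id) {
    s <- signals[[id]]
    if (is.null(s)) return(FALSE)
    lk[[id]] > minGeneKb && sum(signalValues(s) > 0) >= minPositiveBins
  }, logical(1))
  geneIds(genes)[ok]
}
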