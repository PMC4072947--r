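#' @rdname GeneModels-class
#' @param object,x a package object
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-class
#' @export
setGeneric("geneLengthsKb", function(x) standardGeneric("geneLengthsKb"))

#' @rdname GeneModels-class
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))

#' @rdname GeneModels-class
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @rdname IntronSignal-class
#' @export
setGeneric("offsetsKb", function(x) standardGeneric("offsetsKb"))

#' @rdname IntronSignal-class
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname IntronSignal-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname BinnedCoverage-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedCoverage-class
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))

#' @rdname BinnedCoverage-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname BinnedCoverage-class
#' @param cov a \linkS4class{BinnedCoverage}
#' @export
setGeneric("normalizeCoverage", function(cov) standardGeneric("normalizeCoverage"))

#' @rdname WaveExperiment-class
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname WaveExperiment-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname WaveExperiment-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname WaveExperiment-class
#' @param sample sample label
#' @param gene gene identifier
#' @export
setGeneric("intronSignal", function(x, sample, gene) standardGeneric("intronSignal"))

# ---- GeneModels methods ----

#' @rdname GeneModels-class
#' @export
setMethod("geneIds", "GeneModels", function(x) names(x@genes))

#' @rdname GeneModels-class
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @rdname GeneModels-class
#' @export
setMethod("geneLengthsKb", "GeneModels",
  function(x) setNames(GenomicRanges::width(x@genes) / 1000, names(x@genes)))

#' @rdname GeneModels-class
#' @export
setMethod("tssPositions", "GeneModels", function(x) {
  g <- x@genes
  minus <- as.character(GenomicRanges::strand(g)) == "-"
  # 0-based boundary coordinate of the TSS: plus-strand start-1, minus end
  pos <- ifelse(minus, GenomicRanges::end(g), GenomicRanges::start(g) - 1L)
  setNames(pos, names(g))
})

#' @rdname GeneModels-class
#' @export
setMethod("intronRanges", "GeneModels", function(x) {
  res <- GenomicRanges::psetdiff(x@genes, x@exons)
  names(res) <- names(x@genes)
  res
})

#' @rdname GeneModels-class
#' @param i index or gene id
#' @export
setMethod("[", "GeneModels", function(x, i) {
  new("GeneModels", genes = x@genes[i], exons = x@exons[i])
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object), "genes\n")
  if (length(object)) {
    lk <- geneLengthsKb(object)
    cat("  length range:", round(min(lk), 1), "-", round(max(lk), 1), "kb\n")
    cat("  chromosomes:",
        paste(unique(as.character(GenomicRanges::seqnames(object@genes))),
              collapse = ", "), "\n")
  }
})

# ---- IntronSignal methods ----

#' @rdname IntronSignal-class
#' @export
setMethod("geneIds", "IntronSignal", function(x) x@geneId)

#' @rdname IntronSignal-class
#' @export
setMethod("offsetsKb", "IntronSignal", function(x) x@offsetsKb)

#' @rdname IntronSignal-class
#' @export
setMethod("signalValues", "IntronSignal", function(x) x@values)

#' @rdname IntronSignal-class
#' @export
setMethod("nBins", "IntronSignal", function(x) length(x@values))

setMethod("show", "IntronSignal", function(object) {
  cat("IntronSignal for", object@geneId, "with", nBins(object), "bins")
  if (nBins(object))
    cat(" spanning", min(object@offsetsKb), "-", max(object@offsetsKb),
        "kb from TSS")
  cat("\n")
})

# ---- BinnedCoverage methods ----

#' @rdname BinnedCoverage-class
#' @export
setMethod("binSize", "BinnedCoverage", function(x) x@binSize)

#' @rdname BinnedCoverage-class
#' @export
setMethod("coverageValues", "BinnedCoverage", function(x) x@values)

#' @rdname BinnedCoverage-class
#' @export
setMethod("isNormalized", "BinnedCoverage", function(x) x@normalized)

setMethod("show", "BinnedCoverage", function(object) {
  cat("BinnedCoverage:", length(object@values), "contigs,",
      object@binSize, "bp bins,",
      if (object@normalized) "normalized (sum 1e6)" else "raw", "\n")
  cat("  total raw signal:", object@totalRaw, "\n")
  if (length(object@excludedContigs))
    cat("  excluded contigs:",
        paste(object@excludedContigs, collapse = ", "), "\n")
})

# ---- WaveExperiment methods ----

#' @rdname WaveExperiment-class
#' @export
setMethod("sampleSheet", "WaveExperiment", function(x) x@sampleSheet)

#' @rdname WaveExperiment-class
#' @export
setMethod("truthTable", "WaveExperiment", function(x) x@truth)

#' @rdname WaveExperiment-class
#' @export
setMethod("geneModels", "WaveExperiment", function(x) x@genes)

#' @rdname WaveExperiment-class
#' @export
setMethod("geneIds", "WaveExperiment", function(x) geneIds(x@genes))

#' @rdname WaveExperiment-class
#' @export
setMethod("intronSignal", "WaveExperiment", function(x, sample, gene) {
  sig <- x@signals[[sample]]
  if (is.null(sig)) stop("unknown sample label: ", sample)
  s <- sig[[gene]]
  if (is.null(s)) stop("unknown gene: ", gene)
  s
})

setMethod("show", "WaveExperiment", function(object) {
  ss <- object@sampleSheet
  cat("WaveExperiment:", length(object@genes), "genes,", nrow(ss),
      "samples\n")
  tb <- table(ss$timepoint_min)
  cat("  replicates:",
      paste(sprintf("%s min x%d", names(tb), as.integer(tb)),
            collapse = ", "), "\n")
  if (nrow(object@truth))
    cat("  simulated (truth table with", nrow(object@truth), "genes)\n")
})
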