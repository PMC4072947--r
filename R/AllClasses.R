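#' @import methods
#' @importFrom stats lm coef qt sd predict median cor setNames
#' @importFrom utils read.table write.table head tail
NULL

#' Gene models (longest transcript variant per gene)
#'
#' Container for one transcript model per gene: the transcript range with
#' strand, and its exon structure. Introns are the gaps between consecutive
#' exons. The TSS is the 5' end of the transcript on the annotated strand.
#'
#' @slot genes a \link[GenomicRanges]{GRanges} of transcript spans, one per
#'   gene, named by gene identifier.
#' @slot exons a \link[GenomicRanges]{GRangesList} parallel to \code{genes}
#'   with the exon intervals of each transcript, sorted and non-overlapping.
#'
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  e <- object@exons
  if (length(g) != length(e))
    return("genes and exons must be parallel")
  if (is.null(names(g)) || anyDuplicated(names(g)))
    return("genes must be uniquely named by gene_id")
  if (!all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
    return("strand must be + or - for every gene")
  if (any(GenomicRanges::width(g) <= 0))
    return("transcript length must be positive")
  for (i in seq_along(g)) {
    ex <- e[[i]]
    if (length(ex) == 0L) return("each gene needs at least one exon")
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L)
      return("exons must be sorted by start")
    if (length(ex) > 1L && any(st[-1] <= en[-length(ex)]))
      return("exons must be non-overlapping")
    if (min(st) < GenomicRanges::start(g[i]) ||
        max(en) > GenomicRanges::end(g[i]))
      return("exons must lie within the transcript span")
  }
  TRUE
})

#' Binned genome-wide coverage for one sample
#'
#' Genome-wide signal in disjoint, adjacent fixed-width bins (default
#' 100 bp); bin \code{i} (0-based) covers \code{[i*binSize, (i+1)*binSize)}.
#' After \code{\link{normalizeCoverage}} the values over all retained
#' contigs sum to 1e6.
#'
#' @slot values named list, one numeric vector of per-bin values per contig.
#' @slot binSize integer bin width in bp.
#' @slot totalRaw total raw signal before normalization.
#' @slot normalized logical; TRUE after scaling to a 1e6 total.
#' @slot excludedContigs contigs whose reads were discarded (e.g. the
#'   rRNA-bearing \code{chrUn_gl000220}).
#'
#' @export
setClass("BinnedCoverage",
  representation(values = "list", binSize = "integer", totalRaw = "numeric",
                 normalized = "logical", excludedContigs = "character"))

setValidity("BinnedCoverage", function(object) {
  if (object@binSize <= 0L) return("binSize must be positive")
  if (length(object@values) && is.null(names(object@values)))
    return("values must be named by contig")
  for (v in object@values) {
    if (!is.numeric(v)) return("per-contig values must be numeric")
    if (any(v < 0)) return("coverage values must be non-negative")
  }
  TRUE
})

#' Strand-oriented intronic signal of one gene
#'
#' The gene's coverage restricted to bins that overlap no exon and lie
#' fully within the transcript. Offsets are genomic distances of each
#' retained bin from the TSS, strand-oriented (offset 0 is the TSS side),
#' in kb, strictly increasing. An empty signal (single-exon gene) is legal
#' and marks the gene ineligible downstream.
#'
#' @slot geneId gene identifier.
#' @slot offsetsKb numeric, strictly increasing, >= 0.
#' @slot values numeric, same length as \code{offsetsKb}.
#'
#' @export
setClass("IntronSignal",
  representation(geneId = "character", offsetsKb = "numeric",
                 values = "numeric"))

setValidity("IntronSignal", function(object) {
  if (length(object@offsetsKb) != length(object@values))
    return("offsetsKb and values must have equal length")
  if (length(object@offsetsKb)) {
    if (any(object@offsetsKb < 0)) return("offsets must be >= 0")
    if (is.unsorted(object@offsetsKb, strictly = TRUE))
      return("offsets must be strictly increasing")
  }
  TRUE
})

#' Averaged pre-release (0-min) reference profile of one gene
#'
#' Built by averaging the 0-min replicates on the gene's intron-bin grid,
#' then smoothing. \code{corrected} is the background-corrected smoothed
#' profile used in the rough boundary comparison; \code{denom} is the
#' smoothed (mean + 0.01) profile used as the strictly positive ratio
#' denominator in refinement; \code{rawMean} is the unsmoothed replicate
#' mean used as the initiation-fit denominator (plus 1).
#'
#' @slot geneId gene identifier.
#' @slot offsetsKb the shared intron-bin offset grid, kb from the TSS.
#' @slot corrected numeric; smoothed, background-corrected mean profile.
#' @slot denom numeric; smoothed pseudocounted mean profile, all > 0.
#' @slot rawMean numeric; unsmoothed replicate mean.
#' @slot nReplicates integer number of 0-min replicates averaged.
#'
#' @export
setClass("ZeroProfile",
  representation(geneId = "character", offsetsKb = "numeric",
                 corrected = "numeric", denom = "numeric",
                 rawMean = "numeric", nReplicates = "integer"))

setValidity("ZeroProfile", function(object) {
  n <- length(object@offsetsKb)
  if (length(object@corrected) != n || length(object@denom) != n ||
      length(object@rawMean) != n)
    return("profile vectors must share the offset grid")
  if (n && any(object@denom <= 0))
    return("ratio denominator must be strictly positive")
  if (object@nReplicates < 1L) return("needs at least one 0-min replicate")
  TRUE
})

#' Pipeline parameters
#'
#' All tunable constants of the wave-calling pipeline, defaulting to the
#' published values. See the methods vignette for units and rationale.
#'
#' @slot binSize bin width, bp (100).
#' @slot minGeneKb minimum gene length for boundary calling, kb (25).
#' @slot minPositiveBins minimum intron bins with positive signal (20).
#' @slot metageneMinKb minimum gene length for the metagene profile (20).
#' @slot smoothingP cubic smoothing-spline parameter p (1e-5) under the
#'   objective p*sum(residual^2) + (1-p)*integral(f'')^2.
#' @slot pseudocountZero value added to 0-min bins before smoothing the
#'   ratio denominator (0.01, rule of succession).
#' @slot pseudocountInitiation value added to the averaged 0-min signal in
#'   the initiation fit denominator (1).
#' @slot roughTolerance relative tolerance of the rough comparison (0.10).
#' @slot startOffsetKb first offset eligible as a boundary, kb (2.5).
#' @slot derivMinThreshold derivative threshold qualifying a minimum (-0.01).
#' @slot derivZeroThreshold "close to zero" derivative threshold (-0.002).
#' @slot refineWindowKb refinement cap downstream of the rough call, kb (2).
#' @slot ciMaxKbPerMin maximum 50% CI half-width passing QC, kb/min (0.5).
#' @slot delayRange admissible delay-time interval, min (-1, 4).
#' @slot labelTimeMin recovery window T, min (8).
#' @slot excludeFirstKb kb excluded at the 5' end of the initiation fit (0;
#'   2 for the pause-robustness variant).
#' @slot tauAlpha significance level of the modified Thompson tau test (0.05).
#'
#' @export
setClass("WaveParams",
  representation(binSize = "integer", minGeneKb = "numeric",
    minPositiveBins = "integer", metageneMinKb = "numeric",
    smoothingP = "numeric", pseudocountZero = "numeric",
    pseudocountInitiation = "numeric", roughTolerance = "numeric",
    startOffsetKb = "numeric", derivMinThreshold = "numeric",
    derivZeroThreshold = "numeric", refineWindowKb = "numeric",
    ciMaxKbPerMin = "numeric", delayRange = "numeric",
    labelTimeMin = "numeric", excludeFirstKb = "numeric",
    tauAlpha = "numeric"))

setValidity("WaveParams", function(object) {
  if (object@smoothingP < 0 || object@smoothingP > 1)
    return("smoothingP must be in [0, 1]")
  if (object@pseudocountZero <= 0) return("pseudocountZero must be > 0")
  if (length(object@delayRange) != 2L ||
      object@delayRange[1] > object@delayRange[2])
    return("delayRange must be an ordered pair")
  if (object@binSize <= 0L) return("binSize must be positive")
  TRUE
})

#' A multi-sample wave experiment
#'
#' Per-gene intronic signals for every sample of a DRB-release time course,
#' plus the sample sheet (label, timepoint, replicate) and gene models.
#' Simulated experiments additionally carry the generative truth table.
#'
#' @slot genes a \linkS4class{GeneModels}.
#' @slot signals named list (one element per sample label) of named lists of
#'   \linkS4class{IntronSignal} (one per gene).
#' @slot sampleSheet data.frame with columns label, timepoint_min, replicate.
#' @slot truth data.frame of generative parameters (simulated data) or a
#'   zero-row data.frame.
#'
#' @export
setClass("WaveExperiment",
  representation(genes = "GeneModels", signals = "list",
                 sampleSheet = "data.frame", truth = "data.frame"))

setValidity("WaveExperiment", function(object) {
  ss <- object@sampleSheet
  need <- c("label", "timepoint_min", "replicate")
  if (!all(need %in% names(ss)))
    return("sampleSheet needs columns label, timepoint_min, replicate")
  if (!setequal(names(object@signals), ss$label))
    return("signals must be named by the sample sheet labels")
  if (anyDuplicated(ss$label)) return("sample labels must be unique")
  if (!all(ss$timepoint_min %in% c(0, 4, 8)))
    return("timepoints must be 0, 4 or 8 min")
  dup <- duplicated(ss[, c("timepoint_min", "replicate")])
  if (any(dup)) return("replicate indices must be unique per timepoint")
  TRUE
})
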