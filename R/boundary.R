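#' Build the averaged 0-min reference profile of a gene
#'
#' Averages the 0-min biological replicates element-wise on the shared
#' intron-bin grid, then derives the two smoothed views used downstream:
#' the background-corrected profile (rough-boundary comparison) and the
#' pseudocounted strictly positive profile (ratio denominator; the 0.01
#' pseudocount is added to the raw mean before smoothing, per the rule of
#' succession). With a single replicate a warning is emitted.
#'
#' @param zeroSignals list of \linkS4class{IntronSignal}, one per 0-min
#'   replicate of the same gene, on identical offset grids.
#' @param params a \linkS4class{WaveParams}.
#' @return a \linkS4class{ZeroProfile}.
#' @export
averageZeroProfile <- function(zeroSignals, params = waveParams()) {
  stopifnot(length(zeroSignals) >= 1L)
  off <- offsetsKb(zeroSignals[[1]])
  gid <- geneIds(zeroSignals[[1]])
  for (s in zeroSignals[-1]) {
    if (!isTRUE(all.equal(offsetsKb(s), off)))
      stop("0-min replicates are on mismatched offset grids for ", gid)
  }
  if (length(zeroSignals) == 1L)
    warning("single 0-min replicate for ", gid, "; averaging degenerate")
  vals <- do.call(rbind, lapply(zeroSignals, signalValues))
  rawMean <- colMeans(vals)
  if (length(off) < 4L) {
    # too short to smooth; degenerate profile passes through unsmoothed
    sm <- rawMean
    denom <- rawMean + params@pseudocountZero
    corrected <- backgroundCorrect(sm, backgroundTrack(sm))
  } else {
    xbp <- off * 1000
    sm <- smoothSignal(rawMean, x = xbp, p = params@smoothingP)
    corrected <- backgroundCorrect(sm, backgroundTrack(sm))
    denom <- smoothSignal(rawMean + params@pseudocountZero, x = xbp,
                          p = params@smoothingP)
  }
  if (any(denom <= 0))
    denom <- pmax(denom, params@pseudocountZero * 1e-3)
  new("ZeroProfile", geneId = gid, offsetsKb = off, corrected = corrected,
      denom = denom, rawMean = rawMean,
      nReplicates = length(zeroSignals))
}

#' Rough wave-front estimate
#'
#' The first bin downstream of TSS + \code{startOffsetKb} where the
#' sample's background-corrected signal is no higher than the 0-min profile
#' at the same position, up to the relative tolerance (default 10%,
#' i.e. sample <= 1.1 * zero). If that bin is the very first eligible
#' position, or no bin qualifies, no boundary is determined.
#'
#' @param sampleCorrected background-corrected smoothed sample profile.
#' @param zeroCorrected background-corrected smoothed 0-min profile.
#' @param offsetsKb shared offset grid, kb from TSS.
#' @param startOffsetKb first eligible offset, kb (default 2.5).
#' @param tolerance relative tolerance (default 0.10).
#' @return list(index, status) where index is the bin index or NA and
#'   status one of "ok", "no-boundary", "first-position".
#' @export
roughBoundary <- function(sampleCorrected, zeroCorrected, offsetsKb,
                          startOffsetKb = 2.5, tolerance = 0.10) {
  stopifnot(length(sampleCorrected) == length(zeroCorrected),
            length(sampleCorrected) == length(offsetsKb))
  elig <- which(offsetsKb >= startOffsetKb)
  if (!length(elig)) return(list(index = NA_integer_, status = "no-boundary"))
  hit <- elig[sampleCorrected[elig] <= (1 + tolerance) * zeroCorrected[elig]]
  if (!length(hit)) return(list(index = NA_integer_, status = "no-boundary"))
  if (hit[1] == elig[1])
    return(list(index = NA_integer_, status = "first-position"))
  list(index = hit[1], status = "ok")
}

#' Refine a wave-front estimate from the ratio derivative
#'
#' Among the local minima of the sample/0-min ratio derivative upstream of
#' the rough estimate with depth below \code{minThreshold}, the most
#' downstream one is selected; the refined boundary is then the first bin
#' downstream of that minimum whose derivative has returned close to zero
#' (>= \code{zeroThreshold}), no further than \code{windowKb} downstream of
#' the rough estimate. If no qualifying minimum or bin exists the rough
#' estimate is kept.
#'
#' @param deriv ratio derivative (length n-1, from
#'   \code{\link{ratioDerivative}}); \code{deriv[i]} is the step from bin i
#'   to bin i+1.
#' @param roughIdx rough-estimate bin index.
#' @param offsetsKb offset grid of the signal bins, kb.
#' @param minThreshold qualifying-minimum depth (default -0.01).
#' @param zeroThreshold "close to zero" derivative level (default -0.002).
#' @param windowKb cap downstream of the rough estimate, kb (default 2).
#' @return list(index, refined) with the refined bin index and a logical
#'   saying whether refinement moved off the rough estimate.
#' @export
refineBoundary <- function(deriv, roughIdx, offsetsKb,
                           minThreshold = -0.01, zeroThreshold = -0.002,
                           windowKb = 2) {
  stopifnot(roughIdx >= 1L, roughIdx <= length(deriv) + 1L)
  mins <- localMinima(deriv, depthThreshold = minThreshold)
  mins <- mins[mins < roughIdx]
  if (!length(mins)) return(list(index = roughIdx, refined = FALSE))
  m <- max(mins)
  if (m >= length(deriv)) return(list(index = roughIdx, refined = FALSE))
  cap <- offsetsKb[roughIdx] + windowKb
  cand <- seq(m + 1L, length(deriv))
  cand <- cand[offsetsKb[cand] <= cap & deriv[cand] >= zeroThreshold]
  if (!length(cand)) return(list(index = roughIdx, refined = FALSE))
  list(index = cand[1], refined = TRUE)
}

#' Call the transcription-wave front for one gene in one sample
#'
#' Orchestrates the per-sample boundary call: smooth the sample's intron
#' signal, estimate and subtract the downstream background, locate the
#' rough front against the averaged 0-min profile, then refine it from the
#' derivative of the sample/0-min ratio. Positions are reported in kb from
#' the TSS at the bin's offset.
#'
#' @param sampleSignal the gene's \linkS4class{IntronSignal} in one 4- or
#'   8-min sample.
#' @param zero the gene's \linkS4class{ZeroProfile}.
#' @param params a \linkS4class{WaveParams}.
#' @return list(rough_kb, refined_kb, status); positions are NA unless
#'   status is "ok" or "refine-fallback".
#' @export
callBoundary <- function(sampleSignal, zero, params = waveParams()) {
  off <- offsetsKb(sampleSignal)
  if (length(off) < 4L)
    return(list(rough_kb = NA_real_, refined_kb = NA_real_,
                status = "no-boundary"))
  if (!isTRUE(all.equal(off, zero@offsetsKb)))
    stop("sample and 0-min profile are on mismatched grids for ",
         geneIds(sampleSignal))
  sm <- smoothSignal(signalValues(sampleSignal), x = off * 1000,
                     p = params@smoothingP)
  corr <- backgroundCorrect(sm, backgroundTrack(sm))
  rough <- roughBoundary(corr, zero@corrected, off,
                         startOffsetKb = params@startOffsetKb,
                         tolerance = params@roughTolerance)
  if (is.na(rough$index))
    return(list(rough_kb = NA_real_, refined_kb = NA_real_,
                status = rough$status))
  d <- ratioDerivative(corr, zero@denom)
  ref <- refineBoundary(d, rough$index, off,
                        minThreshold = params@derivMinThreshold,
                        zeroThreshold = params@derivZeroThreshold,
                        windowKb = params@refineWindowKb)
  list(rough_kb = off[rough$index], refined_kb = off[ref$index],
       status = if (ref$refined) "ok" else "refine-fallback")
}

#' Call boundaries for all genes and post-release samples of an experiment
#'
#' @param we a \linkS4class{WaveExperiment}.
#' @param genes character vector of gene ids to process (typically the
#'   output of \code{\link{eligibleGenes}}).
#' @param zeroProfiles named list of \linkS4class{ZeroProfile} per gene.
#' @param params a \linkS4class{WaveParams}.
#' @return data.frame: gene_id, timepoint_min, replicate, rough_kb,
#'   refined_kb, status.
#' @export
callBoundaries <- function(we, genes, zeroProfiles, params = waveParams()) {
  ss <- sampleSheet(we)
  post <- ss[ss$timepoint_min %in% c(4, 8), , drop = FALSE]
  rows <- vector("list", nrow(post) * length(genes))
  k <- 0L
  for (j in seq_len(nrow(post))) {
    lab <- post$label[j]
    for (g in genes) {
      call <- callBoundary(intronSignal(we, lab, g), zeroProfiles[[g]],
                           params)
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = g,
                              timepoint_min = post$timepoint_min[j],
                              replicate = post$replicate[j],
                              rough_kb = call$rough_kb,
                              refined_kb = call$refined_kb,
                              status = call$status,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
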