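#' Construct pipeline parameters
#'
#' Every numeric default equals the published value it mirrors; see
#' \linkS4class{WaveParams} for the meaning of each field.
#'
#' @param ... named overrides of \linkS4class{WaveParams} slots.
#' @return a \linkS4class{WaveParams}.
#' @export
waveParams <- function(...) {
  p <- new("WaveParams", binSize = 100L, minGeneKb = 25,
           minPositiveBins = 20L, metageneMinKb = 20, smoothingP = 1e-5,
           pseudocountZero = 0.01, pseudocountInitiation = 1,
           roughTolerance = 0.10, startOffsetKb = 2.5,
           derivMinThreshold = -0.01, derivZeroThreshold = -0.002,
           refineWindowKb = 2, ciMaxKbPerMin = 0.5, delayRange = c(-1, 4),
           labelTimeMin = 8, excludeFirstKb = 0, tauAlpha = 0.05)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), slotNames("WaveParams"))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(ov))
      slot(p, nm) <- if (nm %in% c("binSize", "minPositiveBins"))
        as.integer(ov[[nm]]) else as.numeric(ov[[nm]])
    validObject(p)
  }
  p
}

#' Serialize / deserialize pipeline parameters
#'
#' Flat key: value YAML; unknown keys are rejected on read to guard
#' against silent typos. Round-trips unchanged.
#'
#' @param params a \linkS4class{WaveParams}.
#' @param path file path.
#' @rdname waveParamsIO
#' @export
writeWaveParams <- function(params, path) {
  vals <- lapply(slotNames("WaveParams"), function(nm) slot(params, nm))
  names(vals) <- slotNames("WaveParams")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname waveParamsIO
#' @export
readWaveParams <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), slotNames("WaveParams"))
  if (length(bad)) stop("unknown parameter key(s): ",
                        paste(bad, collapse = ", "))
  do.call(waveParams, vals)
}

#' Run the full wave-calling pipeline on an experiment
#'
#' Checks the replicate design (at least one 0-min, two 4-min and three
#' 8-min samples), averages the 0-min replicates per gene, applies the
#' eligibility filters, calls rough and refined boundaries for every
#' gene/sample, fits elongation rates with QC, infers relative initiation
#' frequencies, and computes the TSS-anchored metagene profile. Fully
#' deterministic given the experiment and parameters. Per-stage gene
#' counts are recorded in the audit table.
#'
#' @param we a \linkS4class{WaveExperiment}.
#' @param params a \linkS4class{WaveParams}.
#' @return list(boundaries, rates, initiation, metagene, audit,
#'   zeroProfiles, eligible, params).
#' @export
runPipeline <- function(we, params = waveParams()) {
  ss <- sampleSheet(we)
  n0 <- sum(ss$timepoint_min == 0)
  n4 <- sum(ss$timepoint_min == 4)
  n8 <- sum(ss$timepoint_min == 8)
  if (n0 < 1L) stop("boundary calling requires at least one 0-min sample")
  if (n4 < 2L)
    stop("rate estimation requires boundaries in both of the 4 min ",
         "samples: at least two 4-min samples are needed (found ", n4, ")")
  if (n8 < 3L)
    stop("rate estimation requires boundaries in at least three of the ",
         "four 8 min samples: at least three 8-min samples are needed ",
         "(found ", n8, ")")
  genes <- geneModels(we)
  zeroLabs <- ss$label[ss$timepoint_min == 0]
  zeroSignals <- lapply(geneIds(genes), function(g)
    lapply(zeroLabs, function(l) intronSignal(we, l, g)))
  names(zeroSignals) <- geneIds(genes)
  # eligibility is evaluated on the averaged raw 0-min intron profile
  rawZeroMeans <- lapply(zeroSignals, function(zl) {
    if (!nBins(zl[[1]]))
      return(zl[[1]])
    new("IntronSignal", geneId = geneIds(zl[[1]]),
        offsetsKb = offsetsKb(zl[[1]]),
        values = colMeans(do.call(rbind, lapply(zl, signalValues))))
  })
  elig <- eligibleGenes(genes, rawZeroMeans, minGeneKb = params@minGeneKb,
                        minPositiveBins = params@minPositiveBins)
  zeroProfiles <- lapply(elig, function(g)
    suppressWarnings(averageZeroProfile(zeroSignals[[g]], params)))
  names(zeroProfiles) <- elig
  boundaries <- callBoundaries(we, elig, zeroProfiles, params)
  rates <- estimateRates(boundaries, params)
  initiation <- estimateInitiation(we, zeroProfiles, boundaries, rates,
                                   params)
  metagene <- metageneProfile(we, minLengthKb = params@metageneMinKb)
  audit <- data.frame(
    stage = c("genes_annotated", "genes_eligible", "genes_with_rate_fit",
              "genes_pass_qc", "genes_with_initiation"),
    n = c(length(genes), length(elig), sum(is.na(rates$reason)),
          sum(rates$pass_qc),
          if (nrow(initiation)) sum(!is.na(initiation$relative_I)) else 0L),
    stringsAsFactors = FALSE)
  list(boundaries = boundaries, rates = rates, initiation = initiation,
       metagene = metagene, audit = audit, zeroProfiles = zeroProfiles,
       eligible = elig, params = params)
}

#' TSS-anchored metagene profile per timepoint
#'
#' For genes longer than \code{minLengthKb}, averages the intronic signal
#' over genes and replicates at each strand-oriented TSS-relative offset;
#' a gene lacking an intron bin at a given offset is skipped at that
#' offset.
#'
#' @param we a \linkS4class{WaveExperiment}.
#' @param minLengthKb minimum gene length, kb (default 20).
#' @param maxOffsetKb truncate the profile at this offset (default the
#'   longest gene).
#' @return data.frame: timepoint_min, offset_kb, mean_signal, n_obs.
#' @export
metageneProfile <- function(we, minLengthKb = 20, maxOffsetKb = Inf) {
  genes <- geneModels(we)
  keep <- geneIds(genes)[geneLengthsKb(genes) > minLengthKb]
  if (!length(keep)) stop("no genes longer than ", minLengthKb, " kb")
  ss <- sampleSheet(we)
  out <- list()
  for (tp in sort(unique(ss$timepoint_min))) {
    labs <- ss$label[ss$timepoint_min == tp]
    tabs <- list()
    for (l in labs) {
      for (g in keep) {
        s <- intronSignal(we, l, g)
        if (!nBins(s)) next
        sel <- offsetsKb(s) <= maxOffsetKb
        tabs[[length(tabs) + 1L]] <-
          data.frame(off = offsetsKb(s)[sel], val = signalValues(s)[sel])
      }
    }
    tab <- do.call(rbind, tabs)
    if (is.null(tab)) next
    # bin offsets to 0.1 kb to make the grid exact across genes
    ok <- round(tab$off, 1)
    ms <- tapply(tab$val, ok, mean)
    no <- tapply(tab$val, ok, length)
    out[[length(out) + 1L]] <- data.frame(
      timepoint_min = tp, offset_kb = as.numeric(names(ms)),
      mean_signal = as.numeric(ms), n_obs = as.integer(no))
  }
  res <- do.call(rbind, out)
  res[order(res$timepoint_min, res$offset_kb), ]
}

#' Pairwise replicate correlation of per-gene mean intron signal
#'
#' For all genes longer than \code{minLengthKb}, computes each sample's
#' mean intronic signal per gene and returns the Pearson correlation
#' matrix across samples — within-condition correlations should exceed
#' cross-condition ones.
#'
#' @param we a \linkS4class{WaveExperiment}.
#' @param minLengthKb minimum gene length, kb (default 10).
#' @return correlation matrix (samples x samples).
#' @export
replicateCorrelation <- function(we, minLengthKb = 10) {
  genes <- geneModels(we)
  keep <- geneIds(genes)[geneLengthsKb(genes) > minLengthKb]
  ss <- sampleSheet(we)
  m <- vapply(ss$label, function(l)
    vapply(keep, function(g) {
      s <- intronSignal(we, l, g)
      if (nBins(s)) mean(signalValues(s)) else NA_real_
    }, numeric(1)), numeric(length(keep)))
  stats::cor(m, use = "pairwise.complete.obs")
}

#' Write pipeline outputs as TSV tables
#'
#' boundaries.tsv, rates.tsv, initiation.tsv, metagene.tsv and audit.tsv;
#' deterministic byte-for-byte given identical results.
#'
#' @param res result list from \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writePipelineOutputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("boundaries", "rates", "initiation", "metagene", "audit")) {
    tab <- res[[nm]]
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, 10))
    write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
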