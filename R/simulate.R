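#' Draw per-gene generative parameters for a simulated cohort
#'
#' Default parameter distributions emulate the study conditions: elongation
#' rates uniform on 2-6 kb/min (the published range), delay times uniform
#' on 0-2 min, gene lengths uniform on 30-65 kb (human genes passing the
#' 25-kb filter), initiation frequencies uniform on 5-20 signal units/min
#' (moderately expressed genes, wave signal about an order of magnitude
#' above background), and a leaky-inhibition background with mean 1 per
#' bin, negative-binomially over-dispersed (variance mu + mu^2/k, k = 10).
#' Simulated steady-state expression is proportional to the initiation
#' frequency (with mild lognormal scatter).
#'
#' @param nGenes number of genes.
#' @param vRange,dRange,iRange,lengthRangeKb uniform parameter ranges.
#' @param bgMean expected background per bin.
#' @param bgDispersion NB dispersion k; \code{Inf} means noiseless
#'   (deterministic means).
#' @param exonLeak mature-mRNA contamination multiplier on exon bins.
#' @return data.frame of per-gene parameters (the truth table skeleton).
#' @export
simGeneParams <- function(nGenes, vRange = c(2, 6), dRange = c(0, 2),
                          iRange = c(5, 20), lengthRangeKb = c(30, 65),
                          bgMean = 1, bgDispersion = 10, exonLeak = 3) {
  stopifnot(nGenes >= 1)
  data.frame(
    gene_id = sprintf("SIMG%04d", seq_len(nGenes)),
    length_kb = round(stats::runif(nGenes, lengthRangeKb[1],
                                   lengthRangeKb[2]), 1),
    I_true = stats::runif(nGenes, iRange[1], iRange[2]),
    V_true = stats::runif(nGenes, vRange[1], vRange[2]),
    D_true = stats::runif(nGenes, dRange[1], dRange[2]),
    bg_mean = bgMean,
    bg_dispersion = bgDispersion,
    exon_leak = exonLeak,
    expression = NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate one gene's intron signal at one timepoint
#'
#' Per 100-bp bin at offset x kb from the TSS the expected nascent signal
#' is \code{mu(x) = bg_mean + I * max(0, t - D - x/V)}: the triangular
#' transcription wave truncated at the front V*(t - D), on top of the
#' leaky-inhibition background. Realized values are drawn from a negative
#' binomial with mean mu and dispersion k (variance mu + mu^2/k); with
#' \code{bg_dispersion = Inf} the expected values are returned exactly.
#' 0-min samples contain background only (for D >= 0).
#'
#' @param params one row of \code{\link{simGeneParams}} (or a list with the
#'   same fields).
#' @param offsetsKb intron-bin offsets of the gene, kb.
#' @param timepointMin 0, 4 or 8.
#' @param seed optional integer seed for this draw.
#' @return an \linkS4class{IntronSignal}.
#' @export
simulateGene <- function(params, offsetsKb, timepointMin, seed = NULL) {
  stopifnot(timepointMin %in% c(0, 4, 8))
  if (!is.null(seed)) set.seed(seed)
  mu <- params$bg_mean +
    params$I_true * pmax(0, timepointMin - params$D_true -
                            offsetsKb / params$V_true)
  vals <- if (is.infinite(params$bg_dispersion)) mu
          else as.numeric(stats::rnbinom(length(mu), mu = mu,
                                         size = params$bg_dispersion))
  new("IntronSignal", geneId = params$gene_id, offsetsKb = offsetsKb,
      values = vals)
}

#' Build synthetic gene models for a simulated cohort
#'
#' Genes are laid head to tail on one synthetic chromosome with 10-kb
#' gaps, on alternating strands, starts aligned to the 100-bp grid.
#' Each gene gets a 200-bp exon at its 5' end and further 200-bp exons
#' every ~3 kb (spacing jittered between 2.4 and 3.6 kb), giving an
#' intron fraction around 0.93.
#'
#' @param truth data.frame from \code{\link{simGeneParams}}.
#' @param chrom synthetic chromosome name.
#' @return a \linkS4class{GeneModels}.
#' @export
simGeneModels <- function(truth, chrom = "chrSim") {
  n <- nrow(truth)
  lenBp <- as.integer(round(truth$length_kb * 1000 / 100) * 100)
  starts0 <- cumsum(c(10000L, head(lenBp, -1) + 10000L))  # 0-based
  strands <- rep(c("+", "-"), length.out = n)
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts0 + 1L,
                              end = starts0 + lenBp),
    strand = strands)
  names(genes) <- truth$gene_id
  exons <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i) {
    # exon starts in transcript coordinates (0-based, from the 5' end)
    pos <- 0L
    txStarts <- integer(0)
    while (pos + 200L <= lenBp[i]) {
      txStarts <- c(txStarts, pos)
      pos <- pos + 200L +
        as.integer(round(stats::runif(1, 2400, 3600) / 100) * 100) - 200L
    }
    if (strands[i] == "+") {
      es <- starts0[i] + txStarts
    } else {
      es <- sort(starts0[i] + lenBp[i] - txStarts - 200L)
    }
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = es + 1L, end = es + 200L),
      strand = strands[i])
  }))
  names(exons) <- truth$gene_id
  new("GeneModels", genes = genes, exons = exons)
}

#' Simulate a full multi-sample cohort
#'
#' Generates per-gene parameters, synthetic gene models, and the replicate
#' design of the study (four 0-min, two 4-min and four 8-min biological
#' repeats by default), drawing every sample's intron signal from the
#' generative wave model. Fully reproducible from \code{seed}. The truth
#' table carries the generative parameters plus the derived front
#' positions front(t) = V*(t - D) clipped to the gene length.
#'
#' @param nGenes number of genes.
#' @param seed integer seed.
#' @param design named vector c(n0 =, n4 =, n8 =) of replicate counts.
#' @param noiseless if TRUE expected values are emitted exactly (and the
#'   background is still present at its mean level).
#' @param ... passed to \code{\link{simGeneParams}}.
#' @return a \linkS4class{WaveExperiment} with the truth table attached.
#' @export
simulateCohort <- function(nGenes = 200L, seed = 1L,
                           design = c(n0 = 4L, n4 = 2L, n8 = 4L),
                           noiseless = FALSE, ...) {
  set.seed(seed)
  truth <- simGeneParams(nGenes, ...)
  if (noiseless) truth$bg_dispersion <- Inf
  truth$expression <- truth$I_true * exp(stats::rnorm(nGenes, 0, 0.2))
  genes <- simGeneModels(truth)
  truth$front4_kb <- pmin(pmax(truth$V_true * (4 - truth$D_true), 0),
                          truth$length_kb)
  truth$front8_kb <- pmin(pmax(truth$V_true * (8 - truth$D_true), 0),
                          truth$length_kb)
  ss <- data.frame(
    label = c(sprintf("t0_r%d", seq_len(design[["n0"]])),
              sprintf("t4_r%d", seq_len(design[["n4"]])),
              sprintf("t8_r%d", seq_len(design[["n8"]]))),
    timepoint_min = c(rep(0, design[["n0"]]), rep(4, design[["n4"]]),
                      rep(8, design[["n8"]])),
    replicate = c(seq_len(design[["n0"]]), seq_len(design[["n4"]]),
                  seq_len(design[["n8"]])),
    stringsAsFactors = FALSE)
  offs <- lapply(truth$gene_id, function(g) intronBins(genes, g)$offsetKb)
  names(offs) <- truth$gene_id
  signals <- lapply(seq_len(nrow(ss)), function(j) {
    sigs <- lapply(seq_len(nGenes), function(i)
      simulateGene(truth[i, ], offs[[i]], ss$timepoint_min[j]))
    names(sigs) <- truth$gene_id
    sigs
  })
  names(signals) <- ss$label
  new("WaveExperiment", genes = genes, signals = signals,
      sampleSheet = ss, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits a BED12 annotation, a headered sample sheet TSV, the truth table
#' TSV, per-sample intron-signal TSVs (gene_id, offset_kb, value) and
#' per-sample bedGraph tracks over the genomic bins (intron bins carry the
#' simulated signal; exon bins carry \code{exon_leak * I * T} mature-mRNA
#' contamination so the genome I/O path can be exercised end to end).
#' Output is deterministic given the experiment.
#'
#' @param we a simulated \linkS4class{WaveExperiment}.
#' @param dir output directory (created if needed).
#' @param bedGraph also write bedGraph tracks (default TRUE).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(we, dir, bedGraph = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- geneModels(we)
  truth <- truthTable(we)
  ss <- sampleSheet(we)
  # BED12
  g <- genes@genes
  bed <- vapply(seq_along(g), function(i) {
    ex <- genes@exons[[i]]
    s0 <- GenomicRanges::start(g)[i] - 1L
    sizes <- paste0(GenomicRanges::width(ex), collapse = ",")
    rel <- paste0(GenomicRanges::start(ex) - 1L - s0, collapse = ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s,\t%s,",
            as.character(GenomicRanges::seqnames(g))[i], s0,
            GenomicRanges::end(g)[i], names(g)[i],
            as.character(GenomicRanges::strand(g))[i], s0,
            GenomicRanges::end(g)[i], length(ex), sizes, rel)
  }, character(1))
  writeLines(bed, file.path(dir, "genes.bed"))
  ss$path <- sprintf("%s.signal.tsv", ss$label)
  write.table(ss[, c("path", "label", "timepoint_min", "replicate")],
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (j in seq_len(nrow(ss))) {
    lab <- ss$label[j]
    tab <- do.call(rbind, lapply(geneIds(genes), function(gid) {
      s <- intronSignal(we, lab, gid)
      if (!nBins(s)) return(NULL)
      data.frame(gene_id = gid, offset_kb = offsetsKb(s),
                 value = signalValues(s), stringsAsFactors = FALSE)
    }))
    write.table(tab, file.path(dir, sprintf("%s.signal.tsv", lab)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (bedGraph) {
      lines <- character(0)
      for (gid in geneIds(genes)) {
        s <- intronSignal(we, lab, gid)
        ib <- intronBins(genes, gid)
        tr <- truth[truth$gene_id == gid, ]
        if (nBins(s)) {
          nz <- which(signalValues(s) != 0)
          lines <- c(lines, sprintf("chrSim\t%d\t%d\t%s", ib$binStart[nz],
                                    ib$binStart[nz] + 100L,
                                    formatC(signalValues(s)[nz],
                                            digits = 10, format = "g")))
        }
        ex <- genes@exons[[which(geneIds(genes) == gid)]]
        leak <- tr$exon_leak * tr$I_true * 8
        es0 <- GenomicRanges::start(ex) - 1L
        lines <- c(lines, sprintf("chrSim\t%d\t%d\t%s", es0,
                                  GenomicRanges::end(ex),
                                  formatC(leak, digits = 10, format = "g")))
      }
      o <- order(as.integer(sub("^chrSim\t(\\d+)\t.*$", "\\1", lines)))
      writeLines(lines[o], file.path(dir, sprintf("%s.bedgraph", lab)))
    }
  }
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' Rebuilds a \linkS4class{WaveExperiment} from the sample sheet, BED12
#' annotation, per-sample signal TSVs and (if present) the truth table.
#'
#' @param dir directory produced by \code{\link{writeCohort}}.
#' @return a \linkS4class{WaveExperiment}.
#' @export
readWaveExperiment <- function(dir) {
  ss <- read.table(file.path(dir, "samples.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  genes <- readGeneModels(file.path(dir, "genes.bed"), format = "bed12")
  truth <- if (file.exists(file.path(dir, "truth.tsv")))
    read.table(file.path(dir, "truth.tsv"), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE)
  else data.frame()
  signals <- lapply(seq_len(nrow(ss)), function(j) {
    tab <- read.table(file.path(dir, ss$path[j]), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    sigs <- lapply(geneIds(genes), function(gid) {
      t <- tab[tab$gene_id == gid, , drop = FALSE]
      new("IntronSignal", geneId = gid, offsetsKb = t$offset_kb,
          values = t$value)
    })
    names(sigs) <- geneIds(genes)
    sigs
  })
  names(signals) <- ss$label
  new("WaveExperiment", genes = genes, signals = signals,
      sampleSheet = ss[, c("label", "timepoint_min", "replicate")],
      truth = truth)
}
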