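# Shared fixture builders: analytic waves, tiny annotations, SAM fixtures.

# analytic intron-only wave parameters as used by simulateGene
analyticParams <- function(I = 2, V = 3, D = 1, bg = 0, disp = Inf,
                           id = "G1") {
  list(gene_id = id, I_true = I, V_true = V, D_true = D, bg_mean = bg,
       bg_dispersion = disp)
}

# dense intron-only offset grid in kb (bins every 0.1 kb)
denseOffsets <- function(lengthKb = 40) seq(0, lengthKb - 0.1, by = 0.1)

# a ZeroProfile built from four noiseless background-only replicates
noiselessZero <- function(offsets, bg = 0, params = waveParams(), id = "G1") {
  zs <- lapply(1:4, function(r)
    simulateGene(analyticParams(bg = bg, id = id), offsets, 0))
  suppressWarnings(averageZeroProfile(zs, params))
}

# write a refFlat file; exons given as 0-based half-open intervals
writeRefFlat <- function(path, genes) {
  lines <- vapply(genes, function(g) {
    paste(g$gene, g$tx, g$chrom, g$strand, g$txStart, g$txEnd,
          g$txStart, g$txEnd, length(g$exonStarts),
          paste0(paste(g$exonStarts, collapse = ","), ","),
          paste0(paste(g$exonEnds, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# a minimal single-end SAM file; reads as list(chrom, pos1, len, flag)
writeSam <- function(path, reads,
                     contigs = c(chr1 = 100000L,
                                 chrUn_gl000220 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  ord <- order(match(vapply(reads, `[[`, "", "chrom"), names(contigs)),
               vapply(reads, function(r) r$pos1, numeric(1)))
  body <- vapply(seq_along(ord), function(k) {
    r <- reads[[ord[k]]]
    flag <- if (is.null(r$flag)) 0L else r$flag
    mapq <- if (is.null(r$mapq)) 42L else r$mapq
    sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
            k, flag, r$chrom, r$pos1, mapq, r$len,
            strrep("A", r$len), strrep("I", r$len))
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# brute-force modified Thompson tau oracle (single pass, one removal max)
tauOracle <- function(v, alpha = 0.05) {
  n <- length(v)
  if (n < 3) return(v)
  s <- sd(v)
  if (s == 0) return(v)
  d <- abs(v - mean(v))
  tcrit <- qt(1 - alpha / 2, n - 2)
  tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
  if (max(d) > tau * s) v[-which.max(d)] else v
}

# exhaustive strict-local-minima scan (plateaus collapsed, last index)
minimaOracle <- function(v, thr) {
  out <- integer(0)
  n <- length(v)
  for (i in 2:(n - 1)) {
    # previous distinct value
    j <- i - 1
    while (j >= 1 && v[j] == v[i]) j <- j - 1
    k <- i + 1
    if (v[k] == v[i]) next  # not the last index of a plateau
    if (j >= 1 && v[j] > v[i] && v[k] > v[i] && v[i] < thr)
      out <- c(out, i)
  }
  out
}
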