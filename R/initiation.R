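#' Linear fit of the 8-min wave decay of one replicate
#'
#' Under constant initiation frequency I and velocity V, the amount of
#' polymerase that has passed position x within T minutes of release is
#' I*(T - D - x/V): linear in x and zero at the wave front B = V*(T - D).
#' This fits the line a*x + b to the 8-min intron signal divided by the
#' averaged 0-min signal plus 1 (pseudocount preventing division by zero),
#' over bins from \code{excludeFirstKb} up to the replicate's refined
#' boundary B. At least 5 usable bins are required. Excluding the first
#' 2 kb guards against promoter-proximal pausing signal.
#'
#' @param sampleSignal the gene's raw \linkS4class{IntronSignal} in one
#'   8-min replicate.
#' @param zero the gene's \linkS4class{ZeroProfile} (its unsmoothed
#'   replicate mean is the denominator).
#' @param boundaryBKb the replicate's refined 8-min boundary, kb.
#' @param excludeFirstKb kb excluded immediately downstream of the TSS
#'   (0 by default; 2 in the pause-robustness variant).
#' @param pseudocount value added to the 0-min mean (default 1).
#' @return list(slope_a, intercept_b, n_bins) or NULL when fewer than 5
#'   bins are usable.
#' @export
fitInitiationSlope <- function(sampleSignal, zero, boundaryBKb,
                               excludeFirstKb = 0, pseudocount = 1) {
  off <- offsetsKb(sampleSignal)
  stopifnot(isTRUE(all.equal(off, zero@offsetsKb)))
  use <- off >= excludeFirstKb & off <= boundaryBKb
  if (sum(use) < 5L) return(NULL)
  y <- signalValues(sampleSignal)[use] / (zero@rawMean[use] + pseudocount)
  x <- off[use]
  fit <- lm(y ~ x)
  list(slope_a = unname(coef(fit)[2]), intercept_b = unname(coef(fit)[1]),
       n_bins = sum(use))
}

#' Relative initiation frequency from the decay intercept
#'
#' Since the fitted line satisfies a*B + b ~ 0 at the boundary B and the
#' model slope is -I/V, the intercept gives I = b*V/B (arbitrary units;
#' only gene-to-gene ratios are meaningful).
#'
#' @param interceptB fitted intercept b, signal units.
#' @param rateV elongation rate V, kb/min.
#' @param boundaryBKb boundary B, kb.
#' @return relative initiation frequency.
#' @export
relativeInitiation <- function(interceptB, rateV, boundaryBKb) {
  if (boundaryBKb <= 0 || rateV <= 0)
    stop("boundary and rate must be positive")
  interceptB * rateV / boundaryBKb
}

#' Aggregate per-replicate initiation estimates
#'
#' Applies the modified Thompson tau test (at most one removal) to the
#' replicate estimates and averages the survivors.
#'
#' @param perReplicateI numeric vector of per-replicate estimates (>= 2).
#' @param tauAlpha significance level of the outlier test.
#' @return list(relative_I, n_used) or NULL with fewer than 2 estimates.
#' @export
aggregateInitiation <- function(perReplicateI, tauAlpha = 0.05) {
  if (length(perReplicateI) < 2L) return(NULL)
  kept <- if (length(perReplicateI) >= 3L)
    thompsonTauFilter(perReplicateI, alpha = tauAlpha) else perReplicateI
  list(relative_I = mean(kept), n_used = length(kept))
}

#' Estimate relative initiation frequencies for an experiment
#'
#' For every gene with a QC-passing elongation rate, fits the 8-min decay
#' separately in each 8-min replicate (each against its own refined
#' boundary B, with the consensus rate V in I = b*V/B), rejects at most
#' one outlier replicate and averages.
#'
#' @param we a \linkS4class{WaveExperiment}.
#' @param zeroProfiles named list of \linkS4class{ZeroProfile} per gene.
#' @param boundaries boundary table from \code{\link{callBoundaries}}.
#' @param rates rate table from \code{\link{estimateRates}}.
#' @param params a \linkS4class{WaveParams}.
#' @param excludeFirstKb overrides \code{params@excludeFirstKb} when given.
#' @return data.frame: gene_id, relative_I, mean_slope_a, n_used, reason.
#' @export
estimateInitiation <- function(we, zeroProfiles, boundaries, rates,
                               params = waveParams(),
                               excludeFirstKb = params@excludeFirstKb) {
  ss <- sampleSheet(we)
  lab8 <- ss$label[ss$timepoint_min == 8]
  rep8 <- ss$replicate[ss$timepoint_min == 8]
  passing <- rates[rates$pass_qc, , drop = FALSE]
  rows <- lapply(seq_len(nrow(passing)), function(i) {
    g <- passing$gene_id[i]
    V <- passing$rate_kb_per_min[i]
    Is <- numeric(0); as <- numeric(0)
    for (j in seq_along(lab8)) {
      b <- boundaries[boundaries$gene_id == g &
                      boundaries$timepoint_min == 8 &
                      boundaries$replicate == rep8[j], , drop = FALSE]
      if (!nrow(b) || is.na(b$refined_kb[1])) next
      B <- b$refined_kb[1]
      if (B <= 0) next
      f <- fitInitiationSlope(intronSignal(we, lab8[j], g),
                              zeroProfiles[[g]], B,
                              excludeFirstKb = excludeFirstKb,
                              pseudocount = params@pseudocountInitiation)
      if (is.null(f)) next
      Is <- c(Is, relativeInitiation(f$intercept_b, V, B))
      as <- c(as, f$slope_a)
    }
    agg <- aggregateInitiation(Is, tauAlpha = params@tauAlpha)
    if (is.null(agg))
      return(data.frame(gene_id = g, relative_I = NA_real_,
                        mean_slope_a = NA_real_, n_used = length(Is),
                        reason = "insufficient-replicates",
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, relative_I = agg$relative_I,
               mean_slope_a = mean(as), n_used = agg$n_used,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene_id = character(0), relative_I = numeric(0),
                      mean_slope_a = numeric(0), n_used = integer(0),
                      reason = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Compare initiation estimates between two computation variants
#'
#' Pairs two initiation tables (e.g. the full fit and the fit excluding
#' the first 2 kb) over their shared genes and reports linear (Pearson)
#' and rank (Spearman) correlations plus the paired scatter data.
#'
#' @param full,variant data.frames with gene_id and relative_I columns.
#' @return list(pearson, spearman, n, data).
#' @export
robustnessCompare <- function(full, variant) {
  m <- merge(full[!is.na(full$relative_I), c("gene_id", "relative_I")],
             variant[!is.na(variant$relative_I), c("gene_id", "relative_I")],
             by = "gene_id", suffixes = c("_full", "_variant"))
  if (!nrow(m)) stop("no shared genes between the two tables")
  list(pearson = cor(m$relative_I_full, m$relative_I_variant),
       spearman = cor(m$relative_I_full, m$relative_I_variant,
                      method = "spearman"),
       n = nrow(m), data = m)
}
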