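#' Modified Thompson tau outlier rejection (at most one removal)
#'
#' The observation with maximal absolute deviation from the mean is removed
#' if that deviation exceeds tau * s, where s is the sample standard
#' deviation and tau the modified Thompson critical value
#' \code{t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))} with
#' \code{t = qt(1 - alpha/2, n - 2)}. At most one value is removed.
#'
#' @param values numeric vector; with fewer than 3 values it is returned
#'   unchanged with a warning.
#' @param alpha two-sided significance level, default 0.05.
#' @return the kept values (original order preserved).
#' @export
thompsonTauFilter <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) {
    warning("fewer than 3 values; no outlier test performed")
    return(values)
  }
  s <- sd(values)
  if (s == 0) return(values)
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
  if (dev[i] > tau * s) values[-i] else values
}

#' Fit an elongation rate from replicate boundary calls of one gene
#'
#' Requires a boundary in both 4-min replicates and in at least three of
#' the four 8-min replicates; the modified Thompson tau test (applied to
#' the 8-min boundary set only) may remove one outlier. The rate is the
#' slope of the ordinary least-squares fit of boundary position (kb)
#' against time (min) over all retained replicate points (the slope equals
#' the averaged-point slope when replicate counts are balanced, and the
#' replicate-level dispersion yields the confidence interval); the
#' reported CI is the half-width of the 50% two-sided confidence interval
#' of the slope (t distribution, df = n - 2). The delay time D is the
#' intersection of the fitted line with the time axis, -intercept/slope.
#'
#' @param calls data.frame of one gene's boundary calls with columns
#'   timepoint_min, refined_kb (NA where no boundary was determined).
#' @param minN4 required 4-min boundaries (default 2).
#' @param minN8 required 8-min boundaries (default 3).
#' @param tauAlpha significance level of the outlier test.
#' @return one-row data.frame: rate_kb_per_min, ci_half_width, delay_min,
#'   mean4_kb, mean8_kb, n_4min_used, n_8min_used, outlier_removed, reason
#'   (NA on success, otherwise why the gene was skipped).
#' @export
fitRate <- function(calls, minN4 = 2L, minN8 = 3L, tauAlpha = 0.05) {
  b4 <- calls$refined_kb[calls$timepoint_min == 4]
  b8 <- calls$refined_kb[calls$timepoint_min == 8]
  b4 <- b4[!is.na(b4)]
  b8 <- b8[!is.na(b8)]
  empty <- data.frame(rate_kb_per_min = NA_real_, ci_half_width = NA_real_,
                      delay_min = NA_real_, mean4_kb = NA_real_,
                      mean8_kb = NA_real_, n_4min_used = length(b4),
                      n_8min_used = length(b8), outlier_removed = FALSE,
                      reason = NA_character_, stringsAsFactors = FALSE)
  if (length(b4) < minN4 || length(b8) < minN8) {
    empty$reason <- "insufficient-replicates"
    return(empty)
  }
  b8kept <- if (length(b8) >= 3L)
    suppressWarnings(thompsonTauFilter(b8, alpha = tauAlpha)) else b8
  removed <- length(b8kept) < length(b8)
  if (length(b8kept) < minN8) {
    empty$reason <- "insufficient-replicates"
    empty$outlier_removed <- removed
    return(empty)
  }
  tt <- c(rep(4, length(b4)), rep(8, length(b8kept)))
  pos <- c(b4, b8kept)
  fit <- lm(pos ~ tt)
  slope <- unname(coef(fit)[2])
  icpt <- unname(coef(fit)[1])
  se <- summary(fit)$coefficients[2, 2]
  ci <- qt(0.75, df = length(pos) - 2) * se
  delay <- if (slope != 0) -icpt / slope else NA_real_
  data.frame(rate_kb_per_min = slope, ci_half_width = ci, delay_min = delay,
             mean4_kb = mean(b4), mean8_kb = mean(b8kept),
             n_4min_used = length(b4), n_8min_used = length(b8kept),
             outlier_removed = removed, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Apply the published QC rules to fitted rates
#'
#' A gene passes QC iff (i) the mean 8-min boundary is not lower than the
#' mean 4-min boundary, (ii) the 50% CI half-width of the slope is at most
#' \code{ciMax} kb/min, (iii) the delay time lies within
#' \code{delayRange} minutes, and (iv) the rate is positive. All genes are
#' retained in the table with a pass flag and failure reason.
#'
#' @param results data.frame as produced by \code{\link{estimateRates}}
#'   (columns of \code{\link{fitRate}} plus gene_id).
#' @param ciMax maximum CI half-width, kb/min (default 0.5).
#' @param delayRange admissible delay interval, min (default c(-1, 4)).
#' @return the table with pass_qc and reason columns filled.
#' @export
qcFilter <- function(results, ciMax = 0.5, delayRange = c(-1, 4)) {
  pass <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    if (!is.na(r$reason)) { pass[i] <- FALSE; next }
    if (r$mean8_kb < r$mean4_kb) {
      results$reason[i] <- "mean8-below-mean4"
    } else if (is.na(r$rate_kb_per_min) || r$rate_kb_per_min <= 0) {
      results$reason[i] <- "nonpositive-rate"
    } else if (r$ci_half_width > ciMax) {
      results$reason[i] <- "ci-above-max"
    } else if (r$delay_min < delayRange[1] || r$delay_min > delayRange[2]) {
      results$reason[i] <- "delay-out-of-range"
    } else {
      pass[i] <- TRUE
    }
  }
  results$pass_qc <- pass
  results
}

#' Estimate elongation rates for all genes of a boundary table
#'
#' Groups the boundary table by gene, fits each gene with
#' \code{\link{fitRate}} and applies \code{\link{qcFilter}}.
#'
#' @param boundaries data.frame from \code{\link{callBoundaries}}.
#' @param params a \linkS4class{WaveParams}.
#' @return data.frame with one row per gene: gene_id, rate_kb_per_min,
#'   ci_half_width, delay_min, mean4_kb, mean8_kb, n_4min_used,
#'   n_8min_used, outlier_removed, reason, pass_qc.
#' @export
estimateRates <- function(boundaries, params = waveParams()) {
  genes <- unique(boundaries$gene_id)
  rows <- lapply(genes, function(g) {
    r <- fitRate(boundaries[boundaries$gene_id == g, , drop = FALSE],
                 tauAlpha = params@tauAlpha)
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE), r)
  })
  qcFilter(do.call(rbind, rows), ciMax = params@ciMaxKbPerMin,
           delayRange = params@delayRange)
}
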