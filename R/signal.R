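#' Cubic smoothing spline under the classic p-parameterization
#'
#' Natural cubic smoothing spline evaluated at the input abscissae,
#' minimizing \code{p * sum((y - f)^2) + (1 - p) * integral(f''(t)^2 dt)}
#' (the parameterization in which the default smoothing parameter of this
#' pipeline, 1e-5, is stated). \code{p -> 1} interpolates; \code{p -> 0}
#' tends to the least-squares line. Solved by the Reinsch algorithm via a
#' banded sparse system; constants and straight lines are reproduced
#' exactly for any \code{p}, and the operator is linear in \code{y}.
#'
#' Note that other spline conventions (e.g. \code{stats::smooth.spline})
#' rescale the parameter; within the pipeline the abscissa is the genomic
#' offset of each intron bin in bp, under which p = 1e-5 at 100-bp spacing
#' denoises gently while preserving the wave front within one bin.
#'
#' @param values numeric vector, length >= 4, finite.
#' @param x abscissae (strictly increasing); defaults to the bin index.
#' @param p smoothing parameter in [0, 1].
#' @return the smoothed vector, same length.
#' @export
smoothSignal <- function(values, x = seq_along(values), p = 1e-5) {
  n <- length(values)
  if (n < 4L) stop("too short to smooth (need >= 4 points)")
  if (!all(is.finite(values))) stop("values must be finite")
  stopifnot(length(x) == n, !is.unsorted(x, strictly = TRUE),
            p >= 0, p <= 1)
  if (p == 1) return(values)
  h <- diff(x)
  alpha <- (1 - p) / p
  m <- n - 2L
  i <- c(seq_len(m), seq_len(m) + 1L, seq_len(m) + 2L)
  j <- rep(seq_len(m), 3L)
  v <- c(1 / h[seq_len(m)], -1 / h[seq_len(m)] - 1 / h[seq_len(m) + 1L],
         1 / h[seq_len(m) + 1L])
  Q <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, m))
  dg <- (h[seq_len(m)] + h[seq_len(m) + 1L]) / 3
  od <- if (m > 1L) h[seq_len(m) + 1L][-m] / 6 else numeric(0)
  R <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L),
                          diagonals = list(od, dg, od))
  gam <- Matrix::solve(R + alpha * Matrix::crossprod(Q),
                       Matrix::crossprod(Q, values))
  as.numeric(values - alpha * (Q %*% gam))
}

#' Most abundant value (histogram mode)
#'
#' Estimates the center of the background distribution as the most abundant
#' value: a histogram with \code{ceiling(sqrt(n))} equal-width bins over
#' [min, max] is built and the center of the highest-count bin returned,
#' ties broken toward the lower bin.
#'
#' @param values numeric vector, length >= 1.
#' @return scalar mode estimate.
#' @export
modeEstimate <- function(values) {
  n <- length(values)
  stopifnot(n >= 1L)
  mn <- min(values); mx <- max(values)
  if (mn == mx) return(mn)
  nb <- ceiling(sqrt(n))
  w <- (mx - mn) / nb
  idx <- pmin(floor((values - mn) / w), nb - 1)
  counts <- tabulate(idx + 1L, nbins = nb)
  b <- which.max(counts)  # which.max takes the first (lower) tie
  mn + (b - 0.5) * w
}

#' Per-bin downstream background track
#'
#' For every bin i the background level is the histogram mode of all values
#' strictly downstream of i (toward the gene 3' end). Bins with fewer than
#' \code{minWindow} downstream values inherit the estimate of the nearest
#' upstream bin that had one; genes too short to hold any window get a
#' constant track (the mode of the whole vector).
#'
#' @param values numeric vector (typically the smoothed intron signal).
#' @param minWindow minimum number of downstream values, default 10.
#' @return numeric background track, same length as \code{values}.
#' @export
backgroundTrack <- function(values, minWindow = 10L) {
  n <- length(values)
  stopifnot(n >= 1L)
  est <- rep(NA_real_, n)
  last <- NA_real_
  for (i in seq_len(n)) {
    m <- n - i
    if (m >= minWindow) {
      last <- modeEstimate(values[(i + 1L):n])
    }
    est[i] <- last
  }
  if (anyNA(est)) {
    fill <- modeEstimate(values)
    est[is.na(est)] <- fill
  }
  est
}

#' Background-correct a signal
#'
#' Element-wise subtraction of the background track, floored at zero.
#'
#' @param values signal vector.
#' @param bg background track of equal length.
#' @return corrected vector, all values >= 0.
#' @export
backgroundCorrect <- function(values, bg) {
  if (length(values) != length(bg))
    stop("signal and background track lengths differ")
  pmax(values - bg, 0)
}

#' Derivative of the sample/reference profile ratio
#'
#' Divides the (smoothed, background-corrected) post-release profile by the
#' smoothed pseudocounted 0-min profile and differences adjacent bins:
#' \code{d[i] = r[i+1] - r[i]} with \code{r = sample / zero}. The 0-min
#' vector must be strictly positive (guaranteed upstream by the 0.01
#' pseudocount added before smoothing).
#'
#' @param sampleSmoothed smoothed post-release profile.
#' @param zeroSmoothed smoothed pseudocounted 0-min profile, all > 0.
#' @return derivative vector of length \code{n - 1}.
#' @export
ratioDerivative <- function(sampleSmoothed, zeroSmoothed) {
  if (length(sampleSmoothed) != length(zeroSmoothed))
    stop("profile lengths differ")
  if (any(zeroSmoothed <= 0))
    stop("0-min profile must be strictly positive (pseudocount contract)")
  diff(sampleSmoothed / zeroSmoothed)
}

#' Local minima below a depth threshold
#'
#' Finds indices that are local minima of \code{values} and lie below
#' \code{depthThreshold}. A plateau (run of equal values) flanked on both
#' sides by larger values counts as one minimum, reported at its most
#' downstream (last) index; endpoints are never minima. An optional
#' prominence filter (height of the lower surrounding maximum above the
#' minimum) is exposed; at \code{prominence = 0} the detector reduces to a
#' pure sign-change scan.
#'
#' @param values numeric vector, finite.
#' @param depthThreshold only minima with value strictly below this
#'   threshold are returned (default -0.01).
#' @param prominence minimum prominence, default 0.
#' @return integer indices (possibly empty), increasing.
#' @export
localMinima <- function(values, depthThreshold = -0.01, prominence = 0) {
  n <- length(values)
  if (!all(is.finite(values))) stop("values must be finite")
  if (n < 3L) return(integer(0))
  # collapse plateaus: runs of equal consecutive values
  r <- rle(values)
  ends <- cumsum(r$lengths)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  isMin <- r$values[mid] < r$values[mid - 1L] & r$values[mid] < r$values[mid + 1L]
  cand <- ends[mid][isMin]
  cand <- cand[values[cand] < depthThreshold]
  if (prominence > 0 && length(cand)) {
    keep <- vapply(cand, function(i) {
      lmax <- max(values[1:i])
      rmax <- max(values[i:n])
      min(lmax, rmax) - values[i] >= prominence
    }, logical(1))
    cand <- cand[keep]
  }
  as.integer(cand)
}
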