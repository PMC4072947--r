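test_that("zero-profile averaging is the element-wise replicate mean", {
  off <- denseOffsets(10)
  mk <- function(vals) new("IntronSignal", geneId = "G",
                           offsetsKb = off, values = vals)
  a <- mk(rep(c(0, 2), length.out = length(off)))
  b <- mk(rep(c(2, 0), length.out = length(off)))
  zp <- averageZeroProfile(list(a, b))
  expect_equal(zp@rawMean, rep(1, length(off)))
  # four identical replicates average to each of them
  zp4 <- averageZeroProfile(rep(list(a), 4))
  expect_equal(zp4@rawMean, signalValues(a))
  expect_warning(averageZeroProfile(list(a)), "single 0-min replicate")
  bad <- new("IntronSignal", geneId = "G", offsetsKb = off + 0.1,
             values = signalValues(a))
  expect_error(averageZeroProfile(list(a, bad)), "mismatched")
})

test_that("rough boundary applies the 2.5-kb start and first-position rules", {
  off <- seq(0, 9.9, by = 0.1)
  zero <- rep(1, 100)
  # sample identical to zero: the very first eligible bin matches
  expect_equal(roughBoundary(zero, zero, off)$status, "first-position")
  # sample always above tolerance: no boundary
  expect_equal(roughBoundary(zero * 1.2, zero, off)$status, "no-boundary")
  # wave on top of zero ending at 6 kb: first bin past the wave
  sample <- zero + pmax(0, 6 - off) * 2
  rb <- roughBoundary(sample, zero, off)
  expect_equal(rb$status, "ok")
  expect_equal(off[rb$index], 6.0)
  # tolerance: 10% above zero still matches
  expect_equal(roughBoundary(zero * 1.05, zero, off)$status, "first-position")
})

test_that("refinement finds the plateau after the most downstream minimum", {
  off <- seq(0, 9.9, by = 0.1)
  # flat derivative upstream: no qualifying minimum, keep the rough estimate
  d <- rep(0, 99)
  expect_equal(refineBoundary(d, 50L, off)$index, 50L)
  expect_false(refineBoundary(d, 50L, off)$refined)
  # one clear minimum then a plateau near zero
  d <- rep(0, 99); d[30] <- -0.05; d[31:40] <- -0.01; d[41:99] <- -0.001
  r <- refineBoundary(d, 45L, off)
  expect_true(r$refined)
  expect_equal(r$index, 41L)
  # two minima: the search starts from the most downstream one
  d <- rep(0, 99); d[20] <- -0.05; d[35] <- -0.03; d[36:99] <- 0
  expect_equal(refineBoundary(d, 45L, off)$index, 36L)
  # the 2-kb cap: a plateau only beyond rough+2 kb falls back
  d <- rep(-0.05, 99); d[30] <- -0.06
  expect_false(refineBoundary(d, 40L, off)$refined)
})

test_that("noiseless wave fronts are recovered within 0.2 kb", {
  off <- denseOffsets(40)
  zp <- noiselessZero(off, bg = 1)
  s8 <- simulateGene(analyticParams(I = 2, V = 3, D = 1, bg = 1), off, 8)
  cb <- callBoundary(s8, zp)
  expect_true(cb$status %in% c("ok", "refine-fallback"))
  expect_lt(abs(cb$refined_kb - 21), 0.2 + 1e-9)
  # a 0-min replicate run against itself gives no boundary (first position)
  s0 <- simulateGene(analyticParams(bg = 1), off, 0)
  expect_equal(callBoundary(s0, zp)$status, "first-position")
  # wave front beyond the gene end: background correction flattens the
  # truncated tail, so any call lands in the downstream quarter of the
  # gene, far past every in-gene front (QC catches such genes later)
  sLong <- simulateGene(analyticParams(I = 2, V = 6, D = 0, bg = 1), off, 8)
  cbLong <- callBoundary(sLong, zp)
  if (!is.na(cbLong$refined_kb)) expect_gt(cbLong$refined_kb, 30)
})

test_that("boundaries advance by 4*V between 4 and 8 min (noiseless)", {
  off <- denseOffsets(50)
  zp <- noiselessZero(off, bg = 1)
  for (V in c(2.5, 4)) {
    p <- analyticParams(I = 3, V = V, D = 1, bg = 1)
    b4 <- callBoundary(simulateGene(p, off, 4), zp)$refined_kb
    b8 <- callBoundary(simulateGene(p, off, 8), zp)$refined_kb
    expect_lt(abs((b8 - b4) - 4 * V), 0.1 + 1e-9)
  }
})

test_that("adding a constant to sample and zero leaves the rough call fixed", {
  off <- denseOffsets(40)
  set.seed(31)
  base <- 2 * pmax(0, 7 - off / 3) + rnbinom(length(off), mu = 2, size = 10)
  zero <- rnbinom(length(off), mu = 2, size = 10)
  call1 <- {
    sC <- backgroundCorrect(smoothSignal(base, off * 1000),
                            backgroundTrack(smoothSignal(base, off * 1000)))
    zC <- backgroundCorrect(smoothSignal(zero, off * 1000),
                            backgroundTrack(smoothSignal(zero, off * 1000)))
    roughBoundary(sC, zC, off)
  }
  call2 <- {
    sC <- backgroundCorrect(smoothSignal(base + 5, off * 1000),
                            backgroundTrack(smoothSignal(base + 5, off * 1000)))
    zC <- backgroundCorrect(smoothSignal(zero + 5, off * 1000),
                            backgroundTrack(smoothSignal(zero + 5, off * 1000)))
    roughBoundary(sC, zC, off)
  }
  expect_equal(call1$index, call2$index)
  expect_equal(call1$status, call2$status)
})

test_that("refinement never moves the call more than 2 kb downstream", {
  we <- simulateCohort(nGenes = 8, seed = 17)
  res <- runPipeline(we)
  b <- res$boundaries
  ok <- !is.na(b$refined_kb)
  expect_true(all(b$refined_kb[ok] <= b$rough_kb[ok] + 2 + 1e-9))
  expect_true(all(b$rough_kb[ok] >= 2.5))
})
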