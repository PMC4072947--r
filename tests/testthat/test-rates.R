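test_that("Thompson tau removes a single gross outlier and nothing else", {
  expect_equal(thompsonTauFilter(c(10, 10.2, 9.8, 20)), c(10, 10.2, 9.8))
  v <- c(10, 10.2, 9.8, 10.4)
  expect_equal(thompsonTauFilter(v), v)
  expect_equal(thompsonTauFilter(rep(5, 6)), rep(5, 6))
  expect_warning(out <- thompsonTauFilter(c(1, 100)), "fewer than 3")
  expect_equal(out, c(1, 100))
})

test_that("Thompson tau agrees with the brute-force oracle", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(3:8, 1)
    v <- rnorm(n, 10, 1)
    if (k %% 3 == 0) v[1] <- v[1] + sample(c(-1, 1), 1) * runif(1, 3, 15)
    expect_equal(thompsonTauFilter(v), tauOracle(v))
  }
})

test_that("rate fits recover exact closed forms", {
  # two perfect timepoint clusters on the line pos = 3.5 t
  calls <- data.frame(timepoint_min = c(4, 4, 8, 8, 8),
                      refined_kb = c(14, 14, 28, 28, 28))
  r <- fitRate(calls)
  expect_equal(r$rate_kb_per_min, 3.5)
  expect_equal(r$ci_half_width, 0)
  expect_equal(r$delay_min, 0)
  expect_equal(r$mean4_kb, 14)
  expect_equal(r$mean8_kb, 28)
  expect_false(r$outlier_removed)
  expect_true(is.na(r$reason))
  # nonzero delay: pos = 3.5 (t - 0.5714...)
  calls2 <- data.frame(timepoint_min = c(4, 4, 8, 8, 8),
                       refined_kb = c(12, 12, 26, 26, 26))
  r2 <- fitRate(calls2)
  expect_equal(r2$rate_kb_per_min, 3.5)
  expect_equal(r2$delay_min, 2 / 3.5)
})

test_that("the slope equals the averaged-point slope for balanced designs", {
  # With equal counts per timepoint the OLS slope is
  # (mean8 - mean4) / 4 regardless of within-timepoint spread.
  set.seed(55)
  b4 <- rnorm(3, 12, 1); b8 <- rnorm(3, 26, 1)
  calls <- data.frame(timepoint_min = rep(c(4, 8), each = 3),
                      refined_kb = c(b4, b8))
  r <- fitRate(calls, minN4 = 2L, minN8 = 3L)
  expect_equal(r$rate_kb_per_min, (mean(b8) - mean(b4)) / 4)
})

test_that("replicate requirements and the 8-min outlier test are enforced", {
  # a missing 4-min boundary blocks the fit
  calls <- data.frame(timepoint_min = c(4, 4, 8, 8, 8, 8),
                      refined_kb = c(14, NA, 28, 28.2, 27.8, 28.1))
  expect_equal(fitRate(calls)$reason, "insufficient-replicates")
  # only two non-NA 8-min boundaries also block it
  calls2 <- data.frame(timepoint_min = c(4, 4, 8, 8, 8, 8),
                       refined_kb = c(14, 14, 28, 28, NA, NA))
  expect_equal(fitRate(calls2)$reason, "insufficient-replicates")
  # one wild 8-min replicate is removed; three survivors keep the gene
  calls3 <- data.frame(timepoint_min = c(4, 4, 8, 8, 8, 8),
                       refined_kb = c(14, 14, 28, 28.2, 27.8, 45))
  r3 <- fitRate(calls3)
  expect_true(r3$outlier_removed)
  expect_equal(r3$n_8min_used, 3L)
  expect_true(is.na(r3$reason))
  expect_equal(r3$mean8_kb, mean(c(28, 28.2, 27.8)))
})

test_that("rate fits are equivariant under a common position rescaling", {
  set.seed(77)
  calls <- data.frame(timepoint_min = c(4, 4, 8, 8, 8, 8),
                      refined_kb = c(rnorm(2, 13, 0.3), rnorm(4, 27, 0.3)))
  scaled <- calls; scaled$refined_kb <- 2 * calls$refined_kb
  a <- fitRate(calls); b <- fitRate(scaled)
  expect_equal(b$rate_kb_per_min, 2 * a$rate_kb_per_min)
  expect_equal(b$ci_half_width, 2 * a$ci_half_width)
  expect_equal(b$delay_min, a$delay_min)  # delay is scale-free
})

test_that("QC rules flag each failure mode with its reason", {
  base <- data.frame(gene_id = "G", rate_kb_per_min = 3.5,
                     ci_half_width = 0.2, delay_min = 1, mean4_kb = 14,
                     mean8_kb = 28, n_4min_used = 2L, n_8min_used = 4L,
                     outlier_removed = FALSE, reason = NA_character_,
                     stringsAsFactors = FALSE)
  expect_true(qcFilter(base)$pass_qc)
  bad <- base; bad$mean8_kb <- 10
  expect_equal(qcFilter(bad)$reason, "mean8-below-mean4")
  bad <- base; bad$rate_kb_per_min <- -1
  expect_equal(qcFilter(bad)$reason, "nonpositive-rate")
  bad <- base; bad$ci_half_width <- 0.7
  expect_equal(qcFilter(bad)$reason, "ci-above-max")
  bad <- base; bad$delay_min <- 5
  expect_equal(qcFilter(bad)$reason, "delay-out-of-range")
  bad <- base; bad$delay_min <- -2
  expect_equal(qcFilter(bad)$reason, "delay-out-of-range")
  # boundary values of the admissible ranges still pass
  edge <- base; edge$ci_half_width <- 0.5; edge$delay_min <- 4
  expect_true(qcFilter(edge)$pass_qc)
  # genes skipped upstream keep their reason and never pass
  skip <- base; skip$reason <- "insufficient-replicates"
  expect_false(qcFilter(skip)$pass_qc)
  expect_equal(qcFilter(skip)$reason, "insufficient-replicates")
})

test_that("estimateRates keeps every gene in the output table", {
  calls <- rbind(
    data.frame(gene_id = "A", timepoint_min = c(4, 4, 8, 8, 8, 8),
               replicate = c(1:2, 1:4),
               refined_kb = c(13.9, 14.1, 27.8, 28.2, 28, 28),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "B", timepoint_min = c(4, 4, 8, 8, 8, 8),
               replicate = c(1:2, 1:4),
               refined_kb = c(NA, NA, 28, 28, 28, 28),
               stringsAsFactors = FALSE))
  res <- estimateRates(calls)
  expect_setequal(res$gene_id, c("A", "B"))
  expect_true(res$pass_qc[res$gene_id == "A"])
  expect_false(res$pass_qc[res$gene_id == "B"])
  expect_equal(res$reason[res$gene_id == "B"], "insufficient-replicates")
})
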