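test_that("exact Mann-Whitney agrees with rank-configuration enumeration", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    m <- sample(4:8, 1)
    vals <- sample(seq(0.01, 1, by = 0.01), n + m)  # tie-free
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    expect_equal(geneMannWhitney(x, y), mwBruteP(x, y), tolerance = 1e-12)
  }
})

test_that("worked extreme configuration gives p = 2/3003", {
  x <- c(2.0, 2.1, 1.9, 2.2, 2.05)
  y <- seq(0.05, 0.95, length.out = 10)  # all controls < 1
  expect_equal(geneMannWhitney(x, y), 2 / 3003, tolerance = 1e-12)
  expect_equal(mwBruteP(x, y), 2 / 3003, tolerance = 1e-12)
})

test_that("guides interleaved around the control median are non-significant", {
  # gene guides at overall ranks 3, 6, 8, 10, 13 of 15
  pool <- seq_len(15) / 10
  x <- pool[c(3, 6, 8, 10, 13)]
  y <- pool[-c(3, 6, 8, 10, 13)]
  expect_gt(geneMannWhitney(x, y), 0.5)
  expect_equal(geneMannWhitney(x, y), mwBruteP(x, y), tolerance = 1e-12)
})

test_that("large-sample path matches wilcox.test's corrected approximation", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(30:80, 1))
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(geneMannWhitney(x, y), ref, tolerance = 1e-12)
  }
  # ties engage the tie-corrected variance, still matching wilcox.test
  x <- c(1, 1, 2, 3, 3)
  y <- c(rep(1, 10), rep(2, 15), rep(3, 10))
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  expect_equal(geneMannWhitney(x, y), ref, tolerance = 1e-12)
})

test_that("too few usable guides yield the missing sentinel, never a p", {
  expect_true(is.na(geneMannWhitney(1.5, rnorm(30))))
  expect_error(geneMannWhitney(c(1, 2), numeric(0)), "empty")
})

test_that("gene score collapse averages the most extreme guides", {
  expect_equal(collapseGeneScore(c(1, 1, 1, 1, 1)), 1.0)
  expect_equal(collapseGeneScore(c(0.1, -0.2, 3.0, 2.5, 2.0)), 2.5)
  # magnitude, not sign, selects the guides
  expect_equal(collapseGeneScore(c(-3, -2.5, 0.1, 0.2, 2.0)),
               mean(c(-3, -2.5, 2.0)))
  # fewer than k guides: average what is there
  expect_equal(collapseGeneScore(c(-1, -3), k = 3), -2.0)
  expect_error(collapseGeneScore(numeric(0)), "no guide")
})

test_that("hit calling is strict at the threshold and sorts by evidence", {
  genes <- data.frame(
    gene = c("A", "B", "C", "D"),
    phenotype_score = c(-2, 1.5, -0.5, 0.4),
    p_value = c(0.004, 0.005, 0.20, NA))
  hits <- callHits(genes, alpha = 0.005)
  expect_equal(hits$is_hit[hits$gene == "A"], TRUE)
  expect_equal(hits$is_hit[hits$gene == "B"], FALSE)  # boundary: p == alpha
  expect_equal(hits$is_hit[hits$gene == "D"], FALSE)  # missing sentinel
  expect_equal(hits$gene[1], "A")
  expect_equal(hits$direction[hits$gene == "A"], "required")
  expect_equal(hits$direction[hits$gene == "B"], "repressor")
  empty <- callHits(genes[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("unity normalization and binning follow the published rule", {
  res <- unityNormalizeBin(c(a = -4, b = -3, c = -1))
  expect_equal(res$Z, c(0, 1 / 3, 1))
  expect_equal(res$bin, c(1L, 2L, 5L))
  # Z exactly on a boundary falls in the upper (half-open) bin
  res2 <- unityNormalizeBin(c(a = -11, b = -9, c = -1))
  expect_equal(res2$Z[2], 0.2)
  expect_equal(res2$bin[2], 2L)
  # positive-score override list forces bin 5
  res3 <- unityNormalizeBin(c(a = -4, b = -3, POLQ = 0.3, other = 0.2),
                            fa_positive_overrides = "POLQ")
  expect_equal(res3$bin[res3$gene == "POLQ"], 5L)
  expect_true(is.na(res3$Z[res3$gene == "POLQ"]))
  expect_true(is.na(res3$bin[res3$gene == "other"]))
  expect_error(unityNormalizeBin(c(a = -1, b = -1)), "distinct negative")
})

test_that("unity normalization preserves order with exact endpoints", {
  set.seed(3)
  s <- stats::setNames(-runif(40, 0.1, 5), paste0("g", 1:40))
  res <- unityNormalizeBin(s)
  expect_equal(order(res$Z), order(res$phenotype_score))
  expect_equal(min(res$Z), 0)
  expect_equal(max(res$Z), 1)
})

test_that("end-to-end gene scoring flags programmed effect genes", {
  lib <- makeGuideLibrary(60, 5, 60, seed = 21)
  pr <- ScreenSimParams(60, 5, 60, seed = 21,
                        effect_multipliers = c(GENE0001 = 4, GENE0002 = 4))
  se <- simulateScreenCounts(lib, pr)
  genes <- scoreGenes(guideEnrichment(se))
  top <- genes$gene[1:2]
  expect_setequal(top, c("GENE0001", "GENE0002"))
  expect_true(all(genes$is_hit[1:2]))
  expect_true(all(genes$phenotype_score[1:2] > 0))
  expect_true(all(genes$n_guides_used == 5L))
})
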