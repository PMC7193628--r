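test_that("generated guide libraries have the requested shape and are seeded", {
  lib <- makeGuideLibrary(20, 5, 8, seed = 1)
  expect_length(lib, 108L)
  expect_equal(sum(isControl(lib)), 8L)
  expect_equal(length(unique(guideGenes(lib)[!isControl(lib)])), 20L)
  expect_false(anyDuplicated(protospacers(lib)) > 0)
  expect_true(all(nchar(protospacers(lib)) == 20L))
  # determinism and seed sensitivity
  expect_identical(as.data.frame(makeGuideLibrary(20, 5, 8, seed = 1)),
                   as.data.frame(lib))
  expect_false(identical(as.data.frame(makeGuideLibrary(20, 5, 8, seed = 2)),
                         as.data.frame(lib)))
  # degenerate control-only library
  lib0 <- makeGuideLibrary(0, 5, 10, seed = 1)
  expect_length(lib0, 10L)
  expect_true(all(isControl(lib0)))
})

test_that("screen count simulation conserves depth and is deterministic", {
  lib <- makeGuideLibrary(50, 5, 25, seed = 3)
  pr <- ScreenSimParams(50, 5, 25, seed = 7)
  se <- simulateScreenCounts(lib, pr)
  counts <- SummarizedExperiment::assay(se, "counts")
  expect_equal(dim(counts), c(275L, 3L))
  # column sums equal depth x n_guides exactly, by multinomial construction
  expect_true(all(colSums(counts) == pr$reads_per_guide_depth * 275L))
  expect_true(all(counts >= 0))
  se2 <- simulateScreenCounts(lib, pr)
  expect_identical(SummarizedExperiment::assay(se2, "counts"), counts)
  # truth table is carried alongside the counts
  rd <- SummarizedExperiment::rowData(se)
  expect_true(all(c("p_g", "multiplier") %in% names(rd)))
  expect_true(all(rd$p_g[rd$is_control] == pr$base_hdr))
})

test_that("screen simulation rejects inconsistent parameters", {
  lib <- makeGuideLibrary(5, 5, 5, seed = 1)
  expect_error(ScreenSimParams(5, 5, 5, reads_per_guide_depth = 0),
               "positive")
  expect_error(ScreenSimParams(5, 5, 5, base_hdr = 0.05,
                               effect_multipliers = c(GENE0001 = 25)),
               "exceeds 1")
  pr <- ScreenSimParams(5, 5, 5,
                        effect_multipliers = c(NOSUCHGENE = 2))
  expect_error(simulateScreenCounts(lib, pr), "unknown gene")
})

test_that("all-null screens have near-zero mean gene enrichment", {
  lib <- makeGuideLibrary(200, 5, 100, seed = 11)
  pr <- ScreenSimParams(200, 5, 100, seed = 11)
  se <- simulateScreenCounts(lib, pr)
  gp <- guideEnrichment(se)
  genes <- scoreGenes(gp)
  # with every multiplier 1 the expected per-gene enrichment is 0
  expect_lt(abs(mean(genes$phenotype_score)), 0.05)
})

test_that("cassette reads reproduce their truth counts exactly", {
  lib <- makeGuideLibrary(10, 5, 5, seed = 2)
  counts <- stats::setNames(rep(c(3L, 2L, 0L), length.out = length(lib)),
                            guideIds(lib))
  tf <- withr::local_tempfile(fileext = ".fastq")
  simulateScreenReads(counts, lib, tf, seed = 5)
  reads <- readFastq(tf)
  expect_length(reads, sum(counts))
  rc <- countGuides(reads, lib)
  expect_identical(rc$counts, counts)
  expect_identical(rc$unassigned, 0L)
  # seeded shuffle: identical bytes across runs
  tf2 <- withr::local_tempfile(fileext = ".fastq")
  simulateScreenReads(counts, lib, tf2, seed = 5)
  expect_identical(readBin(tf, "raw", file.size(tf)),
                   readBin(tf2, "raw", file.size(tf2)))
  # empty counts give an empty FASTQ
  tf3 <- withr::local_tempfile(fileext = ".fastq")
  simulateScreenReads(stats::setNames(integer(0), character(0)), lib, tf3,
                      seed = 1)
  expect_equal(file.size(tf3), 0)
})

test_that("pure amplicon mixtures reconstruct their template exactly", {
  spec <- toyAmpliconSpec()
  for (tmpl in c("unedited", "hdr")) {
    pr <- AmpliconSimParams(stats::setNames(1, tmpl), n_reads = 40,
                            substitution_error_rate = 0, read_length = 80,
                            seed = 3)
    r1 <- withr::local_tempfile(fileext = ".fastq")
    r2 <- withr::local_tempfile(fileext = ".fastq")
    sim <- simulateAmpliconReads(spec, pr, r1, r2)
    mg <- mergePairs(readFastq(r1), readFastq(r2))
    expect_length(mg$failed, 0L)
    want <- if (tmpl == "unedited") refSeq(spec) else donorSeq(spec)
    expect_true(all(as.character(mg$merged) == want))
  }
})

test_that("amplicon truth table equals the seeded multinomial draw", {
  spec <- toyAmpliconSpec()
  mix <- c(hdr = 0.30, `del2@cut` = 0.45, unedited = 0.25)
  pr <- AmpliconSimParams(mix, n_reads = 500, seed = 17)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  sim <- simulateAmpliconReads(spec, pr, r1, r2)
  expect_equal(sum(sim$template_counts), 500L)
  expect_equal(as.vector(table(sim$truth$template)[names(mix)]),
               unname(sim$template_counts[names(mix)]))
  # conservation: one truth row and one read pair per draw
  expect_equal(nrow(sim$truth), 500L)
  expect_length(readFastq(r1), 500L)
  expect_length(readFastq(r2), 500L)
  # determinism: same params + seed -> identical bytes
  r1b <- withr::local_tempfile(fileext = ".fastq")
  r2b <- withr::local_tempfile(fileext = ".fastq")
  simulateAmpliconReads(spec, pr, r1b, r2b)
  expect_identical(readBin(r1, "raw", file.size(r1)),
                   readBin(r1b, "raw", file.size(r1b)))
})

test_that("mixture probabilities must sum to one and templates must fit", {
  spec <- toyAmpliconSpec()
  expect_error(AmpliconSimParams(c(unedited = 0.5, hdr = 0.4)), "sum to 1")
  pr <- AmpliconSimParams(c(`del500@0` = 1), n_reads = 5, seed = 1)
  expect_error(
    simulateAmpliconReads(spec, pr, tempfile(), tempfile()),
    "outside the reference")
})
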