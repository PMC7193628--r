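adapter <- "AGATCGGAAGAGCACACGTC"

test_that("adapter trimming removes read-through, full and partial", {
  insert <- "ACGTACGTCCGGTTAA"
  reads <- sequenceReads(
    c("full", "partial", "none", "short"),
    c(paste0(insert, adapter),            # full adapter
      paste0(insert, substr(adapter, 1, 5)),  # first 5 nt of adapter
      insert,                              # no adapter content
      "AG"))                               # shorter than min match
  out <- trimAdapter(reads, adapter)
  expect_equal(as.character(out)[1], insert, ignore_attr = TRUE)
  expect_equal(as.character(out)[2], insert, ignore_attr = TRUE)
  expect_equal(as.character(out)[3], insert, ignore_attr = TRUE)
  expect_equal(as.character(out)[4], "AG", ignore_attr = TRUE)
  # qualities are trimmed in step
  expect_equal(unname(Biostrings::width(Biostrings::quality(out))),
               unname(nchar(as.character(out))))
})

test_that("pair merging reconstructs the fragment from its mates", {
  set.seed(30)
  amplicon <- randomDna(16)
  r1 <- sequenceReads("p", substr(amplicon, 1, 12))
  r2 <- sequenceReads("p", revcompChr(substring(amplicon, 5, 16)))
  mg <- mergePairs(r1, r2, min_overlap = 8)
  expect_length(mg$failed, 0L)
  expect_equal(as.character(mg$merged), amplicon, ignore_attr = TRUE)
})

test_that("disjoint mates fail to merge and are reported", {
  r1 <- sequenceReads("q", "ACGTACGTACGT")
  r2 <- sequenceReads("q", "CCCCGGGGTTTT")
  mg <- mergePairs(r1, r2, min_overlap = 10)
  expect_equal(mg$failed, "q")
  expect_length(mg$merged, 0L)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  # identical 12-mers except position 6; mate arrives reverse-complemented
  s1 <- "ACGTACGTACGT"
  s2 <- "ACGTAGGTACGT"
  r2rc <- revcompChr(s2)
  r1 <- sequenceReads("d", s1, list(c(rep(40L, 5), 40L, rep(40L, 6))))
  r2 <- sequenceReads("d", r2rc, list(rep(10L, 12)))
  mg <- mergePairs(r1, r2, min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(as.character(mg$merged), s1, ignore_attr = TRUE)
  # now give the mate the higher quality: its base wins
  r1b <- sequenceReads("d", s1, list(rep(10L, 12)))
  r2b <- sequenceReads("d", r2rc, list(rep(40L, 12)))
  mgb <- mergePairs(r1b, r2b, min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(as.character(mgb$merged), s2, ignore_attr = TRUE)
})

test_that("cut inference is strand-symmetric and rejects bad sites", {
  spec <- toyAmpliconSpec()
  expect_equal(inferCutIndex(spec), 57L)
  # same protospacer on the reverse strand of the mirrored reference
  ps <- substr(refSeq(spec), 41, 60)
  rc_ref <- revcompChr(refSeq(spec))
  rc_don <- revcompChr(donorSeq(spec))
  fl <- editFlags(spec)
  L <- nchar(refSeq(spec))
  mir <- AmpliconSpec(
    "mirror", rc_ref, rc_don, protospacer = ps,
    pam = "NNN",
    flags = data.frame(
      ref_pos = rev(L - 1L - fl$ref_pos),
      ref_base = rev(chartr("ACGT", "TGCA", fl$ref_base)),
      alt_base = rev(chartr("ACGT", "TGCA", fl$alt_base))))
  # manual reverse-complement placement: cut mirrors across the amplicon
  expect_equal(cutIndex(mir), L - 57L)
  # absent or multiply-occurring protospacers are rejected
  expect_error(
    AmpliconSpec("x", refSeq(spec), refSeq(spec),
                 protospacer = "AAAAAAAAAAAAAAAAAAAA"),
    "not found")
  dup_ref <- paste0(refSeq(spec), substr(refSeq(spec), 31, 80))
  expect_error(
    AmpliconSpec("x", dup_ref, dup_ref, protospacer = ps),
    "times")
})

test_that("canonical constructed reads classify exactly as expected", {
  spec <- toyAmpliconSpec()
  cls <- classifyReads(canonicalReads(spec), spec)
  expect_equal(cls$category,
               c("UNEDITED", "HDR", "NHEJ", "MIXED"))
  expect_equal(cls$indel_in_window, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cls$flags_converted, c(0L, 2L, 0L, 2L))
  expect_equal(cls$chosen_template,
               c("reference", "donor", "reference", "donor"))
})

test_that("indels outside the window do not trigger the NHEJ rule", {
  spec <- toyAmpliconSpec()
  ref <- refSeq(spec)
  cut <- cutIndex(spec)
  # 1-nt deletion far from the cut: indel, but not in window
  far_del <- paste0(substr(ref, 1, 9), substring(ref, 11))
  # deletion just inside the downstream window edge
  edge_del <- paste0(substr(ref, 1, cut + 2), substring(ref, cut + 4))
  # deletion just beyond the downstream window edge
  out_del <- paste0(substr(ref, 1, cut + 3), substring(ref, cut + 5))
  cls <- classifyReads(
    sequenceReads(c("far", "edge", "out"), c(far_del, edge_del, out_del)),
    spec)
  expect_equal(cls$indel_in_window, c(FALSE, TRUE, FALSE))
  expect_equal(cls$category[2], "NHEJ")
})

test_that("window half-width is configurable and widens the NHEJ net", {
  spec <- toyAmpliconSpec()
  ref <- refSeq(spec)
  cut <- cutIndex(spec)
  probe <- paste0(substr(ref, 1, cut + 4), substring(ref, cut + 6))
  narrow <- classifyReads(sequenceReads("p", probe), spec,
                          window_halfwidth = 3)
  wide <- classifyReads(sequenceReads("p", probe), spec,
                        window_halfwidth = 6)
  expect_false(narrow$indel_in_window)
  expect_true(wide$indel_in_window)
})

test_that("partial flag conversion is counted per flag, not as HDR", {
  spec <- toyAmpliconSpec()
  fl <- editFlags(spec)
  partial <- refSeq(spec)
  substr(partial, fl$ref_pos[1] + 1, fl$ref_pos[1] + 1) <- fl$alt_base[1]
  cls <- classifyReads(sequenceReads("p", partial), spec)
  expect_equal(cls$flags_converted, 1L)
  expect_false(cls$category == "HDR")
  expect_true(cls[[paste0("flag_", fl$ref_pos[1])]])
  expect_false(cls[[paste0("flag_", fl$ref_pos[2])]])
})

test_that("short or garbage reads are AMBIGUOUS, never silently dropped", {
  spec <- toyAmpliconSpec()
  short <- substr(refSeq(spec), 1, 30)
  garbage <- paste(rep("ACGG", 30), collapse = "")
  cls <- classifyReads(sequenceReads(c("s", "g"), c(short, garbage)), spec)
  expect_equal(cls$category, c("AMBIGUOUS", "AMBIGUOUS"))
})

test_that("rate bookkeeping follows the aligned-read denominator", {
  mk <- function(cat, n) data.frame(category = rep(cat, n))
  cls <- rbind(mk("HDR", 9), mk("UNEDITED", 81))
  r <- summarizeRates(cls, n_failed = 10)
  expect_equal(r@hdrRate, 9 / 90)
  expect_equal(r@totalReads, 100L)
  expect_equal(r@alignedReads, 90L)
  cls2 <- rbind(mk("HDR", 30), mk("NHEJ", 45), mk("MIXED", 5),
                mk("UNEDITED", 20))
  r2 <- summarizeRates(cls2)
  expect_equal(r2@hdrRate, 0.30)
  expect_equal(r2@nhejRate, 0.50)  # MIXED counts in the NHEJ numerator
  expect_equal(r2@uneditedRate, 0.20)
  expect_equal(r2@mixedRate, 0.05)
  expect_equal(r2@hdrRate + r2@nhejRate + r2@uneditedRate, 1)
  r3 <- summarizeRates(mk("UNEDITED", 10))
  expect_equal(r3@hdrRate, 0)
  expect_equal(r3@nhejRate, 0)
  # zero aligned reads: missing sentinel, not zero
  r4 <- summarizeRates(mk("AMBIGUOUS", 5), n_failed = 5)
  expect_true(is.na(r4@hdrRate))
  expect_equal(r4@alignedReads, 0L)
})

test_that("classification is a partition: every read gets one category", {
  spec <- toyAmpliconSpec()
  pr <- AmpliconSimParams(
    c(hdr = 0.3, `del2@cut` = 0.3, `ins1@cut` = 0.1, unedited = 0.2,
      `partial@1` = 0.1),
    n_reads = 300, read_length = 80, seed = 31)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  simulateAmpliconReads(spec, pr, r1, r2)
  res <- quantifyEditing(r1, r2, spec)
  cls <- res$classifications
  expect_true(all(cls$category %in%
                    c("UNEDITED", "HDR", "NHEJ", "MIXED", "AMBIGUOUS")))
  r <- res$rates
  expect_equal(r@hdrRate + r@nhejRate + r@uneditedRate, 1, tolerance = 1e-9)
})

test_that("programmed HDR fractions are recovered monotonically", {
  spec <- toyAmpliconSpec()
  est <- vapply(c(0.1, 0.3, 0.5), function(h) {
    pr <- AmpliconSimParams(
      c(hdr = h, `del2@cut` = 0.3, unedited = 0.7 - h),
      n_reads = 400, read_length = 80, seed = 97)
    r1 <- withr::local_tempfile(fileext = ".fastq")
    r2 <- withr::local_tempfile(fileext = ".fastq")
    simulateAmpliconReads(spec, pr, r1, r2)
    quantifyEditing(r1, r2, spec)$rates@hdrRate
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
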