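.CATEGORIES <- c("UNEDITED", "HDR", "NHEJ", "MIXED", "AMBIGUOUS")

# read base observed at every template position (gap character for
# template bases deleted from the read)
.read_base_at_template <- function(aligned_read, aligned_template) {
  zr <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  zt <- strsplit(aligned_template, "", fixed = TRUE)[[1]]
  zr[zt != "-"]
}

# does any indel operation touch the window of `halfwidth` bases on each
# side of the blunt cut (reference coordinates, 0-based)?
.indel_in_window <- function(ops, cut, halfwidth, to_ref = identity) {
  idx <- ops$op %in% c("insertion", "deletion")
  if (!any(idx)) return(FALSE)
  lo <- cut - halfwidth
  hi <- cut + halfwidth
  for (i in which(idx)) {
    s <- to_ref(ops$b_start[i])
    e <- to_ref(ops$b_end[i])
    hit <- if (ops$op[i] == "insertion") s >= lo && s <= hi
           else s < hi && e > lo
    if (hit) return(TRUE)
  }
  FALSE
}

#' Classify merged amplicon reads as editing outcomes
#'
#' Each merged read is globally aligned to the reference and to the donor;
#' the higher-scoring template is kept (ties prefer the reference, which
#' biases against over-calling HDR).  A read is `HDR` when every donor
#' flag is converted and no insertion/deletion falls in the cut-site
#' window, `MIXED` when fully converted but carrying a window indel,
#' `NHEJ` when it carries a window indel without full conversion, and
#' `UNEDITED` otherwise (this complement class also holds partial flag
#' conversions without indels; per-flag counts retain that signal).
#' Reads shorter than half the reference, or aligning below
#' `ambiguous_floor` of the maximum attainable score, are `AMBIGUOUS` and
#' excluded from the aligned-read denominator.
#'
#' @param reads merged reads (`QualityScaledDNAStringSet`, see
#'   [mergePairs()]).
#' @param spec an [AmpliconSpec-class].
#' @param match,mismatch,gap_open,gap_extend alignment scores passed to
#'   [needlemanWunsch()].
#' @param window_halfwidth overrides the spec's indel-window half-width.
#' @param ambiguous_floor minimum fraction of the maximum attainable
#'   alignment score (`match` times the shorter sequence length) a read
#'   must reach to be called (default 0.6).
#' @return `data.frame` with one row per read: `read_id`, `category`,
#'   `indel_in_window`, `flags_converted`, `chosen_template`,
#'   `alignment_score`, plus one logical `flag_<ref_pos>` column per flag.
#' @export
classifyReads <- function(reads, spec, match = 5, mismatch = -4,
                          gap_open = 10, gap_extend = 0.5,
                          window_halfwidth = NULL, ambiguous_floor = 0.6) {
  stopifnot(is(spec, "AmpliconSpec"))
  w <- if (is.null(window_halfwidth)) spec@windowHalfwidth
       else as.integer(window_halfwidth)
  ref <- refSeq(spec)
  don <- donorSeq(spec)
  fl <- editFlags(spec)
  bases <- as.character(reads)
  ids <- if (is.null(names(reads))) as.character(seq_along(reads))
         else names(reads)
  n <- length(bases)
  category <- character(n)
  indel_win <- logical(n)
  conv_count <- integer(n)
  template <- character(n)
  score <- numeric(n)
  flag_mat <- matrix(FALSE, n, nrow(fl))
  for (i in seq_len(n)) {
    rd <- bases[i]
    if (nchar(rd) < 0.5 * nchar(ref)) {
      category[i] <- "AMBIGUOUS"
      template[i] <- NA_character_
      score[i] <- NA_real_
      next
    }
    ar <- needlemanWunsch(rd, ref, match, mismatch, gap_open, gap_extend)
    ad <- needlemanWunsch(rd, don, match, mismatch, gap_open, gap_extend)
    use_donor <- ad$score > ar$score
    aln <- if (use_donor) ad else ar
    tmpl <- if (use_donor) don else ref
    template[i] <- if (use_donor) "donor" else "reference"
    score[i] <- aln$score
    if (aln$score < ambiguous_floor * match * min(nchar(rd), nchar(tmpl))) {
      category[i] <- "AMBIGUOUS"
      next
    }
    # template->reference coordinate map (identity unless the donor
    # carries an insertion cassette)
    to_ref <- if (use_donor && !is.na(spec@insertionPos)) {
      ilen <- nchar(spec@insertionSeq)
      ipos <- spec@insertionPos
      function(p) ifelse(p <= ipos, p, pmax(ipos, p - ilen))
    } else identity
    indel_win[i] <- .indel_in_window(aln$ops, cutIndex(spec), w, to_ref)
    if (nrow(fl)) {
      at <- .read_base_at_template(aln$aligned_a, aln$aligned_b)
      tpos <- if (use_donor) .donor_pos(spec, fl$ref_pos) else fl$ref_pos
      flag_mat[i, ] <- at[tpos + 1L] == fl$alt_base
      conv_count[i] <- sum(flag_mat[i, ])
    }
    all_conv <- nrow(fl) > 0L && conv_count[i] == nrow(fl)
    category[i] <- if (all_conv && !indel_win[i]) "HDR"
      else if (all_conv && indel_win[i]) "MIXED"
      else if (indel_win[i]) "NHEJ"
      else "UNEDITED"
  }
  out <- data.frame(read_id = ids, category = category,
                    indel_in_window = indel_win,
                    flags_converted = conv_count,
                    chosen_template = template,
                    alignment_score = score,
                    stringsAsFactors = FALSE)
  if (nrow(fl)) {
    colnames(flag_mat) <- paste0("flag_", fl$ref_pos)
    out <- cbind(out, as.data.frame(flag_mat))
  }
  out
}

#' Summarize read classifications into editing rates
#'
#' Aligned reads are `total - merge failures - AMBIGUOUS`.  The HDR rate is
#' the fraction of aligned reads fully converted to the donor with no
#' cut-window indel; the NHEJ rate counts *any* aligned read with a
#' cut-window indel (so MIXED reads are included, and reported separately);
#' per-flag conversion is the fraction of aligned reads carrying each
#' flag's donor base.  With zero aligned reads all rates are `NA`.
#'
#' @param classifications output of [classifyReads()].
#' @param n_failed number of read pairs that failed to merge (counted in
#'   `totalReads` but never aligned).
#' @return an [EditingRates-class].
#' @export
summarizeRates <- function(classifications, n_failed = 0L) {
  cls <- classifications$category
  total <- nrow(classifications) + n_failed
  n_amb <- sum(cls == "AMBIGUOUS")
  aligned <- nrow(classifications) - n_amb
  flag_cols <- grep("^flag_", names(classifications), value = TRUE)
  if (aligned == 0L) {
    per_flag <- rep(NA_real_, length(flag_cols))
    names(per_flag) <- flag_cols
    return(new("EditingRates", totalReads = as.integer(total),
               alignedReads = 0L, hdrRate = NA_real_, nhejRate = NA_real_,
               uneditedRate = NA_real_, mixedRate = NA_real_,
               ambiguousRate = if (total) (n_amb + n_failed) / total
                               else NA_real_,
               perFlagConversion = per_flag))
  }
  ok <- cls != "AMBIGUOUS"
  per_flag <- vapply(flag_cols, function(cn)
    sum(classifications[[cn]][ok]) / aligned, numeric(1))
  new("EditingRates",
      totalReads = as.integer(total), alignedReads = as.integer(aligned),
      hdrRate = sum(cls == "HDR") / aligned,
      nhejRate = sum(cls %in% c("NHEJ", "MIXED")) / aligned,
      uneditedRate = sum(cls == "UNEDITED") / aligned,
      mixedRate = sum(cls == "MIXED") / aligned,
      ambiguousRate = (n_amb + n_failed) / total,
      perFlagConversion = per_flag)
}

#' @rdname EditingRates-class
#' @param object an `EditingRates`.
#' @export
setMethod("show", "EditingRates", function(object) {
  cat(sprintf(paste0("EditingRates over %d aligned / %d total reads\n",
                     "  HDR %.4f | NHEJ %.4f (mixed %.4f) | ",
                     "unedited %.4f | ambiguous %.4f\n"),
              object@alignedReads, object@totalReads, object@hdrRate,
              object@nhejRate, object@mixedRate, object@uneditedRate,
              object@ambiguousRate))
  if (length(object@perFlagConversion))
    cat("  per-flag conversion:",
        paste(sprintf("%s=%.4f", names(object@perFlagConversion),
                      object@perFlagConversion), collapse = " "), "\n")
})

#' @rdname EditingRates-class
#' @export
editingRates <- function(object) {
  c(hdr = object@hdrRate, nhej = object@nhejRate,
    unedited = object@uneditedRate, mixed = object@mixedRate,
    ambiguous = object@ambiguousRate)
}

#' Quantify editing outcomes from paired amplicon FASTQ files
#'
#' End-to-end driver: adapter-trim both mates, merge pairs, classify every
#' merged read against the amplicon spec, and summarize rates.
#'
#' @param r1_path,r2_path paired FASTQ files (mate 2 as sequenced).
#' @param spec an [AmpliconSpec-class].
#' @param adapter adapter to trim (skipped when `NULL`).
#' @param min_overlap,max_mismatch_frac pair-merging parameters
#'   (see [mergePairs()]).
#' @param ... alignment/classification parameters passed to
#'   [classifyReads()].
#' @return list with `rates` ([EditingRates-class]) and `classifications`
#'   (per-read `data.frame`).
#' @export
quantifyEditing <- function(r1_path, r2_path, spec, adapter = NULL,
                            min_overlap = 10L, max_mismatch_frac = 0.2,
                            ...) {
  r1 <- readFastq(r1_path)
  r2 <- readFastq(r2_path)
  if (!is.null(adapter)) {
    r1 <- trimAdapter(r1, adapter)
    r2 <- trimAdapter(r2, adapter)
  }
  mg <- mergePairs(r1, r2, min_overlap, max_mismatch_frac)
  cls <- classifyReads(mg$merged, spec, ...)
  list(rates = summarizeRates(cls, n_failed = length(mg$failed)),
       classifications = cls)
}
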