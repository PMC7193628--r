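#' @importFrom Biostrings DNAStringSet PhredQuality QualityScaledDNAStringSet
#'   readQualityScaledDNAStringSet writeQualityScaledXStringSet quality
#' @useDynLib crisprHDR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.phred_string <- function(scores) {
  vapply(scores, function(q) rawToChar(as.raw(q + 33L)), character(1))
}

.phred_scores <- function(x) {
  lapply(as.character(Biostrings::quality(x)),
         function(s) as.integer(charToRaw(s)) - 33L)
}

#' Build a set of quality-scaled reads
#'
#' Convenience constructor for the read container used throughout the
#' package, a `QualityScaledDNAStringSet` (Sanger/phred+33 qualities).
#'
#' @param ids read identifiers.
#' @param bases character vector of base strings (may contain `N`).
#' @param quals list of per-base integer quality scores (recycled scalar
#'   allowed), or a character vector of phred+33 strings.
#' @return a `QualityScaledDNAStringSet` named by `ids`.
#' @export
sequenceReads <- function(ids, bases, quals = 37L) {
  if (is.numeric(quals)) {
    quals <- mapply(function(b, q) rep(as.integer(q), nchar(b)),
                    bases, rep_len(list(quals), length(bases)),
                    SIMPLIFY = FALSE)
  }
  if (is.list(quals)) {
    stopifnot(lengths(quals) == nchar(bases))
    quals <- .phred_string(quals)
  }
  s <- DNAStringSet(bases)
  names(s) <- ids
  q <- PhredQuality(unname(quals))
  names(q) <- ids
  QualityScaledDNAStringSet(s, q)
}

.validate_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record at record ", n %/% 4L + 1L, " in ", path)
  if (n == 0L) return(invisible(TRUE))
  rec <- seq_len(n %/% 4L)
  hdr <- lines[(rec - 1L) * 4L + 1L]
  sep <- lines[(rec - 1L) * 4L + 3L]
  seqs <- lines[(rec - 1L) * 4L + 2L]
  quals <- lines[(rec - 1L) * 4L + 4L]
  bad <- !startsWith(hdr, "@")
  if (any(bad))
    stop("malformed FASTQ header at record ", rec[bad][1], " in ", path)
  bad <- !startsWith(sep, "+")
  if (any(bad))
    stop("malformed FASTQ separator at record ", rec[bad][1], " in ", path)
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("bases/qualities length mismatch at record ", rec[bad][1],
         " in ", path)
  invisible(TRUE)
}

#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed 4-line FASTQ (Sanger phred+33).  The file
#' structure is validated first so malformed input fails with the offending
#' record index rather than a downstream parse error.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return a `QualityScaledDNAStringSet`.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  .validate_fastq_lines(lines, path)
  if (length(lines) == 0L) return(sequenceReads(character(), character()))
  # Biostrings warns about dropping its own metadata columns here; the
  # reads themselves are unaffected
  withCallingHandlers(
    readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write a FASTQ file
#'
#' Writes canonical 4-line records; `writeFastq()` then [readFastq()]
#' round-trips ids, bases and qualities exactly, and the bytes themselves
#' for canonical input.
#'
#' @param reads a `QualityScaledDNAStringSet` (see [sequenceReads()]).
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
writeFastq <- function(reads, path) {
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  writeQualityScaledXStringSet(reads, path,
                               compress = grepl("\\.gz$", path))
  invisible(path)
}
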