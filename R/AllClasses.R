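#' @import methods
#' @importFrom S4Vectors metadata
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T")

.is_dna <- function(x, allow_n = FALSE) {
  alpha <- if (allow_n) c(.DNA_ALPHABET, "N") else .DNA_ALPHABET
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% alpha)
}

#' Guide library catalogue
#'
#' Holds the targeting and non-targeting (control) guide catalogue a pooled
#' CRISPRi screen is counted and tested against.  Control guides match no
#' genomic site and define the null enrichment distribution; every targeting
#' guide is annotated with the gene whose transcription start site it
#' represses.
#'
#' @slot entries `data.frame` with columns `guide_id` (unique), `gene`,
#'   `protospacer` (uppercase ACGT) and `is_control` (logical).
#' @export
setClass("GuideLibrary", representation(entries = "data.frame"))

setValidity("GuideLibrary", function(object) {
  e <- object@entries
  need <- c("guide_id", "gene", "protospacer", "is_control")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$guide_id))
    return(paste0("duplicate guide_id: ",
                  e$guide_id[duplicated(e$guide_id)][1]))
  bad <- !vapply(e$protospacer, .is_dna, logical(1))
  if (any(bad))
    return(paste0("protospacer not over {A,C,G,T} at row ", which(bad)[1]))
  if (anyDuplicated(e$protospacer))
    return("protospacers must be unique")
  if (any(!e$is_control & (is.na(e$gene) | e$gene == "")))
    return("every targeting (non-control) guide needs a non-empty gene")
  # a protospacer contained in a longer one makes exact-match counting
  # ambiguous by construction, so it is rejected at load time
  len <- nchar(e$protospacer)
  if (length(unique(len)) > 1L) {
    sp <- e$protospacer[order(len)]
    for (i in seq_along(sp)[-length(sp)]) {
      hit <- grepl(sp[i], sp[-seq_len(i)], fixed = TRUE)
      if (any(hit))
        return(paste0("protospacer ", sp[i], " is contained in ",
                      sp[-seq_len(i)][hit][1]))
    }
  }
  TRUE
})

#' Amplicon specification
#'
#' The coordinate frame for amplicon read classification: the unedited
#' reference sequence, the donor sequence (reference with every programmed
#' edit applied), the blunt Cas9 cut position, and the "flag" positions --
#' programmed donor substitutions whose conversion is scored per read.
#'
#' Coordinates are 0-based; `cutIndex` counts reference bases 5' of the
#' blunt cut, i.e. the cut falls between positions `cutIndex - 1` and
#' `cutIndex`.  Donors may differ from the reference only at flag positions,
#' or additionally by one declared insertion cassette
#' (`insertionPos`/`insertionSeq`).
#'
#' @slot name amplicon label.
#' @slot reference,donor uppercase ACGT strings.
#' @slot protospacer optional 20-nt spacer (empty string when absent).
#' @slot pam PAM pattern, default `"NGG"`.
#' @slot cutIndex integer in `[0, nchar(reference)]`.
#' @slot flags `data.frame` with `ref_pos` (0-based), `ref_base`, `alt_base`.
#' @slot windowHalfwidth half-width (bases each side of the cut) of the
#'   indel window used by the NHEJ rule; default 3.
#' @slot insertionPos,insertionSeq optional donor insertion cassette
#'   (`NA`/`""` when the donor is substitution-only).
#' @export
setClass("AmpliconSpec", representation(
  name = "character", reference = "character", donor = "character",
  protospacer = "character", pam = "character", cutIndex = "integer",
  flags = "data.frame", windowHalfwidth = "integer",
  insertionPos = "integer", insertionSeq = "character"))

# donor coordinate homologous to a reference coordinate
.donor_pos <- function(spec, ref_pos) {
  if (is.na(spec@insertionPos)) return(ref_pos)
  ifelse(ref_pos >= spec@insertionPos,
         ref_pos + nchar(spec@insertionSeq), ref_pos)
}

setValidity("AmpliconSpec", function(object) {
  ref <- object@reference; don <- object@donor
  if (!.is_dna(ref) || !.is_dna(don))
    return("reference and donor must be uppercase over {A,C,G,T}")
  if (object@cutIndex < 0L || object@cutIndex > nchar(ref))
    return("cutIndex must lie in [0, nchar(reference)]")
  if (object@windowHalfwidth < 0L)
    return("windowHalfwidth must be >= 0")
  fl <- object@flags
  if (nrow(fl)) {
    if (is.unsorted(fl$ref_pos, strictly = TRUE))
      return("flags must be sorted by ref_pos, without duplicates")
    refb <- substring(ref, fl$ref_pos + 1L, fl$ref_pos + 1L)
    if (any(refb != fl$ref_base))
      return(paste0("flag at ref_pos ", fl$ref_pos[refb != fl$ref_base][1],
                    ": ref_base disagrees with the reference"))
    dpos <- .donor_pos(object, fl$ref_pos)
    donb <- substring(don, dpos + 1L, dpos + 1L)
    if (any(donb != fl$alt_base))
      return(paste0("flag at ref_pos ", fl$ref_pos[donb != fl$alt_base][1],
                    ": alt_base disagrees with the donor"))
    if (any(fl$ref_base == fl$alt_base))
      return("flag ref_base and alt_base must differ")
  }
  # reconstruct the donor from reference + declared edits; any further
  # difference means the spec under-declares its edits
  expected <- strsplit(ref, "", fixed = TRUE)[[1]]
  if (nrow(fl)) expected[fl$ref_pos + 1L] <- fl$alt_base
  expected <- paste(expected, collapse = "")
  if (!is.na(object@insertionPos)) {
    if (object@insertionPos < 0L || object@insertionPos > nchar(ref))
      return("insertionPos outside the reference")
    expected <- paste0(substr(expected, 1L, object@insertionPos),
                       object@insertionSeq,
                       substring(expected, object@insertionPos + 1L))
  }
  if (expected != don)
    return(paste0("donor differs from the reference outside the declared ",
                  "flags/insertion (lengths ", nchar(ref), " vs ",
                  nchar(don), ")"))
  TRUE
})

#' Editing-outcome rate summary
#'
#' Per-amplicon HDR/NHEJ/unedited/mixed/ambiguous fractions over aligned
#' reads, plus per-flag conversion frequencies.  Following the field's
#' convention, the NHEJ rate counts *any* read with an indel in the cut-site
#' window, so donor-converted reads that also carry a window indel (MIXED)
#' are included in `nhejRate` and reported separately as `mixedRate`.
#' Aligned reads are those that merged and passed the alignment-quality
#' floor; HDR, NHEJ and unedited rates use the number of aligned reads as
#' denominator (and so `hdrRate + nhejRate + uneditedRate == 1`), while
#' `ambiguousRate` is reported over total reads.  When no read aligns the
#' rates are `NA`, never 0.
#'
#' @slot totalReads,alignedReads integer counts.
#' @slot hdrRate,nhejRate,uneditedRate,mixedRate numeric fractions of
#'   aligned reads (`NA` when `alignedReads == 0`).
#' @slot ambiguousRate fraction of total reads that failed to merge or
#'   align confidently.
#' @slot perFlagConversion named numeric, one entry per donor flag.
#' @export
setClass("EditingRates", representation(
  totalReads = "integer", alignedReads = "integer",
  hdrRate = "numeric", nhejRate = "numeric", uneditedRate = "numeric",
  mixedRate = "numeric", ambiguousRate = "numeric",
  perFlagConversion = "numeric"))

setValidity("EditingRates", function(object) {
  if (object@alignedReads > object@totalReads)
    return("alignedReads cannot exceed totalReads")
  r <- c(object@hdrRate, object@nhejRate, object@uneditedRate,
         object@mixedRate, object@ambiguousRate, object@perFlagConversion)
  if (object@alignedReads > 0L) {
    if (any(is.na(r)) || any(r < 0) || any(r > 1))
      return("rates must lie in [0, 1]")
    part <- object@hdrRate + object@nhejRate + object@uneditedRate
    if (abs(part - 1) > 1e-9)
      return("HDR + NHEJ + unedited must sum to 1 over aligned reads")
    if (object@mixedRate > object@nhejRate + 1e-12)
      return("mixedRate is a subset of nhejRate")
  }
  TRUE
})
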