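#' Construct an amplicon specification
#'
#' @param name amplicon label.
#' @param reference,donor DNA strings (uppercased on input).  The donor must
#'   equal the reference with the declared flags (and optional insertion
#'   cassette) applied; any undeclared difference is a validation error.
#' @param protospacer optional 20-nt spacer used to infer `cut_index` when
#'   it is not given.
#' @param pam PAM pattern (`N` = any base), default `"NGG"`.
#' @param cut_index 0-based count of reference bases 5' of the blunt cut;
#'   when `NULL` and a protospacer is given it is filled in with
#'   [inferCutIndex()].
#' @param flags `data.frame` with 0-based `ref_pos`, `ref_base`, `alt_base`
#'   columns describing each programmed donor substitution.
#' @param window_halfwidth bases on each side of the cut included in the
#'   indel window (default 3, i.e. a six-base-pair window).
#' @param insertion optional `list(pos = <0-based ref position>,
#'   seq = <cassette>)` for donors carrying an insertion.
#' @return a validated [AmpliconSpec-class].
#' @export
AmpliconSpec <- function(name, reference, donor, protospacer = "",
                         pam = "NGG", cut_index = NULL,
                         flags = data.frame(ref_pos = integer(),
                                            ref_base = character(),
                                            alt_base = character()),
                         window_halfwidth = 3L, insertion = NULL) {
  reference <- toupper(reference)
  donor <- toupper(donor)
  protospacer <- toupper(protospacer)
  flags <- as.data.frame(flags)
  if (nrow(flags)) {
    flags$ref_pos <- as.integer(flags$ref_pos)
    flags <- flags[order(flags$ref_pos), , drop = FALSE]
    rownames(flags) <- NULL
  }
  ins_pos <- if (is.null(insertion)) NA_integer_ else as.integer(insertion$pos)
  ins_seq <- if (is.null(insertion)) "" else toupper(insertion$seq)
  if (is.null(cut_index) || is.na(cut_index)) {
    if (!nzchar(protospacer))
      stop("either cut_index or a protospacer must be supplied")
    cut_index <- .infer_cut(reference, protospacer, toupper(pam))
  }
  new("AmpliconSpec", name = as.character(name),
      reference = reference, donor = donor,
      protospacer = protospacer, pam = toupper(pam),
      cutIndex = as.integer(cut_index),
      flags = flags, windowHalfwidth = as.integer(window_halfwidth),
      insertionPos = ins_pos, insertionSeq = ins_seq)
}

#' @rdname AmpliconSpec-class
#' @aliases refSeq donorSeq cutIndex editFlags windowHalfwidth
#' @export
setMethod("refSeq", "AmpliconSpec", function(x) x@reference)

#' @rdname AmpliconSpec-class
#' @export
setMethod("donorSeq", "AmpliconSpec", function(x) x@donor)

#' @rdname AmpliconSpec-class
#' @export
setMethod("cutIndex", "AmpliconSpec", function(x) x@cutIndex)

#' @rdname AmpliconSpec-class
#' @export
setMethod("editFlags", "AmpliconSpec", function(x) x@flags)

#' @rdname AmpliconSpec-class
#' @export
setMethod("windowHalfwidth", "AmpliconSpec", function(x) x@windowHalfwidth)

#' @rdname AmpliconSpec-class
#' @param object an `AmpliconSpec`.
#' @export
setMethod("show", "AmpliconSpec", function(object) {
  cat("AmpliconSpec '", object@name, "': ", nchar(object@reference),
      " bp reference, cut at ", object@cutIndex, ", ",
      nrow(object@flags), " flag(s), window +/-",
      object@windowHalfwidth, " bp\n", sep = "")
})

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.pam_matches <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  all(p == "N" | p == s)
}

.find_fixed <- function(needle, haystack) {
  hits <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L  # 0-based
}

#' Infer the blunt cut position from the protospacer
#'
#' Locates the protospacer in the reference (either strand), verifies the
#' adjacent PAM, and places the cut between protospacer positions 17 and 18
#' (3 nt 5' of the PAM), the canonical SpCas9 blunt-cut position, converted
#' to 0-based reference coordinates.
#'
#' @param spec an [AmpliconSpec-class] with a non-empty protospacer.
#' @return integer `cut_index`.
#' @export
inferCutIndex <- function(spec) {
  if (!nzchar(spec@protospacer)) stop("spec has no protospacer")
  .infer_cut(spec@reference, spec@protospacer, spec@pam)
}

.infer_cut <- function(ref, ps, pam) {
  L <- nchar(ps)
  fwd <- .find_fixed(ps, ref)
  rev <- .find_fixed(.revcomp(ps), ref)
  n_occ <- length(fwd) + length(rev)
  if (n_occ == 0L) stop("protospacer not found in the reference")
  if (n_occ > 1L) stop("protospacer occurs ", n_occ,
                       " times in the reference; expected exactly one site")
  if (length(fwd)) {
    s <- fwd
    pam_seq <- substring(ref, s + L + 1L, s + L + nchar(pam))
    if (!.pam_matches(pam_seq, pam))
      stop("no ", pam, " PAM adjacent to the forward protospacer site")
    s + L - 3L
  } else {
    s <- rev
    pam_seq <- substring(ref, s - nchar(pam) + 1L, s)
    if (!.pam_matches(pam_seq, .revcomp(pam)))
      stop("no ", pam, " PAM adjacent to the reverse-strand protospacer site")
    s + 3L
  }
}

#' Read an amplicon specification from a YAML document
#'
#' One spec per file, with keys matching the [AmpliconSpec()] constructor
#' arguments (`name`, `reference`, `donor`, optional `protospacer`, `pam`,
#' `cut_index`, `window_halfwidth`, a `flags` list of
#' `{ref_pos, ref_base, alt_base}` records and an optional
#' `insertion: {pos, seq}`).  All invariants are checked; if `cut_index`
#' is absent but a protospacer is given, the cut is inferred from the
#' protospacer/PAM placement.
#'
#' @param path path to the YAML file.
#' @return a validated [AmpliconSpec-class].
#' @export
readAmpliconSpec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- yaml::read_yaml(path)
  for (key in c("name", "reference", "donor"))
    if (is.null(doc[[key]])) stop("amplicon spec is missing '", key, "'")
  flags <- if (is.null(doc$flags)) {
    data.frame(ref_pos = integer(), ref_base = character(),
               alt_base = character())
  } else {
    do.call(rbind, lapply(doc$flags, function(f)
      data.frame(ref_pos = as.integer(f$ref_pos),
                 ref_base = toupper(f$ref_base),
                 alt_base = toupper(f$alt_base))))
  }
  AmpliconSpec(
    name = doc$name, reference = doc$reference, donor = doc$donor,
    protospacer = if (is.null(doc$protospacer)) "" else doc$protospacer,
    pam = if (is.null(doc$pam)) "NGG" else doc$pam,
    cut_index = doc$cut_index, flags = flags,
    window_halfwidth = if (is.null(doc$window_halfwidth)) 3L
                       else doc$window_halfwidth,
    insertion = doc$insertion)
}

#' Write an amplicon specification to YAML
#'
#' @param spec an [AmpliconSpec-class].
#' @param path output path.
#' @export
writeAmpliconSpec <- function(spec, path) {
  stopifnot(is(spec, "AmpliconSpec"))
  doc <- list(name = spec@name, reference = spec@reference,
              donor = spec@donor, cut_index = spec@cutIndex,
              window_halfwidth = spec@windowHalfwidth)
  if (nzchar(spec@protospacer)) doc$protospacer <- spec@protospacer
  doc$pam <- spec@pam
  if (nrow(spec@flags))
    doc$flags <- lapply(seq_len(nrow(spec@flags)), function(i)
      as.list(spec@flags[i, ]))
  if (!is.na(spec@insertionPos))
    doc$insertion <- list(pos = spec@insertionPos, seq = spec@insertionSeq)
  yaml::write_yaml(doc, path)
  invisible(path)
}
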