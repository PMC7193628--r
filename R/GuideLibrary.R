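#' Construct a guide library
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene gene symbol per guide; control guides may use `""`.
#' @param protospacer 20-nt (typically) spacer sequences; lowercase input is
#'   normalized to uppercase.
#' @param is_control logical; `TRUE` for non-targeting control guides.
#' @return a validated [GuideLibrary-class] object.
#' @examples
#' GuideLibrary(c("g1", "ctrl1"), c("BRCA1", ""),
#'              c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTAAAA"),
#'              c(FALSE, TRUE))
#' @export
GuideLibrary <- function(guide_id, gene, protospacer, is_control) {
  entries <- data.frame(
    guide_id = as.character(guide_id),
    gene = as.character(gene),
    protospacer = toupper(as.character(protospacer)),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE)
  new("GuideLibrary", entries = entries)
}

#' @rdname GuideLibrary-class
#' @aliases guideIds guideGenes protospacers isControl
#' @export
setMethod("guideIds", "GuideLibrary", function(x) x@entries$guide_id)

#' @rdname GuideLibrary-class
#' @export
setMethod("guideGenes", "GuideLibrary", function(x) x@entries$gene)

#' @rdname GuideLibrary-class
#' @export
setMethod("protospacers", "GuideLibrary", function(x) x@entries$protospacer)

#' @rdname GuideLibrary-class
#' @export
setMethod("isControl", "GuideLibrary", function(x) x@entries$is_control)

#' @rdname GuideLibrary-class
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@entries))

#' @rdname GuideLibrary-class
#' @param object a `GuideLibrary`.
#' @export
setMethod("show", "GuideLibrary", function(object) {
  n <- length(object)
  nc <- sum(isControl(object))
  cat("GuideLibrary with", n, "guides (", n - nc, "targeting,", nc,
      "non-targeting controls ) covering",
      length(unique(guideGenes(object)[!isControl(object)])), "genes\n")
})

#' Coerce a guide library to a data.frame
#'
#' @param x a `GuideLibrary`.
#' @param ... ignored.
#' @export
as.data.frame.GuideLibrary <- function(x, ...) x@entries

#' Read a guide library from a tab-separated file
#'
#' Expects a header line with columns `guide_id`, `gene`, `protospacer`,
#' `is_control` (logical or 0/1).  Lowercase protospacer bases are
#' normalized to uppercase; all [GuideLibrary-class] invariants are
#' enforced, so duplicate ids, non-ACGT spacers or targeting guides
#' without a gene raise errors naming the offending row or id.
#'
#' @param path path to the TSV file.
#' @return a [GuideLibrary-class].
#' @export
readGuideLibrary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("guide_id", "gene", "protospacer", "is_control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("guide library is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  is_ctrl <- tab$is_control %in% c("TRUE", "True", "true", "1")
  bad <- !(tab$is_control %in% c("TRUE", "True", "true", "1",
                                 "FALSE", "False", "false", "0"))
  if (any(bad))
    stop("is_control not interpretable as logical at row ", which(bad)[1])
  sp <- toupper(tab$protospacer)
  ok <- vapply(sp, .is_dna, logical(1))
  if (any(!ok))
    stop("protospacer contains non-ACGT characters at row ", which(!ok)[1])
  GuideLibrary(tab$guide_id, tab$gene, sp, is_ctrl)
}

#' Write a guide library to a tab-separated file
#'
#' @param x a [GuideLibrary-class].
#' @param path output path.
#' @export
writeGuideLibrary <- function(x, path) {
  stopifnot(is(x, "GuideLibrary"))
  utils::write.table(x@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
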