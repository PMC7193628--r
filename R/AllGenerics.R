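#' @rdname GuideLibrary-class
#' @param x a `GuideLibrary`.
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("guideGenes", function(x) standardGeneric("guideGenes"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("protospacers", function(x) standardGeneric("protospacers"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname AmpliconSpec-class
#' @param x an `AmpliconSpec`.
#' @export
setGeneric("refSeq", function(x) standardGeneric("refSeq"))

#' @rdname AmpliconSpec-class
#' @export
setGeneric("donorSeq", function(x) standardGeneric("donorSeq"))

#' @rdname AmpliconSpec-class
#' @export
setGeneric("cutIndex", function(x) standardGeneric("cutIndex"))

#' @rdname AmpliconSpec-class
#' @export
setGeneric("editFlags", function(x) standardGeneric("editFlags"))

#' @rdname AmpliconSpec-class
#' @export
setGeneric("windowHalfwidth", function(x) standardGeneric("windowHalfwidth"))
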