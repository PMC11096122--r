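#' Accessors for CloneModel objects
#'
#' @param object a [CloneModel-class].
#' @return `cloneFractions`: the length-K clone-fraction vector;
#'   `cloneProfiles`: the K x V clone-by-variant heteroplasmy matrix;
#'   `assignProb`: the cells x K posterior assignment matrix;
#'   `elboTrace`: the per-iteration objective values.
#' @name CloneModel-accessors
NULL

#' @rdname CloneModel-accessors
#' @export
setGeneric("cloneFractions", function(object) standardGeneric("cloneFractions"))
#' @rdname CloneModel-accessors
#' @export
setMethod("cloneFractions", "CloneModel", function(object) object@pi)

#' @rdname CloneModel-accessors
#' @export
setGeneric("cloneProfiles", function(object) standardGeneric("cloneProfiles"))
#' @rdname CloneModel-accessors
#' @export
setMethod("cloneProfiles", "CloneModel", function(object) object@P)

#' @rdname CloneModel-accessors
#' @export
setGeneric("assignProb", function(object) standardGeneric("assignProb"))
#' @rdname CloneModel-accessors
#' @export
setMethod("assignProb", "CloneModel", function(object) object@gamma)

#' @rdname CloneModel-accessors
#' @export
setGeneric("elboTrace", function(object) standardGeneric("elboTrace"))
#' @rdname CloneModel-accessors
#' @export
setMethod("elboTrace", "CloneModel", function(object) object@elboTrace)
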