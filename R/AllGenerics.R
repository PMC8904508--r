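#' @name adnapipe-generics
#' @title Accessor generics
#' @description Small accessor generics for the package's S4 containers.
#' @param x An object.
#' @param ... Passed on to methods.
NULL

#' @rdname adnapipe-generics
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname adnapipe-generics
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname adnapipe-generics
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname adnapipe-generics
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname adnapipe-generics
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname adnapipe-generics
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname adnapipe-generics
#' @export
setGeneric("freq", function(x) standardGeneric("freq"))

#' @rdname adnapipe-generics
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname adnapipe-generics
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname adnapipe-generics
#' @export
setGeneric("graphRoot", function(x) standardGeneric("graphRoot"))

#' @rdname adnapipe-generics
#' @export
setGeneric("graphLeaves", function(x) standardGeneric("graphLeaves"))

#' @rdname adnapipe-generics
#' @export
setGeneric("admixtureNodes", function(x) standardGeneric("admixtureNodes"))
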