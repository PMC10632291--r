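#' @rdname GenotypeMatrix-class
#' @param x,object a package object
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genoValues", function(x) standardGeneric("genoValues"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname PhenotypeSet-class
#' @param x a \linkS4class{PhenotypeSet}
#' @export
setGeneric("lineMeans", function(x, ...) standardGeneric("lineMeans"))

#' @rdname PhenotypeSet-class
#' @export
setGeneric("lineVariances", function(x, ...) standardGeneric("lineVariances"))

#' @rdname PhenotypeSet-class
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @rdname ModelDesign-class
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname ModelDesign-class
#' @export
setGeneric("termInfo", function(x) standardGeneric("termInfo"))
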