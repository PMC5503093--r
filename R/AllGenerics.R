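#' @rdname accessors
#' @export
setGeneric("nWaters", function(x) standardGeneric("nWaters"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("timestep", function(x) standardGeneric("timestep"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("boxDims", function(x, frame) standardGeneric("boxDims"))

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, frame) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("trajMetadata", function(x) standardGeneric("trajMetadata"))

#' @rdname accessors
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
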