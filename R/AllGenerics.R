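#' @rdname LMSFResult-class
#' @param x an object.
#' @export
setGeneric("filteredImage", function(x) standardGeneric("filteredImage"))

#' @rdname LMSFResult-class
#' @export
setGeneric("backgroundMask", function(x) standardGeneric("backgroundMask"))

#' @rdname LMSFResult-class
#' @export
setGeneric("filterTheta", function(x) standardGeneric("filterTheta"))

#' @rdname LMSFResult-class
#' @export
setGeneric("filterScales", function(x) standardGeneric("filterScales"))

#' @rdname NucleiScene-class
#' @param x an object.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname NucleiScene-class
#' @export
setGeneric("trueBackground", function(x) standardGeneric("trueBackground"))

#' @rdname NucleiScene-class
#' @export
setGeneric("sceneBlobs", function(x) standardGeneric("sceneBlobs"))

#' @rdname NucleiScene-class
#' @export
setGeneric("sceneSpec", function(x) standardGeneric("sceneSpec"))

#' @rdname ColocClassMap-class
#' @param x an object.
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))

#' @rdname ColocClassMap-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Recover per-channel masks from a class map
#'
#' @param x a [ColocClassMap-class].
#' @param ... passed to methods.
#' @return for `channelMasks`, a named list of integer background masks
#'   (1 = background), decoded from the class-map bits.
#' @export
setGeneric("channelMasks", function(x, ...) standardGeneric("channelMasks"))

#' Class-wise pixel counts of a co-localization map
#'
#' @param x a [ColocClassMap-class] or an integer label matrix.
#' @param ... passed to methods.
#' @export
setGeneric("classAreaTable", function(x, ...) standardGeneric("classAreaTable"))
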