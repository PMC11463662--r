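#' @import methods
NULL

#' Result of local mean suppression filtering
#'
#' Container returned by [lmsf2d()] and [cumulativeLMSF()]. It pairs the
#' filtered image (background pixels set to zero, foreground pixels kept
#' bit-identical to the input) with the binary background mask and the
#' filter parameters that produced them.
#'
#' @slot filteredImage numeric or integer matrix; the input image with all
#'   background pixels replaced by zero.
#' @slot backgroundMask integer matrix of the same dimensions; 1 marks a
#'   background (zero-response) pixel, 0 a foreground pixel.
#' @slot theta positive numeric scalar; the suppression threshold applied to
#'   the intensity / local-mean ratio.
#' @slot scales strictly increasing integer vector of averaging half-window
#'   sizes used (a single value for a single-scale response).
#'
#' @seealso [filteredImage()], [backgroundMask()], [filterTheta()],
#'   [filterScales()]
#' @export
setClass("LMSFResult",
    slots = c(
        filteredImage  = "matrix",
        backgroundMask = "matrix",
        theta          = "numeric",
        scales         = "integer"
    )
)

setValidity("LMSFResult", function(object) {
    img  <- object@filteredImage
    mask <- object@backgroundMask
    msg <- character(0)
    if (!identical(dim(img), dim(mask)))
        msg <- c(msg, "filteredImage and backgroundMask dimensions differ")
    if (!all(mask %in% c(0L, 1L)))
        msg <- c(msg, "backgroundMask values must be 0 or 1")
    if (length(object@theta) != 1L || !is.finite(object@theta) ||
        object@theta <= 0)
        msg <- c(msg, "theta must be a single positive number")
    if (length(object@scales) < 1L || any(object@scales < 1L) ||
        is.unsorted(object@scales, strictly = TRUE))
        msg <- c(msg, "scales must be a strictly increasing positive integer vector")
    if (any(img[mask == 1L] != 0))
        msg <- c(msg, "pixels flagged background must be zero in filteredImage")
    if (length(msg)) msg else TRUE
})

#' Parameters of a synthetic fluorescence-nuclei scene
#'
#' Specification consumed by [simNucleiImage()]. The scene is a sum of a
#' constant background offset, a smooth diagonal intensity gradient,
#' Gaussian-profile nuclei blobs (a fraction of which are dim), and
#' zero-truncated additive Gaussian noise. The seed fully determines the
#' output. Use [NucleiSceneSpec()] to construct instances and
#' [scenePreset()] for the frozen named regimes.
#'
#' @slot dim integer vector (rows, columns) of the image.
#' @slot nBlobs number of nuclei blobs (may be zero).
#' @slot radiusRange numeric length-2; nominal blob radii in pixels.
#' @slot peakRange numeric length-2; peak intensities of bright blobs
#'   (arbitrary fluorescence units).
#' @slot dimFraction fraction of blobs drawn as dim nuclei.
#' @slot dimRatio intensity ratio of dim to bright blobs, in (0, 1).
#' @slot backgroundOffset constant background level added everywhere.
#' @slot gradientAmplitude amplitude of the smooth diagonal gradient.
#' @slot noiseSd standard deviation of the additive Gaussian noise
#'   (truncated at zero after summation).
#' @slot clustering numeric in [0, 1]; 0 places blobs uniformly, 1 packs
#'   them into tight clusters.
#' @slot seed integer random seed; fully determines the scene.
#' @slot theta recommended suppression threshold for this regime.
#' @slot scales recommended averaging scale set for this regime (may be
#'   empty for user-defined specs).
#' @slot name human-readable regime name.
#' @export
setClass("NucleiSceneSpec",
    slots = c(
        dim               = "integer",
        nBlobs            = "integer",
        radiusRange       = "numeric",
        peakRange         = "numeric",
        dimFraction       = "numeric",
        dimRatio          = "numeric",
        backgroundOffset  = "numeric",
        gradientAmplitude = "numeric",
        noiseSd           = "numeric",
        clustering        = "numeric",
        seed              = "integer",
        theta             = "numeric",
        scales            = "integer",
        name              = "character"
    )
)

setValidity("NucleiSceneSpec", function(object) {
    msg <- character(0)
    if (length(object@dim) != 2L || any(object@dim < 2L))
        msg <- c(msg, "dim must be two integers >= 2")
    if (object@nBlobs < 0L)
        msg <- c(msg, "nBlobs must be non-negative")
    if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
        diff(object@radiusRange) < 0)
        msg <- c(msg, "radiusRange must be positive and non-decreasing")
    if (length(object@peakRange) != 2L || any(object@peakRange <= 0) ||
        diff(object@peakRange) < 0)
        msg <- c(msg, "peakRange must be positive and non-decreasing")
    if (object@dimFraction < 0 || object@dimFraction > 1)
        msg <- c(msg, "dimFraction must be in [0, 1]")
    if (object@dimRatio <= 0 || object@dimRatio >= 1)
        msg <- c(msg, "dimRatio must be in (0, 1)")
    if (object@backgroundOffset < 0 || object@gradientAmplitude < 0 ||
        object@noiseSd < 0)
        msg <- c(msg, "offset, gradient amplitude and noiseSd must be >= 0")
    if (object@clustering < 0 || object@clustering > 1)
        msg <- c(msg, "clustering must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' A simulated fluorescence-nuclei scene with ground truth
#'
#' Returned by [simNucleiImage()]: the simulated image together with the
#' true background mask (complement of the union of blob supports) and the
#' per-blob parameters actually drawn.
#'
#' @slot image numeric matrix of non-negative intensities.
#' @slot background integer matrix; 1 = true background pixel.
#' @slot blobs data.frame with one row per blob (row, col, radius, sigma,
#'   peak, dim flag).
#' @slot spec the [NucleiSceneSpec-class] that generated the scene.
#' @export
setClass("NucleiScene",
    slots = c(
        image      = "matrix",
        background = "matrix",
        blobs      = "data.frame",
        spec       = "NucleiSceneSpec"
    )
)

setValidity("NucleiScene", function(object) {
    msg <- character(0)
    if (!identical(dim(object@image), dim(object@background)))
        msg <- c(msg, "image and background dimensions differ")
    if (!all(object@background %in% c(0L, 1L)))
        msg <- c(msg, "background mask values must be 0 or 1")
    if (any(!is.finite(object@image)) || any(object@image < 0))
        msg <- c(msg, "image intensities must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' Multi-channel co-localization class map
#'
#' Returned by [colocalize()]. Each pixel carries an integer label in
#' [0, 2^C - 1] whose bit c (channel 1 = least significant bit) records
#' foreground membership of that channel, so C binary masks combine into
#' 2^C co-localization classes.
#'
#' @slot classMap integer matrix of per-pixel class labels.
#' @slot channelNames character vector of channel names.
#' @slot theta per-channel suppression thresholds.
#' @slot scales list of per-channel averaging scale sets.
#' @slot masks list of per-channel background masks (integer matrices).
#' @export
setClass("ColocClassMap",
    slots = c(
        classMap     = "matrix",
        channelNames = "character",
        theta        = "numeric",
        scales       = "list",
        masks        = "list"
    )
)

setValidity("ColocClassMap", function(object) {
    C <- length(object@channelNames)
    msg <- character(0)
    if (C < 1L || C > 16L)
        msg <- c(msg, "between 1 and 16 channels are supported")
    if (length(object@theta) != C || length(object@scales) != C ||
        length(object@masks) != C)
        msg <- c(msg, "theta, scales and masks must have one entry per channel")
    if (any(object@classMap < 0L) || any(object@classMap > 2^C - 1L))
        msg <- c(msg, sprintf("class labels must lie in [0, %d]", 2^C - 1L))
    if (length(msg)) msg else TRUE
})
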