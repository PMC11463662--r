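# Applications of the multi-scale filter: multi-channel co-localization
# class maps, pre-segmentation denoising, and the display-only gamma
# transform.

#' Multi-channel co-localization class map
#'
#' Runs the cumulative multi-scale filter independently on each channel of
#' a registered multiplexed fluorescence stack and combines the resulting
#' binary foreground masks into a single class map: the label of a pixel
#' is \eqn{\sum_c f_c 2^{c-1}} where \eqn{f_c} is its foreground
#' membership in channel c (channel 1 is the least significant bit), so C
#' channels yield \eqn{2^C} co-localization classes. Channels are assumed
#' to be registered already; a shape mismatch is an error.
#'
#' @param channels a list of non-negative numeric matrices, or a 3-D array
#'   (rows x columns x channels). 1 to 16 channels.
#' @param theta per-channel suppression thresholds (recycled if scalar).
#'   For nuclear, nuclear-membrane and cell-membrane markers, thresholds
#'   around 0.5, 0.95 and 0.6 respectively work well.
#' @param scales a single integer vector of averaging scales shared by all
#'   channels, or a list with one scale vector per channel.
#' @param channelNames optional channel names; defaults to names of
#'   `channels` or `ch1`, `ch2`, ...
#' @return a [ColocClassMap-class].
#' @examples
#' a <- matrix(0, 32, 32); a[8:14, 8:14] <- 1
#' b <- matrix(0, 32, 32); b[11:20, 11:20] <- 1
#' cm <- colocalize(list(nuc = a, mem = b), theta = 0.5, scales = c(2, 5))
#' classAreaTable(cm)
#' @export
colocalize <- function(channels, theta = 0.5, scales,
                       channelNames = NULL) {
    if (is.array(channels) && length(dim(channels)) == 3L)
        channels <- lapply(seq_len(dim(channels)[3L]),
                           function(i) channels[, , i])
    if (!is.list(channels) || length(channels) < 1L)
        stop("'channels' must be a non-empty list of matrices or a 3-D array",
             call. = FALSE)
    C <- length(channels)
    if (C > 16L)
        stop("at most 16 channels are supported", call. = FALSE)
    dims <- dim(channels[[1L]])
    for (ch in channels)
        if (!identical(dim(ch), dims))
            stop("all channels must share the same dimensions ",
                 "(register the images first)", call. = FALSE)
    if (is.null(channelNames))
        channelNames <- if (!is.null(names(channels)) &&
                            all(nzchar(names(channels)))) names(channels)
                        else paste0("ch", seq_len(C))
    theta <- rep_len(as.numeric(theta), C)
    if (!is.list(scales)) scales <- rep(list(scales), C)
    if (length(scales) != C)
        stop("'scales' must be one vector or one vector per channel",
             call. = FALSE)
    masks <- vector("list", C)
    cmap <- matrix(0L, dims[1L], dims[2L])
    for (c in seq_len(C)) {
        res <- cumulativeLMSF(channels[[c]], scales[[c]], theta[c])
        masks[[c]] <- backgroundMask(res)
        cmap <- cmap + (1L - masks[[c]]) * as.integer(2^(c - 1L))
    }
    names(masks) <- channelNames
    new("ColocClassMap", classMap = cmap, channelNames = channelNames,
        theta = theta, scales = lapply(scales, as.integer), masks = masks)
}

#' @rdname ColocClassMap-class
#' @export
setMethod("classMap", "ColocClassMap", function(x) x@classMap)

#' @rdname ColocClassMap-class
#' @export
setMethod("channelNames", "ColocClassMap", function(x) x@channelNames)

#' @rdname channelMasks
#' @export
setMethod("channelMasks", "ColocClassMap", function(x) {
    C <- length(x@channelNames)
    out <- lapply(seq_len(C), function(c)
        matrix(1L - (x@classMap %/% as.integer(2^(c - 1L))) %% 2L,
               nrow(x@classMap), ncol(x@classMap)))
    names(out) <- x@channelNames
    out
})

.areaTable <- function(labels, channelNames = NULL) {
    tab <- table(labels)
    lab <- as.integer(names(tab))
    n <- as.integer(tab)
    combo <- if (is.null(channelNames)) NA_character_ else
        vapply(lab, function(l) {
            on <- channelNames[bitwAnd(l, 2^(seq_along(channelNames) - 1)) > 0]
            if (length(on)) paste(on, collapse = "+") else "none"
        }, character(1))
    data.frame(label = lab, channels = combo, count = n,
               fraction = n / sum(n))
}

#' @rdname classAreaTable
#' @return a data.frame with one row per distinct class label: `label`,
#'   `channels` (names of the foreground channels encoded by the label),
#'   `count` (pixels) and `fraction` (of the image); counts sum to the
#'   image area and fractions to 1.
#' @export
setMethod("classAreaTable", "ColocClassMap", function(x)
    .areaTable(x@classMap, x@channelNames))

#' @rdname classAreaTable
#' @export
setMethod("classAreaTable", "matrix", function(x)
    .areaTable(x))

setMethod("show", "ColocClassMap", function(object) {
    d <- dim(object@classMap)
    C <- length(object@channelNames)
    cat(sprintf("ColocClassMap: %d x %d, %d channels (%s), %d/%d classes present\n",
                d[1L], d[2L], C,
                paste(object@channelNames, collapse = ", "),
                length(unique(as.vector(object@classMap))), 2^C))
    invisible(NULL)
})

#' Background-suppression denoising for downstream segmentation
#'
#' Convenience wrapper returning the image output of [cumulativeLMSF()]:
#' background pixels are set to zero and foreground pixels are untouched
#' (integer inputs stay bit-identical), which makes a clean input for
#' instance-segmentation models. A scale family such as \{5, 10, 20, 40\}
#' with theta = 0.5 works well for densely packed nuclei.
#'
#' @inheritParams cumulativeLMSF
#' @return the denoised image, same type and dimensions as the input.
#' @export
denoiseImage <- function(image, scales, theta = 0.5) {
    filteredImage(cumulativeLMSF(image, scales, theta))
}

#' Gamma transform for display
#'
#' Normalizes an image to [0, 1] by its maximum and raises it to the
#' power `gamma`; gamma below 1 (for example 0.5) reveals dim structure.
#' Normalization is by the image maximum, not the storage-type maximum, so
#' integer and floating images behave identically. An all-zero image is
#' returned unchanged. Display-only: never feed the result back into the
#' filter.
#'
#' @param image non-negative numeric matrix.
#' @param gamma positive exponent.
#' @return numeric matrix in [0, 1].
#' @export
gammaDisplay <- function(image, gamma = 0.5) {
    .checkImage(image)
    .checkNonNegative(image)
    .checkScalar(gamma, "gamma")
    if (gamma <= 0)
        stop("'gamma' must be positive", call. = FALSE)
    mx <- max(image)
    if (mx <= 0) return(matrix(0, nrow(image), ncol(image)))
    (image / mx)^gamma
}
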