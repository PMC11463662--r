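# Core LMSF mathematics: adaptive local means, single-scale and cumulative
# multi-scale suppression, admissible-scale bound and scale-selection
# heuristic.

.checkImage <- function(image, arg = "image") {
    if (!is.matrix(image) || !is.numeric(image))
        stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
    if (nrow(image) < 2L || ncol(image) < 2L)
        stop(sprintf("'%s' must be at least 2 x 2", arg), call. = FALSE)
    if (any(!is.finite(image)))
        stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
    invisible(image)
}

.checkNonNegative <- function(x, arg = "image") {
    if (any(x < 0))
        stop(sprintf("'%s' contains negative intensities; LMSF assumes non-negative fluorescence values",
                     arg), call. = FALSE)
    invisible(x)
}

.checkScalar <- function(x, arg) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", arg),
             call. = FALSE)
    invisible(x)
}

.checkHalfWindow <- function(n, nmax = NULL) {
    .checkScalar(n, "n")
    if (n < 1 || n != round(n))
        stop("'n' must be a positive integer", call. = FALSE)
    n <- as.integer(n)
    if (!is.null(nmax) && n > nmax)
        stop(sprintf("'n' = %d exceeds the admissible bound nMax = %d",
                     n, nmax), call. = FALSE)
    n
}

.checkTheta <- function(theta) {
    .checkScalar(theta, "theta")
    if (theta <= 0)
        stop("'theta' must be positive", call. = FALSE)
    theta
}

# Scale sets are deduplicated and sorted; values above nmax are an error,
# not silently clamped, so runs stay reproducible.
.checkScales <- function(scales, nmax) {
    if (length(scales) < 1L)
        stop("'scales' must contain at least one half-window size",
             call. = FALSE)
    if (!is.numeric(scales) || any(!is.finite(scales)) ||
        any(scales != round(scales)) || any(scales < 1))
        stop("'scales' must be positive integers", call. = FALSE)
    scales <- sort(unique(as.integer(scales)))
    if (scales[length(scales)] > nmax)
        stop(sprintf("largest scale %d exceeds nMax = %d for this image",
                     scales[length(scales)], nmax), call. = FALSE)
    scales
}

#' Largest admissible averaging half-window
#'
#' The half-window size \eqn{n} of the square \eqn{(2n+1)\times(2n+1)}
#' averaging neighbourhood is bounded above by
#' \eqn{n_{max} = \lfloor \min(K, M)/2 \rfloor - 1} for a \eqn{K \times M}
#' image, so that the window never spans the full image extent.
#'
#' @param K number of image rows, or a matrix (in which case `M` is taken
#'   from its dimensions).
#' @param M number of image columns.
#' @return a positive integer, the largest admissible half-window.
#' @examples
#' nMax(200, 200)   # 99
#' nMax(1000, 1000) # 499
#' @export
nMax <- function(K, M) {
    if (is.matrix(K) && missing(M)) {
        M <- ncol(K)
        K <- nrow(K)
    }
    .checkScalar(K, "K"); .checkScalar(M, "M")
    if (K != round(K) || M != round(M) || K < 4 || M < 4)
        stop("image dimensions must be integers >= 4 for any valid ",
             "half-window", call. = FALSE)
    as.integer(min(K, M) %/% 2L - 1L)
}

# admissible half-window bound for an image; 2-3 pixel-wide images have no
# nMax in the strict sense but still admit n = 1 through the adaptive
# clipped window
.boundN <- function(image) {
    if (min(dim(image)) >= 4L) nMax(image) else 1L
}

#' Adaptive local mean of a 1-D signal
#'
#' Each sample is replaced by the mean of the samples inside a window of
#' half-length `n` centred on it. Near the sequence ends the window is
#' clipped to the available samples and the sum is divided by their count
#' (n+1 values at an end point, n+2 at the next, and so on): no padding is
#' ever applied, which avoids edge artefacts.
#'
#' @param signal numeric vector of samples (any finite reals; the
#'   suppression filter itself additionally requires non-negative values).
#' @param n positive integer half-window.
#' @return numeric vector of local means, same length as `signal`.
#' @examples
#' localMean1d(c(1, 2, 3), 1) # 1.5 2.0 2.5
#' @export
localMean1d <- function(signal, n) {
    if (!is.numeric(signal) || length(signal) < 1L)
        stop("'signal' must be a non-empty numeric vector", call. = FALSE)
    if (any(!is.finite(signal)))
        stop("'signal' contains non-finite values", call. = FALSE)
    n <- .checkHalfWindow(n)
    K <- length(signal)
    # centring on the global mean keeps the running sums small, so a
    # constant signal yields its exact value back
    mu <- mean(signal)
    cs <- c(0, cumsum(as.double(signal) - mu))
    k <- seq_len(K)
    lo <- pmax(k - n, 1L)
    hi <- pmin(k + n, K)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L) + mu
}

#' 1-D local mean suppression filter
#'
#' Replaces a sample by zero when the ratio of its value to the adaptive
#' local mean ([localMean1d()]) is strictly below `theta`; all other
#' samples are returned exactly unchanged. A zero local mean can only
#' occur when every sample in the window is zero (non-negative input), so
#' such samples are labelled background directly.
#'
#' @param signal non-negative numeric vector.
#' @param n positive integer half-window.
#' @param theta positive suppression threshold; the recommended range is
#'   0.5 to 1, with 0.5 a good default.
#' @return a list with elements `response` (the filtered signal) and
#'   `background` (logical vector flagging the zeroed samples).
#' @examples
#' lmsf1d(c(10, 1, 10), n = 1, theta = 0.5)$response # 10 0 10
#' @export
lmsf1d <- function(signal, n, theta = 0.5) {
    theta <- .checkTheta(theta)
    mbar <- localMean1d(signal, n)
    .checkNonNegative(signal, "signal")
    bg <- (mbar <= 0) | (signal < theta * mbar)
    out <- signal
    out[bg] <- if (is.integer(signal)) 0L else 0
    list(response = out, background = bg)
}

# Summed-area table of a centred image, with a zero guard row/column so
# window sums are pure corner differences.
.sat <- function(xc) {
    K <- nrow(xc); M <- ncol(xc)
    S <- matrix(0, K + 1L, M + 1L)
    cs <- apply(xc, 2L, cumsum)
    if (K == 1L) cs <- matrix(cs, 1L, M)
    S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
    S
}

.satMean <- function(S, mu, K, M, n) {
    k <- seq_len(K); m <- seq_len(M)
    r1 <- pmax(k - n, 1L); r2 <- pmin(k + n, K)
    c1 <- pmax(m - n, 1L); c2 <- pmin(m + n, M)
    sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] -
            S[r1,      c2 + 1L, drop = FALSE] -
            S[r2 + 1L, c1,      drop = FALSE] +
            S[r1,      c1,      drop = FALSE]
    counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
    sums / counts + mu
}

#' Adaptive local mean of an image
#'
#' The mean intensity over the \eqn{(2n+1)\times(2n+1)} square window
#' centred on each pixel, restricted to the intersection of the window
#' with the image domain: near the borders the sum is divided by the count
#' of available pixels instead of padding. Computed with a summed-area
#' table, so the per-pixel cost is independent of `n`.
#'
#' @param image numeric matrix (K rows, M columns), finite values.
#' @param n positive integer half-window, at most [nMax()] of the image.
#' @return numeric matrix of local means, same dimensions as `image`.
#' @export
localMean2d <- function(image, n) {
    .checkImage(image)
    n <- .checkHalfWindow(n, .boundN(image))
    mu <- mean(image)
    S <- .sat(matrix(as.double(image), nrow(image), ncol(image)) - mu)
    .satMean(S, mu, nrow(image), ncol(image), n)
}

.suppress <- function(image, mbar, theta) {
    bg <- (mbar <= 0) | (image < theta * mbar)
    out <- image
    out[bg] <- if (is.integer(image)) 0L else 0
    mask <- matrix(0L, nrow(image), ncol(image))
    mask[bg] <- 1L
    list(image = out, mask = mask)
}

#' Single-scale local mean suppression filter of an image
#'
#' Zeroes every pixel whose intensity divided by the adaptive local mean
#' over the \eqn{(2n+1)\times(2n+1)} neighbourhood is strictly below
#' `theta`; all other pixels keep their exact input value (integer inputs
#' stay bit-identical). A zero local mean implies an all-zero window, so
#' those pixels are background by definition.
#'
#' @inheritParams localMean2d
#' @param theta positive suppression threshold (default 0.5; recommended
#'   range 0.5 to 1, up to about 1.1 for very fuzzy foregrounds).
#' @return an [LMSFResult-class] holding the filtered image and the
#'   background mask.
#' @examples
#' img <- matrix(0, 5, 5); img[3, 3] <- 100
#' res <- lmsf2d(img, n = 1, theta = 0.5)
#' sum(backgroundMask(res)) # 24: only the bright centre survives
#' @export
lmsf2d <- function(image, n, theta = 0.5) {
    theta <- .checkTheta(theta)
    .checkImage(image)
    .checkNonNegative(image)
    n <- .checkHalfWindow(n, .boundN(image))
    mu <- mean(image)
    S <- .sat(matrix(as.double(image), nrow(image), ncol(image)) - mu)
    sup <- .suppress(image, .satMean(S, mu, nrow(image), ncol(image), n),
                     theta)
    new("LMSFResult", filteredImage = sup$image, backgroundMask = sup$mask,
        theta = theta, scales = n)
}

#' Cumulative multi-scale LMSF background identification
#'
#' Applies the single-scale filter to the original image once per scale in
#' `scales` and combines the responses: a pixel belongs to the cumulative
#' background when any scale labels it background (equivalently, the
#' Boolean product of the per-scale foreground masks). Small scales
#' capture narrow gaps between crowded nuclei; large scales capture wide,
#' gradually varying background. The output image is the original with the
#' cumulative background zeroed.
#'
#' @inheritParams lmsf2d
#' @param scales vector of positive integer half-window sizes; duplicates
#'   are dropped, values above [nMax()] are an error.
#' @return an [LMSFResult-class].
#' @examples
#' scn <- simNucleiImage(scenePreset("large-foreground"))
#' res <- cumulativeLMSF(sceneImage(scn), scales = c(5, 10, 20, 40))
#' mean(backgroundMask(res)) # fraction of the image labelled background
#' @export
cumulativeLMSF <- function(image, scales, theta = 0.5) {
    theta <- .checkTheta(theta)
    .checkImage(image)
    .checkNonNegative(image)
    scales <- .checkScales(scales, .boundN(image))
    K <- nrow(image); M <- ncol(image)
    mu <- mean(image)
    S <- .sat(matrix(as.double(image), K, M) - mu)
    bg <- matrix(FALSE, K, M)
    for (n in scales) {
        mbar <- .satMean(S, mu, K, M, n)
        bg <- bg | (mbar <= 0) | (image < theta * mbar)
    }
    out <- image
    out[bg] <- if (is.integer(image)) 0L else 0
    mask <- matrix(0L, K, M)
    mask[bg] <- 1L
    new("LMSFResult", filteredImage = out, backgroundMask = mask,
        theta = theta, scales = scales)
}

#' Rule-of-thumb averaging scale selection
#'
#' For images whose background forms narrow gaps between foreground
#' objects, set the largest scale to half the maximal gap width and add
#' successive halvings down to `minScale`. For images with a large,
#' slowly varying background additionally include the upper bound
#' [nMax()] so long-range variation is captured.
#'
#' @param maxGapWidth approximate maximal width, in pixels, of the narrow
#'   background gaps (a rough estimate suffices).
#' @param minScale smallest scale to keep (default 5).
#' @param largeBackground set `TRUE` when the image also has extended
#'   background regions; appends `nMax(dim)` to the halving family.
#' @param dim image dimensions (rows, columns); required when
#'   `largeBackground = TRUE` and used to validate the scales otherwise,
#'   if supplied.
#' @return increasing integer vector of scales.
#' @examples
#' selectScales(80, minScale = 5)                     # 5 10 20 40
#' selectScales(80, 5, TRUE, dim = c(1000, 1000))     # 5 10 20 40 499
#' @export
selectScales <- function(maxGapWidth, minScale = 5L, largeBackground = FALSE,
                         dim = NULL) {
    .checkScalar(maxGapWidth, "maxGapWidth")
    .checkScalar(minScale, "minScale")
    if (maxGapWidth < 1 || maxGapWidth != round(maxGapWidth) ||
        minScale < 1 || minScale != round(minScale))
        stop("'maxGapWidth' and 'minScale' must be positive integers",
             call. = FALSE)
    if (!largeBackground && maxGapWidth < 2 * minScale)
        stop("'maxGapWidth' must be at least twice 'minScale'",
             call. = FALSE)
    fam <- integer(0)
    v <- as.integer(maxGapWidth) %/% 2L
    while (v >= minScale) {
        fam <- c(fam, v)
        v <- v %/% 2L
    }
    if (largeBackground) {
        if (is.null(dim))
            stop("'dim' is required when largeBackground = TRUE",
                 call. = FALSE)
        nm <- nMax(dim[1L], dim[2L])
        fam <- c(fam[fam <= nm], nm)
    } else if (!is.null(dim)) {
        nm <- nMax(dim[1L], dim[2L])
        if (length(fam) && max(fam) > nm)
            stop(sprintf("largest selected scale %d exceeds nMax = %d",
                         max(fam), nm), call. = FALSE)
    }
    fam <- sort(unique(fam))
    if (!length(fam))
        stop("no admissible scales for these inputs", call. = FALSE)
    fam
}

#' Pixelwise F1 score of a predicted background mask
#'
#' Treats background (mask value 1) as the positive class and computes the
#' harmonic mean of precision and recall against a ground-truth mask.
#'
#' @param predicted,truth binary matrices of identical dimensions
#'   (1 = background).
#' @return a single numeric F1 score in [0, 1].
#' @export
backgroundF1 <- function(predicted, truth) {
    if (!identical(dim(predicted), dim(truth)))
        stop("mask dimensions differ", call. = FALSE)
    p <- predicted == 1L
    t <- truth == 1L
    tp <- sum(p & t)
    if (tp == 0L) return(0)
    2 * tp / (2 * tp + sum(p & !t) + sum(!p & t))
}

#' @rdname LMSFResult-class
#' @export
setMethod("filteredImage", "LMSFResult", function(x) x@filteredImage)

#' @rdname LMSFResult-class
#' @export
setMethod("backgroundMask", "LMSFResult", function(x) x@backgroundMask)

#' @rdname LMSFResult-class
#' @export
setMethod("filterTheta", "LMSFResult", function(x) x@theta)

#' @rdname LMSFResult-class
#' @export
setMethod("filterScales", "LMSFResult", function(x) x@scales)

setMethod("show", "LMSFResult", function(object) {
    d <- dim(object@filteredImage)
    cat(sprintf("LMSFResult: %d x %d image\n", d[1L], d[2L]))
    cat(sprintf("  theta:  %g\n", object@theta))
    cat(sprintf("  scales: {%s}\n", paste(object@scales, collapse = ", ")))
    cat(sprintf("  background: %d px (%.1f%%)\n",
                sum(object@backgroundMask),
                100 * mean(object@backgroundMask)))
    invisible(NULL)
})
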