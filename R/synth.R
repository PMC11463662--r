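# Deterministic synthetic fixtures: 1-D test signals and fluorescence-like
# nuclei scenes with known ground-truth background masks.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. NULL seed leaves the RNG untouched.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = globalenv()),
                add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(expr)
}

#' Sampled sine-squared test signal
#'
#' Uniform samples of \eqn{\sin^2(t)}, the classic varying-intensity
#' signal used to motivate the suppression threshold: when the averaging
#' half-window spans an integer number of half-periods (T = pi/2, pi, ...)
#' the local mean sits at 0.5, so theta = 0.5 suppresses exactly the
#' samples below 0.25 and theta = 1 those below 0.5.
#'
#' The signal has period pi, so the sampling step is
#' `pi / samplesPerPeriod` and a half-window of T time units corresponds
#' to `n = round(T * samplesPerPeriod / pi)` samples.
#'
#' @param numPeriods positive number of signal periods to cover.
#' @param samplesPerPeriod samples per period (at least 8).
#' @return numeric vector of `round(numPeriods * samplesPerPeriod)`
#'   samples starting at t = 0.
#' @examples
#' s <- simSineSignal(2, 1000)
#' range(s)  # 0 .. ~1
#' mean(s)   # ~0.5
#' @export
simSineSignal <- function(numPeriods, samplesPerPeriod) {
    .checkScalar(numPeriods, "numPeriods")
    .checkScalar(samplesPerPeriod, "samplesPerPeriod")
    if (numPeriods <= 0)
        stop("'numPeriods' must be positive", call. = FALSE)
    if (samplesPerPeriod < 8 || samplesPerPeriod != round(samplesPerPeriod))
        stop("'samplesPerPeriod' must be an integer >= 8", call. = FALSE)
    K <- round(numPeriods * samplesPerPeriod)
    dt <- pi / samplesPerPeriod
    sin((seq_len(K) - 1) * dt)^2
}

#' Piecewise-constant test signal with optional noise
#'
#' A step signal built from (value, length) segments, mimicking
#' alternating low (background) and high (foreground) signal levels with
#' narrow and wide gaps, plus optional additive Gaussian noise truncated
#' at zero. Fully deterministic for a given seed.
#'
#' @param levels a two-column matrix or data.frame, first column segment
#'   value (non-negative), second column segment length (positive
#'   integer); or a list of length-2 vectors.
#' @param noiseSd standard deviation of the additive noise (0 = none).
#' @param seed integer seed used when `noiseSd > 0`; NULL draws from the
#'   current RNG state.
#' @return numeric vector of concatenated segments.
#' @examples
#' simStepSignal(rbind(c(0, 10), c(1, 10)))
#' @export
simStepSignal <- function(levels, noiseSd = 0, seed = NULL) {
    if (is.list(levels) && !is.data.frame(levels))
        levels <- do.call(rbind, levels)
    levels <- as.matrix(levels)
    if (ncol(levels) != 2L)
        stop("'levels' must have two columns: value, length", call. = FALSE)
    vals <- as.double(levels[, 1L])
    lens <- levels[, 2L]
    if (any(vals < 0))
        stop("segment values must be non-negative", call. = FALSE)
    if (any(lens < 1) || any(lens != round(lens)))
        stop("segment lengths must be positive integers", call. = FALSE)
    .checkScalar(noiseSd, "noiseSd")
    if (noiseSd < 0)
        stop("'noiseSd' must be non-negative", call. = FALSE)
    x <- rep(vals, as.integer(lens))
    if (noiseSd > 0)
        x <- .withSeed(seed, pmax(x + stats::rnorm(length(x), 0, noiseSd), 0))
    x
}

#' Construct a synthetic nuclei-scene specification
#'
#' See [NucleiSceneSpec-class] for the meaning of each parameter. The
#' defaults describe a moderately sparse field of bright and dim nuclei on
#' a faint, slightly graded background — the common situation the
#' multi-scale filter is designed for.
#'
#' @param dim image dimensions (rows, columns).
#' @param nBlobs number of nuclei.
#' @param radiusRange nominal blob radius range, pixels.
#' @param peakRange peak intensity range of bright nuclei.
#' @param dimFraction fraction of nuclei drawn dim.
#' @param dimRatio dim/bright intensity ratio, in (0, 1).
#' @param backgroundOffset constant background level.
#' @param gradientAmplitude amplitude of the smooth diagonal gradient.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param clustering 0 = uniform placement, 1 = tight clusters.
#' @param seed integer seed; fully determines the scene.
#' @param theta recommended suppression threshold for this scene.
#' @param scales recommended averaging scales (may be empty).
#' @param name label for the spec.
#' @return a [NucleiSceneSpec-class].
#' @export
NucleiSceneSpec <- function(dim = c(192L, 192L), nBlobs = 40L,
                            radiusRange = c(6, 10), peakRange = c(0.6, 1),
                            dimFraction = 0.3, dimRatio = 0.15,
                            backgroundOffset = 0.01,
                            gradientAmplitude = 0.01, noiseSd = 0.003,
                            clustering = 0, seed = 1L, theta = 0.5,
                            scales = integer(0), name = "custom") {
    new("NucleiSceneSpec",
        dim = as.integer(dim), nBlobs = as.integer(nBlobs),
        radiusRange = as.numeric(radiusRange),
        peakRange = as.numeric(peakRange),
        dimFraction = as.numeric(dimFraction),
        dimRatio = as.numeric(dimRatio),
        backgroundOffset = as.numeric(backgroundOffset),
        gradientAmplitude = as.numeric(gradientAmplitude),
        noiseSd = as.numeric(noiseSd),
        clustering = as.numeric(clustering),
        seed = as.integer(seed), theta = as.numeric(theta),
        scales = as.integer(scales), name = as.character(name))
}

#' Frozen scene presets for the three practical imaging regimes
#'
#' Named parameter sets emulating the regimes the multi-scale filter is
#' used in: `"large-background"` (sparse nuclei on an extended, faint,
#' noisy background; scales include the upper bound [nMax()]),
#' `"large-foreground"` (dense, clustered nuclei separated by narrow
#' gaps; a narrow halved scale family), and `"fuzzy-foreground"` (dim,
#' low-contrast nuclei barely above the background; a raised threshold).
#' Each preset carries its recommended `theta` and scale set, retrievable
#' with `spec@theta` and `spec@scales`.
#'
#' @param name one of `"large-background"`, `"large-foreground"`,
#'   `"fuzzy-foreground"`.
#' @param seed optional seed overriding the preset's frozen default.
#' @return a [NucleiSceneSpec-class].
#' @examples
#' scenePreset("large-background")
#' @export
scenePreset <- function(name = c("large-background", "large-foreground",
                                 "fuzzy-foreground"), seed = NULL) {
    name <- match.arg(name)
    spec <- switch(name,
        "large-background" = NucleiSceneSpec(
            dim = c(192L, 192L), nBlobs = 25L, radiusRange = c(6, 10),
            peakRange = c(0.5, 1), dimFraction = 0.3, dimRatio = 0.15,
            backgroundOffset = 0.01, gradientAmplitude = 0.005,
            noiseSd = 0.003, clustering = 0.3, seed = 101L, theta = 0.5,
            scales = selectScales(80, 5, largeBackground = TRUE,
                                  dim = c(192L, 192L)),
            name = name),
        "large-foreground" = NucleiSceneSpec(
            dim = c(192L, 192L), nBlobs = 40L, radiusRange = c(10, 16),
            peakRange = c(0.5, 1), dimFraction = 0.25, dimRatio = 0.2,
            backgroundOffset = 0.01, gradientAmplitude = 0.005,
            noiseSd = 0.003, clustering = 0.3, seed = 202L, theta = 0.5,
            scales = selectScales(80, 5), name = name),
        "fuzzy-foreground" = NucleiSceneSpec(
            dim = c(192L, 192L), nBlobs = 35L, radiusRange = c(7, 12),
            peakRange = c(0.08, 0.16), dimFraction = 0.3, dimRatio = 0.4,
            backgroundOffset = 0.02, gradientAmplitude = 0.01,
            noiseSd = 0.004, clustering = 0.3, seed = 303L, theta = 0.9,
            scales = selectScales(80, 5, largeBackground = TRUE,
                                  dim = c(192L, 192L)),
            name = name))
    if (!is.null(seed)) spec@seed <- as.integer(seed)
    spec
}

#' Simulate a fluorescence-nuclei scene with ground truth
#'
#' Builds `background offset + smooth gradient + sum of Gaussian-profile
#' blobs + truncated Gaussian noise`, clipped to non-negative values. A
#' blob of nominal radius r has Gaussian sigma = r/2; its ground-truth
#' support is the disk where its own profile exceeds 10 percent of its
#' peak (radius `sigma * sqrt(2 log 10)`, about 1.07 r), and the true
#' background mask is the complement of the union of supports. The seed
#' in the spec fully determines the output.
#'
#' @param spec a [NucleiSceneSpec-class].
#' @return a [NucleiScene-class].
#' @examples
#' scn <- simNucleiImage(scenePreset("large-background"))
#' mean(trueBackground(scn))
#' @export
simNucleiImage <- function(spec) {
    stopifnot(is(spec, "NucleiSceneSpec"))
    validObject(spec)
    K <- spec@dim[1L]; M <- spec@dim[2L]
    rmax <- spec@radiusRange[2L]
    if (spec@nBlobs > 0L && 2 * rmax + 4 > min(K, M))
        stop("blobs of the requested radius cannot fit the image",
             call. = FALSE)
    .withSeed(spec@seed, {
        nb <- spec@nBlobs
        fg <- matrix(FALSE, K, M)
        blobSum <- matrix(0, K, M)
        blobs <- data.frame(row = numeric(0), col = numeric(0),
                            radius = numeric(0), sigma = numeric(0),
                            peak = numeric(0), dim = logical(0))
        if (nb > 0L) {
            radius <- stats::runif(nb, spec@radiusRange[1L], rmax)
            peak <- stats::runif(nb, spec@peakRange[1L], spec@peakRange[2L])
            isDim <- stats::runif(nb) < spec@dimFraction
            peak[isDim] <- peak[isDim] * spec@dimRatio
            margin <- radius + 2
            if (spec@clustering > 0) {
                nc <- max(1L, ceiling(nb / 8L))
                ccr <- stats::runif(nc, rmax + 2, K - rmax - 1)
                ccc <- stats::runif(nc, rmax + 2, M - rmax - 1)
                pick <- sample.int(nc, nb, replace = TRUE)
                spread <- 2 * mean(radius) +
                    (1 - spec@clustering) * min(K, M) / 3
                rowc <- ccr[pick] + stats::rnorm(nb, 0, spread)
                colc <- ccc[pick] + stats::rnorm(nb, 0, spread)
            } else {
                rowc <- stats::runif(nb, margin, K - margin + 1)
                colc <- stats::runif(nb, margin, M - margin + 1)
            }
            rowc <- pmin(pmax(rowc, margin), K - margin + 1)
            colc <- pmin(pmax(colc, margin), M - margin + 1)
            sigma <- radius / 2
            rsup <- sigma * sqrt(2 * log(10))  # 10% of peak
            for (i in seq_len(nb)) {
                ext <- ceiling(3.5 * sigma[i])
                r1 <- max(1L, floor(rowc[i] - ext))
                r2 <- min(K, ceiling(rowc[i] + ext))
                c1 <- max(1L, floor(colc[i] - ext))
                c2 <- min(M, ceiling(colc[i] + ext))
                rr <- r1:r2; cc <- c1:c2
                d2 <- outer((rr - rowc[i])^2, (cc - colc[i])^2, "+")
                blobSum[rr, cc] <- blobSum[rr, cc] +
                    peak[i] * exp(-d2 / (2 * sigma[i]^2))
                fg[rr, cc] <- fg[rr, cc] | (d2 <= rsup[i]^2)
            }
            blobs <- data.frame(row = rowc, col = colc, radius = radius,
                                sigma = sigma, peak = peak, dim = isDim)
        }
        grad <- spec@gradientAmplitude *
            outer(seq(0, 1, length.out = K), seq(0, 1, length.out = M),
                  function(a, b) (a + b) / 2)
        img <- spec@backgroundOffset + grad + blobSum
        if (spec@noiseSd > 0)
            img <- img + stats::rnorm(K * M, 0, spec@noiseSd)
        img <- pmax(img, 0)
        bg <- matrix(1L, K, M)
        bg[fg] <- 0L
        new("NucleiScene", image = matrix(img, K, M), background = bg,
            blobs = blobs, spec = spec)
    })
}

#' @rdname NucleiScene-class
#' @export
setMethod("sceneImage", "NucleiScene", function(x) x@image)

#' @rdname NucleiScene-class
#' @export
setMethod("trueBackground", "NucleiScene", function(x) x@background)

#' @rdname NucleiScene-class
#' @export
setMethod("sceneBlobs", "NucleiScene", function(x) x@blobs)

#' @rdname NucleiScene-class
#' @export
setMethod("sceneSpec", "NucleiScene", function(x) x@spec)

setMethod("show", "NucleiSceneSpec", function(object) {
    cat(sprintf("NucleiSceneSpec '%s': %d x %d, %d blobs, seed %d\n",
                object@name, object@dim[1L], object@dim[2L],
                object@nBlobs, object@seed))
    cat(sprintf("  radii %g-%g px, peaks %g-%g, %.0f%% dim (ratio %g)\n",
                object@radiusRange[1L], object@radiusRange[2L],
                object@peakRange[1L], object@peakRange[2L],
                100 * object@dimFraction, object@dimRatio))
    cat(sprintf("  offset %g, gradient %g, noise sd %g, clustering %g\n",
                object@backgroundOffset, object@gradientAmplitude,
                object@noiseSd, object@clustering))
    cat(sprintf("  recommended theta %g, scales {%s}\n", object@theta,
                paste(object@scales, collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "NucleiScene", function(object) {
    d <- dim(object@image)
    cat(sprintf("NucleiScene '%s': %d x %d, %d blobs, %.1f%% background\n",
                object@spec@name, d[1L], d[2L], nrow(object@blobs),
                100 * mean(object@background)))
    invisible(NULL)
})
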