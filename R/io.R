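# Grayscale image I/O (TIFF/PNG), run manifests and fixture export.

.isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
.isPng  <- function(path) grepl("\\.png$",  path, ignore.case = TRUE)

.pickChannel <- function(page, channel, path) {
    if (length(dim(page)) == 3L) {
        if (is.null(channel))
            stop(sprintf("'%s' has %d samples per pixel; pass 'channel' to select one",
                         path, dim(page)[3L]), call. = FALSE)
        page[, , channel]
    } else page
}

#' Read a grayscale image
#'
#' Reads a single-channel TIFF or PNG into a non-negative matrix.
#' Integer files come back as integer matrices holding the original
#' sample values (8-bit PNG pixel 7 reads as 7, not 7/255);
#' floating-point TIFFs come back as numeric matrices. Multi-sample
#' images (RGB, multi-page TIFF stacks) require an explicit `channel`
#' (page or sample index) to avoid silent conversion.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param channel page index for a multi-page TIFF, or sample index for an
#'   RGB(A) image; NULL for plain single-channel files.
#' @return a matrix with attributes `bitdepth` (bits per sample, NA for
#'   float) and `source` (the path), for faithful round-tripping.
#' @export
readGray <- function(path, channel = NULL) {
    if (!file.exists(path))
        stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
    if (.isTiff(path)) {
        raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
        dbl <- tiff::readTIFF(path, all = TRUE)
        info <- attributes(raw[[1L]])
        if (length(raw) > 1L) {
            if (is.null(channel))
                stop(sprintf("'%s' has %d pages; pass 'channel' to select one",
                             path, length(raw)), call. = FALSE)
            raw <- raw[channel]; dbl <- dbl[channel]
        }
        ri <- .pickChannel(raw[[1L]], channel, path)
        rd <- .pickChannel(dbl[[1L]], channel, path)
        bits <- info$bits.per.sample
        # integer files satisfy raw == round(scaled * (2^bits - 1));
        # float files reinterpret to unrelated (often negative) integers
        isInt <- !is.null(bits) &&
            max(abs(as.double(ri) - round(rd * (2^bits - 1)))) < 0.5
        img <- if (isInt) {
            m <- matrix(as.integer(ri), nrow(rd), ncol(rd))
            m
        } else matrix(as.double(rd), nrow(rd), ncol(rd))
        attr(img, "bitdepth") <- if (isInt) as.integer(bits) else NA_integer_
    } else if (.isPng(path)) {
        a <- png::readPNG(path, info = TRUE)
        info <- attr(a, "info")
        a <- .pickChannel(unclass(a), channel, path)
        scale <- 2^info$bit.depth - 1
        img <- matrix(as.integer(round(a * scale)), nrow(a), ncol(a))
        attr(img, "bitdepth") <- as.integer(info$bit.depth)
    } else {
        stop(sprintf("unsupported image format: '%s' (use TIFF or PNG)",
                     path), call. = FALSE)
    }
    if (any(img < 0))
        stop(sprintf("'%s' contains negative intensities", path),
             call. = FALSE)
    attr(img, "source") <- path
    img
}

#' Write a grayscale image
#'
#' Integer matrices (or any matrix with `bitdepth` given) are written as
#' 8- or 16-bit TIFF/PNG with sample values preserved exactly; other
#' numeric matrices are written as 32-bit float TIFF, rescaled by their
#' maximum when it exceeds 1 (the scale factor is returned so callers can
#' record it).
#'
#' @param image matrix of non-negative intensities.
#' @param path output `.tif`/`.tiff` or `.png` path.
#' @param bitdepth 8 or 16 for integer output; NULL picks the image's
#'   `bitdepth` attribute, else 16 for integer data, else float.
#' @return invisibly, a list with `path`, `bitdepth` (NA for float) and
#'   `scale` (divisor applied before writing; 1 unless float data
#'   exceeded 1).
#' @export
writeGray <- function(image, path, bitdepth = NULL) {
    if (!is.matrix(image) || any(image < 0) || any(!is.finite(image)))
        stop("'image' must be a finite non-negative matrix", call. = FALSE)
    if (is.null(bitdepth)) bitdepth <- attr(image, "bitdepth")
    if (is.null(bitdepth) && is.integer(image)) bitdepth <- 16L
    if (!is.null(bitdepth) && is.na(bitdepth)) bitdepth <- NULL
    scale <- 1
    if (!is.null(bitdepth)) {
        bitdepth <- as.integer(bitdepth)
        if (!bitdepth %in% c(8L, 16L))
            stop("'bitdepth' must be 8 or 16", call. = FALSE)
        mxv <- 2^bitdepth - 1
        if (max(image) > mxv)
            stop(sprintf("intensities exceed the %d-bit range", bitdepth),
                 call. = FALSE)
        norm <- matrix(as.double(image) / mxv, nrow(image), ncol(image))
        if (.isTiff(path)) {
            tiff::writeTIFF(norm, path, bits.per.sample = bitdepth)
        } else if (.isPng(path)) {
            if (bitdepth != 8L)
                stop("PNG output is written as 8-bit; use TIFF for 16-bit",
                     call. = FALSE)
            png::writePNG(norm, path)
        } else stop("unsupported output format", call. = FALSE)
        return(invisible(list(path = path, bitdepth = bitdepth,
                              scale = scale)))
    }
    if (!.isTiff(path))
        stop("floating-point images can only be written as TIFF",
             call. = FALSE)
    mx <- max(image)
    if (mx > 1) scale <- mx
    tiff::writeTIFF(matrix(as.double(image) / scale, nrow(image),
                           ncol(image)),
                    path, bits.per.sample = 32L)
    invisible(list(path = path, bitdepth = NA_integer_, scale = scale))
}

#' Write a filter result with a provenance manifest
#'
#' Writes the filtered image (`<name>_filtered.tif`, input type
#' preserved), the background mask (`<name>_background.png`, 8-bit) and a
#' JSON manifest (`<name>_manifest.json`) recording the parameters,
#' package version, mask polarity, output checksums and, when `input` is
#' given, the input file checksum. The default polarity writes foreground
#' as white (255) and background as black (0); `"bg-white"` flips the
#' written values only, never the in-memory mask.
#'
#' @param result an [LMSFResult-class].
#' @param outdir output directory (created if needed).
#' @param name basename prefix for the three files.
#' @param maskPolarity `"fg-white"` (default) or `"bg-white"`.
#' @param input optional path of the source image, checksummed into the
#'   manifest.
#' @return invisibly, named character vector of the written paths.
#' @export
writeOutputs <- function(result, outdir, name = "lmsf",
                         maskPolarity = c("fg-white", "bg-white"),
                         input = NULL) {
    stopifnot(is(result, "LMSFResult"))
    maskPolarity <- match.arg(maskPolarity)
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory '%s'", outdir),
             call. = FALSE)
    imgPath  <- file.path(outdir, paste0(name, "_filtered.tif"))
    maskPath <- file.path(outdir, paste0(name, "_background.png"))
    manPath  <- file.path(outdir, paste0(name, "_manifest.json"))
    winfo <- writeGray(filteredImage(result), imgPath)
    mask <- backgroundMask(result)
    maskOut <- if (maskPolarity == "fg-white") (1L - mask) * 255L
               else mask * 255L
    writeGray(maskOut, maskPath, bitdepth = 8L)
    manifest <- list(
        package = "LMSFilter",
        version = as.character(utils::packageVersion("LMSFilter")),
        theta = filterTheta(result),
        scales = filterScales(result),
        dim = dim(filteredImage(result)),
        maskPolarity = maskPolarity,
        imageScale = winfo$scale,
        backgroundPixels = sum(mask),
        checksums = list(
            filtered = unname(tools::md5sum(imgPath)),
            mask = unname(tools::md5sum(maskPath))
        )
    )
    if (!is.null(input))
        manifest$input <- list(path = input,
                               md5 = unname(tools::md5sum(input)))
    jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(filtered = imgPath, mask = maskPath, manifest = manPath))
}

#' Export a synthetic scene as files
#'
#' Writes the scene image as a 16-bit TIFF (quantized by its recorded
#' maximum), the ground-truth background mask as an 8-bit PNG
#' (background = 0, foreground = 255) and a JSON sidecar holding the full
#' generating specification and the quantization scale, so the fixture is
#' reproducible and reusable outside R.
#'
#' @param scene a [NucleiScene-class].
#' @param outdir output directory (created if needed).
#' @param name basename prefix; defaults to the spec's name.
#' @return invisibly, named character vector of the written paths.
#' @export
writeScene <- function(scene, outdir, name = NULL) {
    stopifnot(is(scene, "NucleiScene"))
    spec <- sceneSpec(scene)
    if (is.null(name)) name <- spec@name
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory '%s'", outdir),
             call. = FALSE)
    imgPath  <- file.path(outdir, paste0(name, ".tif"))
    maskPath <- file.path(outdir, paste0(name, "_truth.png"))
    specPath <- file.path(outdir, paste0(name, ".json"))
    img <- sceneImage(scene)
    mx <- max(img, 1e-12)
    q <- matrix(as.integer(round(img / mx * 65535)), nrow(img), ncol(img))
    writeGray(q, imgPath, bitdepth = 16L)
    writeGray((1L - trueBackground(scene)) * 255L, maskPath, bitdepth = 8L)
    sidecar <- list(
        synthetic = TRUE,
        name = spec@name,
        dim = spec@dim, nBlobs = spec@nBlobs,
        radiusRange = spec@radiusRange, peakRange = spec@peakRange,
        dimFraction = spec@dimFraction, dimRatio = spec@dimRatio,
        backgroundOffset = spec@backgroundOffset,
        gradientAmplitude = spec@gradientAmplitude,
        noiseSd = spec@noiseSd, clustering = spec@clustering,
        seed = spec@seed, theta = spec@theta, scales = spec@scales,
        quantizationMax = mx
    )
    jsonlite::write_json(sidecar, specPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(image = imgPath, mask = maskPath, spec = specPath))
}
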