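# Builds a 3-channel stack in which every foreground combination occurs:
# eight 32-column blocks, block b bright in channel c iff bit c of b is set.
comboStack <- function() {
    K <- 32L; M <- 8L * 32L
    channels <- lapply(0:2, function(c) {
        img <- matrix(0, K, M)
        for (b in 0:7)
            if (bitwAnd(b, 2^c) > 0)
                img[, (b * 32L + 1L):((b + 1L) * 32L)] <- 10
        img
    })
    names(channels) <- c("hoechst", "laminAC", "atpase")
    channels
}

test_that("all-zero channels give class 0 everywhere", {
    z <- matrix(0, 16, 16)
    cm <- colocalize(list(z, z, z), theta = 0.5, scales = c(2, 4))
    expect_true(all(classMap(cm) == 0L))
    expect_equal(nrow(classAreaTable(cm)), 1)
})

test_that("three channels with every membership combination give 8 classes", {
    channels <- comboStack()
    cm <- colocalize(channels, theta = 0.5, scales = c(2, 5))
    labs <- sort(unique(as.vector(classMap(cm))))
    expect_identical(labs, 0:7)
    # block interiors carry exactly their encoded label
    mid <- 16L
    for (b in 0:7)
        expect_identical(classMap(cm)[mid, b * 32L + 16L], b)
})

test_that("the bit encoding puts channel 1 in the least significant bit", {
    channels <- comboStack()
    cm <- colocalize(channels, theta = 0.5, scales = c(2, 5))
    # block 5 = binary 101: foreground in channels 1 and 3 only
    px <- classMap(cm)[16L, 5L * 32L + 16L]
    expect_identical(px, 5L)
})

test_that("per-channel masks are exactly recoverable from the class map", {
    channels <- comboStack()
    cm <- colocalize(channels, theta = 0.5, scales = c(2, 5))
    rec <- channelMasks(cm)
    expect_identical(rec, cm@masks)
    expect_named(rec, c("hoechst", "laminAC", "atpase"))
})

test_that("per-channel thresholds and scales are honoured", {
    channels <- comboStack()
    cm <- colocalize(channels, theta = c(0.5, 0.95, 0.6),
                     scales = list(c(2, 5), c(2, 5), c(5)))
    expect_equal(cm@theta, c(0.5, 0.95, 0.6))
    expect_identical(cm@scales[[3]], 5L)
})

test_that("channel shape mismatch is an input error", {
    expect_error(colocalize(list(matrix(0, 8, 8), matrix(0, 8, 9)),
                            scales = 2),
                 "register")
})

test_that("class area table counts every pixel exactly once", {
    m <- matrix(0L, 10, 10)
    tab <- classAreaTable(m)
    expect_identical(tab$label, 0L)
    expect_identical(tab$count, 100L)
    expect_identical(tab$fraction, 1)

    m2 <- matrix(c(rep(0L, 60), rep(5L, 40)), 10, 10)
    tab2 <- classAreaTable(m2)
    expect_identical(tab2$label, c(0L, 5L))
    expect_equal(tab2$fraction, c(0.6, 0.4))

    channels <- comboStack()
    cm <- colocalize(channels, theta = 0.5, scales = c(2, 5))
    tab3 <- classAreaTable(cm)
    expect_identical(nrow(tab3),
                     length(unique(as.vector(classMap(cm)))))
    expect_identical(sum(tab3$count), length(classMap(cm)))
    expect_lt(abs(sum(tab3$fraction) - 1), 1e-12)
})

test_that("denoising is the cumulative filter's image output", {
    img <- matrix(5, 20, 20)
    expect_identical(denoiseImage(img, c(2, 5)), img)

    scn <- simNucleiImage(scenePreset("large-foreground"))
    img <- sceneImage(scn)
    den <- denoiseImage(img, c(5, 10, 20, 40), 0.5)
    expect_identical(den,
                     filteredImage(cumulativeLMSF(img, c(5, 10, 20, 40), 0.5)))
    nz <- den != 0
    expect_true(all(img[nz] == den[nz]))   # nonzero outputs kept exactly
})

test_that("gamma display normalizes by the image maximum", {
    img <- matrix(c(0, 1, 2, 4), 2, 2)
    expect_equal(gammaDisplay(img, 1), img / 4)
    g <- gammaDisplay(img, 0.5)
    expect_equal(max(g), 1)
    expect_equal(g[2, 1], sqrt(0.25))     # 0.25 of max -> 0.5
    z <- matrix(0, 3, 3)
    expect_identical(gammaDisplay(z, 0.5), z)
    expect_error(gammaDisplay(img, 0), "positive")
})
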