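test_that("sampled sine-squared signal has the expected range, mean and length", {
    s <- simSineSignal(2, 1000)
    expect_length(s, 2000)
    expect_equal(min(s), 0)
    expect_equal(max(s), 1, tolerance = 1e-5)
    expect_equal(mean(s), 0.5, tolerance = 1e-3)
    expect_error(simSineSignal(2, 4), ">= 8")
})

test_that("step signals concatenate segments and respect the seed", {
    x <- simStepSignal(rbind(c(0, 10), c(1, 10)))
    expect_length(x, 20)
    expect_identical(x[1:10], rep(0, 10))
    expect_identical(x[11:20], rep(1, 10))
    a <- simStepSignal(list(c(0.2, 30), c(2, 15)), noiseSd = 0.05, seed = 4)
    b <- simStepSignal(list(c(0.2, 30), c(2, 15)), noiseSd = 0.05, seed = 4)
    expect_identical(a, b)
    expect_true(all(a >= 0))
    expect_error(simStepSignal(rbind(c(-1, 5))), "non-negative")
})

test_that("a blob-free scene is the constant offset with all-background truth", {
    spec <- NucleiSceneSpec(dim = c(32, 32), nBlobs = 0,
                            backgroundOffset = 0.3, gradientAmplitude = 0,
                            noiseSd = 0, seed = 1)
    scn <- simNucleiImage(spec)
    expect_identical(sceneImage(scn), matrix(0.3, 32, 32))
    expect_true(all(trueBackground(scn) == 1L))
    expect_equal(nrow(sceneBlobs(scn)), 0)
})

test_that("scenes are bit-identical under a fixed seed and differ across seeds", {
    spec <- scenePreset("large-background")
    a <- simNucleiImage(spec)
    b <- simNucleiImage(spec)
    expect_identical(sceneImage(a), sceneImage(b))
    expect_identical(trueBackground(a), trueBackground(b))
    c <- simNucleiImage(scenePreset("large-background", seed = 77))
    expect_false(identical(sceneImage(a), sceneImage(c)))
})

test_that("scene generation does not perturb the caller's RNG stream", {
    set.seed(123)
    before <- runif(1)
    set.seed(123)
    invisible(simNucleiImage(scenePreset("large-foreground")))
    expect_identical(runif(1), before)
})

test_that("generated scenes are non-negative, finite, with a binary partition", {
    for (p in c("large-background", "large-foreground", "fuzzy-foreground")) {
        scn <- simNucleiImage(scenePreset(p))
        img <- sceneImage(scn)
        expect_true(all(is.finite(img)) && all(img >= 0))
        expect_true(all(trueBackground(scn) %in% c(0L, 1L)))
        expect_identical(dim(img), dim(trueBackground(scn)))
    }
})

test_that("preset regimes order background fractions as intended", {
    lb <- mean(trueBackground(simNucleiImage(scenePreset("large-background"))))
    lf <- mean(trueBackground(simNucleiImage(scenePreset("large-foreground"))))
    expect_gt(lb, 0.75)   # extended background regime
    expect_lt(lf, 0.65)   # dense foreground regime
})

test_that("infeasible blob sizes are rejected", {
    expect_error(simNucleiImage(NucleiSceneSpec(dim = c(16, 16),
                                                radiusRange = c(10, 12))),
                 "cannot fit")
})
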