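test_that("1-D suppression zeroes only samples below theta times the mean", {
    r <- lmsf1d(c(10, 1, 10), n = 1, theta = 0.5)
    # local means are (5.5, 7, 5.5); only 1/7 falls below 0.5
    expect_equal(r$response, c(10, 0, 10))
    expect_equal(r$background, c(FALSE, TRUE, FALSE))
    expect_equal(r$response == 0, r$background)
})

test_that("the comparison is strict: ratio exactly theta survives", {
    x <- rep(4.2, 30)
    r <- lmsf1d(x, n = 3, theta = 1)
    expect_identical(r$response, x)
    expect_false(any(r$background))
})

test_that("suppression rejects negative samples", {
    expect_error(lmsf1d(c(1, -0.1, 2), 1), "negative")
    expect_error(lmsf2d(matrix(c(1, -1, 2, 3), 2, 2), 1), "negative")
})

test_that("zero samples inside all-zero windows are background", {
    x <- c(0, 0, 0, 0, 10, 10)
    r <- lmsf1d(x, n = 1, theta = 0.5)
    expect_true(all(r$background[1:3]))   # zero local mean, zero sample
    expect_true(r$background[4])          # ratio 0 < theta
    expect_false(any(r$background[5:6]))
})

test_that("sine-squared suppression cuts at theta/2 of the signal peak", {
    spp <- 2000
    s <- simSineSignal(3, spp)
    dt <- pi / spp
    n <- round((pi / 2) / dt)
    interior <- (n + 1):(length(s) - n)
    for (th in c(0.5, 1)) {
        r <- lmsf1d(s, n, th)
        cut <- th / 2
        zeroed <- interior[r$background[interior]]
        kept <- interior[!r$background[interior]]
        expect_true(all(s[zeroed] < cut + dt))
        expect_true(all(s[kept] > cut - dt))
    }
})

test_that("constant positive images pass through for theta <= 1", {
    img <- matrix(2.5, 16, 16)
    for (th in c(0.5, 1)) {
        res <- lmsf2d(img, 3, th)
        expect_identical(filteredImage(res), img)
        expect_equal(sum(backgroundMask(res)), 0)
    }
})

test_that("an isolated bright pixel survives while its zero surround does not", {
    img <- matrix(0, 5, 5); img[3, 3] <- 100
    res <- lmsf2d(img, 1, 0.5)
    expect_equal(filteredImage(res)[3, 3], 100)
    expect_equal(sum(backgroundMask(res)), 24)
    expect_equal(backgroundMask(res)[3, 3], 0L)
})

test_that("filter outputs preserve values, type and shape", {
    set.seed(5)
    for (rep in 1:10) {
        img <- randImage(sample(6:24, 1), sample(6:24, 1))
        n <- sample(seq_len(nMax(img)), 1)
        res <- lmsf2d(img, n, 0.7)
        out <- filteredImage(res)
        expect_identical(dim(out), dim(img))
        keep <- backgroundMask(res) == 0L
        expect_identical(out[keep], img[keep])
        expect_true(all(out[!keep] == 0))
    }
    # integer images stay integer with kept pixels bit-identical
    imgI <- matrix(sample.int(65535L, 400, replace = TRUE), 20, 20)
    resI <- lmsf2d(imgI, 2, 0.5)
    expect_true(is.integer(filteredImage(resI)))
    keep <- backgroundMask(resI) == 0L
    expect_identical(filteredImage(resI)[keep], imgI[keep])
})

test_that("background grows monotonically with theta", {
    set.seed(9)
    img <- randImage(24, 24)
    thetas <- c(0.3, 0.5, 0.7, 0.9, 1, 1.1)
    for (n in c(1, 4, 10)) {
        prev <- NULL
        for (th in thetas) {
            bg <- backgroundMask(lmsf2d(img, n, th))
            if (!is.null(prev)) expect_true(all(bg[prev == 1L] == 1L))
            prev <- bg
        }
    }
})

test_that("LMSFResult validity catches inconsistent objects", {
    res <- lmsf2d(matrix(runif(36), 6, 6), 1)
    bad <- res
    bad@backgroundMask <- matrix(0L, 3, 3)
    expect_error(validObject(bad), "dimensions differ")
    bad2 <- res
    bad2@theta <- -1
    expect_error(validObject(bad2), "positive")
})
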