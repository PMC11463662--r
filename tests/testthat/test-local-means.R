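test_that("1-D adaptive averaging divides by the available sample count", {
    expect_equal(localMean1d(c(1, 2, 3), 1), c(1.5, 2, 2.5))
    # second-from-end points average n+2 values, and so on inward
    x <- c(4, 8, 0, 2, 6)
    expect_equal(localMean1d(x, 2),
                 c(mean(x[1:3]), mean(x[1:4]), mean(x), mean(x[2:5]),
                   mean(x[3:5])))
    # a window wider than the signal reduces every mean to the global mean
    expect_equal(localMean1d(x, 50), rep(mean(x), 5))
})

test_that("1-D local means preserve constants and length", {
    for (n in c(1, 3, 10)) {
        expect_identical(localMean1d(rep(7, 25), n), rep(7, 25))
        expect_length(localMean1d(runif(13), n), 13)
    }
})

test_that("1-D local means match the brute-force oracle", {
    set.seed(11)
    for (rep in 1:25) {
        K <- sample(1:60, 1)
        x <- runif(K, 0, 100)
        n <- sample(1:20, 1)
        expect_lt(relErr(localMean1d(x, n), naiveLocalMean1d(x, n)), 1e-9)
    }
    # negative values are legal for the bare mean operator
    x <- rnorm(40)
    expect_lt(relErr(localMean1d(x, 4), naiveLocalMean1d(x, 4)), 1e-9)
})

test_that("1-D mean rejects invalid windows and signals", {
    expect_error(localMean1d(1:5, 0), "positive integer")
    expect_error(localMean1d(1:5, -2), "positive integer")
    expect_error(localMean1d(1:5, 1.5), "positive integer")
    expect_error(localMean1d(numeric(0), 1), "non-empty")
    expect_error(localMean1d(c(1, NA, 2), 1), "non-finite")
})

test_that("2-D adaptive window counts follow the clipped geometry", {
    img <- matrix(0, 3, 3); img[2, 2] <- 9
    got <- localMean2d(img, 1)
    expected <- matrix(9 / 6, 3, 3)       # edge windows hold 6 pixels
    expected[c(1, 3), c(1, 3)] <- 9 / 4   # corner windows hold 4
    expected[2, 2] <- 1                   # full 3x3 window
    expect_equal(got, expected)
})

test_that("2-D local means preserve constant images exactly", {
    img <- matrix(3.7, 12, 9)
    for (n in c(1, 2, 3))
        expect_identical(localMean2d(img, n), img)
})

test_that("2-D local means match the brute-force oracle on random images", {
    set.seed(23)
    for (rep in 1:40) {
        K <- sample(4:32, 1); M <- sample(4:32, 1)
        img <- randImage(K, M)
        for (n in seq_len(nMax(K, M)))
            expect_lt(relErr(localMean2d(img, n),
                             naiveLocalMean2d(img, n)), 1e-9)
    }
})

test_that("2-D local means accept integer matrices", {
    img <- matrix(sample.int(1000L, 64, replace = TRUE), 8, 8)
    expect_lt(relErr(localMean2d(img, 2), naiveLocalMean2d(img, 2)), 1e-9)
})

test_that("window bound is enforced", {
    img <- randImage(10, 10)   # nMax = 4
    expect_error(localMean2d(img, 5), "nMax")
    expect_silent(localMean2d(img, 4))
})
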