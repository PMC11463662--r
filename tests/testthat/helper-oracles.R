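# Independent brute-force oracles: explicit clipped-window loops, no
# shared code with the summed-area-table implementation.

naiveLocalMean1d <- function(x, n) {
    K <- length(x)
    vapply(seq_len(K), function(k)
        mean(x[max(1L, k - n):min(K, k + n)]), numeric(1))
}

naiveLocalMean2d <- function(img, n) {
    K <- nrow(img); M <- ncol(img)
    out <- matrix(0, K, M)
    for (k in seq_len(K))
        for (m in seq_len(M))
            out[k, m] <- mean(img[max(1L, k - n):min(K, k + n),
                                  max(1L, m - n):min(M, m + n)])
    out
}

randImage <- function(K, M, maxval = 100) {
    matrix(runif(K * M, 0, maxval), K, M)
}

relErr <- function(a, b) {
    max(abs(a - b) / pmax(abs(b), 1e-12))
}

# bright bars flanking a wide uniform low strip; used for the
# saturation-effect checks
stripImage <- function(K = 128L, M = 256L, stripCols = 99:158,
                       low = 1, high = 100) {
    img <- matrix(high, K, M)
    img[, stripCols] <- low
    img
}
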