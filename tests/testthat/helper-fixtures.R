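# Shared fixtures, built in code.

# Rasterized disk mask of radius r (pixels) centred in a square patch.
disk_mask <- function(r, pad = 3L) {
    n <- 2L * (r + pad) + 1L
    ctr <- r + pad + 1L
    d2 <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                function(i, j) i^2 + j^2)
    d2 <= r^2
}

# Brute-force GLCM + Haralick oracle: explicit pair enumeration, written
# independently of the package's vectorized implementation.
oracle_haralick <- function(img, mask, levels, offsets, symmetric = TRUE) {
    v <- img[mask]
    mn <- min(v); mx <- max(v)
    qn <- matrix(NA_integer_, nrow(img), ncol(img))
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
        if (mask[i, j])
            qn[i, j] <- if (mx > mn)
                min(levels - 1L, floor((img[i, j] - mn) / (mx - mn) * levels))
            else 0L
    feats <- matrix(0, length(offsets), 5L)
    for (k in seq_along(offsets)) {
        off <- offsets[[k]]
        p <- matrix(0, levels, levels)
        for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
            i2 <- i + off[1L]; j2 <- j + off[2L]
            if (i2 < 1 || i2 > nrow(img) || j2 < 1 || j2 > ncol(img)) next
            if (is.na(qn[i, j]) || is.na(qn[i2, j2])) next
            a <- qn[i, j] + 1L; b <- qn[i2, j2] + 1L
            p[a, b] <- p[a, b] + 1
            if (symmetric) p[b, a] <- p[b, a] + 1
        }
        if (sum(p) > 0) p <- p / sum(p)
        ii <- row(p) - 1; jj <- col(p) - 1
        pi_m <- rowSums(p); pj_m <- colSums(p)
        mui <- sum((0:(levels - 1)) * pi_m)
        muj <- sum((0:(levels - 1)) * pj_m)
        sdi <- sqrt(sum((0:(levels - 1) - mui)^2 * pi_m))
        sdj <- sqrt(sum((0:(levels - 1) - muj)^2 * pj_m))
        corr <- if (sdi > 0 && sdj > 0)
            sum((ii - mui) * (jj - muj) * p) / (sdi * sdj) else 0
        nz <- p[p > 0]
        feats[k, ] <- c(sum(p * (ii - jj)^2), corr, sum(p^2),
                        sum(p / (1 + (ii - jj)^2)), -sum(nz * log(nz)))
    }
    setNames(colMeans(feats),
             c("har_contrast", "har_correlation", "har_energy",
               "har_homogeneity", "har_entropy"))
}

default_offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# One cached default classifier shared across test files (training is the
# expensive step).
cached_model <- local({
    model <- NULL
    function() {
        if (is.null(model)) model <<- train_default_classifier(seed = 11)
        model
    }
})
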