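test_that("GLCM/Haralick matches the brute-force pair-enumeration oracle", {
    set.seed(501)
    for (rep in 1:6) {
        img <- matrix(runif(16 * 16, 0, 1000), 16, 16)
        mask <- matrix(TRUE, 16, 16)
        got <- haralick_features(glcm(img, mask, levels = 8L,
                                      offsets = default_offsets))
        want <- oracle_haralick(img, mask, 8L, default_offsets)
        expect_equal(got, want, tolerance = 1e-10)
    }
    # irregular mask
    img <- matrix(runif(100, 0, 50), 10, 10)
    mask <- matrix(runif(100) > 0.4, 10, 10)
    got <- haralick_features(glcm(img, mask, levels = 4L,
                                  offsets = default_offsets))
    want <- oracle_haralick(img, mask, 4L, default_offsets)
    expect_equal(got, want, tolerance = 1e-10)
})

test_that("checkerboard and constant patches give closed-form Haralick values", {
    chk <- matrix(c(0, 1, 1, 0), 2, 2)
    h <- haralick_features(glcm(chk, matrix(TRUE, 2, 2), levels = 2L,
                                offsets = list(c(0L, 1L))))
    expect_equal(unname(h["har_contrast"]), 1.0)
    expect_equal(unname(h["har_energy"]), 0.5)

    const <- matrix(7, 6, 6)
    h <- haralick_features(glcm(const, matrix(TRUE, 6, 6), levels = 32L,
                                offsets = default_offsets))
    expect_equal(unname(h["har_contrast"]), 0)
    expect_equal(unname(h["har_energy"]), 1)
    expect_equal(unname(h["har_homogeneity"]), 1)
    expect_equal(unname(h["har_entropy"]), 0)
})

test_that("Haralick features are invariant to affine intensity rescaling", {
    set.seed(502)
    img <- matrix(runif(144, 10, 90), 12, 12)
    mask <- matrix(TRUE, 12, 12)
    a <- haralick_features(glcm(img, mask))
    b <- haralick_features(glcm(3.7 * img + 120, mask))
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("Gabor bank responds maximally at the grating orientation", {
    n <- 64
    f <- 0.15
    # grating varying down the rows: wave vector at theta = 0
    img <- matrix(rep(sin(2 * pi * f * seq_len(n)), times = n), n, n) * 100
    mask <- matrix(FALSE, n, n); mask[17:48, 17:48] <- TRUE
    v <- gabor_features(img, mask, frequencies = f,
                        orientations = c(0, 45, 90, 135) * pi / 180)
    means <- v[grep("_mean$", names(v))]
    expect_equal(which.max(means), 1L, ignore_attr = TRUE)

    const <- matrix(500, n, n)
    v0 <- gabor_features(const, mask)
    expect_lt(max(abs(v0[grep("_mean$", names(v0))])), 1e-6)
})

test_that("rotating the image by 90 degrees permutes Gabor orientations", {
    set.seed(503)
    n <- 48
    img <- matrix(0, n, n)
    img[seq(8, 40, 4), ] <- 100           # horizontal stripes
    img <- img + matrix(runif(n * n, 0, 5), n, n)
    mask <- matrix(FALSE, n, n); mask[13:36, 13:36] <- TRUE
    v1 <- gabor_features(img, mask)
    v2 <- gabor_features(t(img)[n:1, ], mask)  # 90-degree rotation
    m1 <- v1[grep("_mean$", names(v1))]
    m2 <- v2[grep("_mean$", names(v2))]
    # orientations 0 <-> 90 and 45 <-> 135 swap within each frequency
    perm <- c(3, 4, 1, 2, 7, 8, 5, 6)
    expect_equal(unname(m1), unname(m2[perm]), tolerance = 0.05)
})

test_that("SER features separate blobs from lines and vanish on constants", {
    n <- 41; ctr <- 21
    mask <- matrix(FALSE, n, n); mask[(ctr - 8):(ctr + 8), (ctr - 8):(ctr + 8)] <- TRUE

    blob <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                  function(i, j) 100 * exp(-(i^2 + j^2) / (2 * 2^2)))
    sb <- ser_features(blob, mask, scales = 2)
    expect_gt(sb[["ser_s2_spot"]], sb[["ser_s2_ridge"]])

    line <- matrix(0, n, n); line[ctr, ] <- 100
    sl <- ser_features(line, mask, scales = 2)
    expect_gt(sl[["ser_s2_ridge"]], sl[["ser_s2_spot"]])

    s0 <- ser_features(matrix(42, n, n), mask, scales = c(1, 2))
    expect_true(all(abs(unlist(s0)) < 1e-12))
})

test_that("morphology features match closed forms on simple shapes", {
    dm <- disk_mask(20L)
    m <- morphology_features(dm, pixel_size = 1)
    expect_gt(m[["form_factor"]], 0.95)
    expect_lt(m[["form_factor"]], 1.05)
    expect_equal(m[["area_um2"]], sum(dm))
    expect_equal(m[["lobe_count"]], 1)

    sq <- matrix(FALSE, 16, 16); sq[4:13, 4:13] <- TRUE
    ms <- morphology_features(sq, pixel_size = 1)
    expect_equal(ms[["area_um2"]], 100)
    # the smooth-contour estimator runs ~15% short on axis-aligned squares
    # (ideal 40); it is calibrated for round nuclei, not polygons
    expect_equal(ms[["perimeter_um"]], 40, tolerance = 0.16)
    expect_equal(ms[["solidity"]], 1, tolerance = 0.02)
    expect_error(morphology_features(matrix(FALSE, 8, 8)), "empty")
})

test_that("area scales with pixel size squared", {
    dm <- disk_mask(10L)
    a1 <- morphology_features(dm, pixel_size = 0.6)[["area_um2"]]
    a2 <- morphology_features(dm, pixel_size = 1.2)[["area_um2"]]
    expect_equal(a2 / a1, 4)
})

test_that("intensity features use the population sd convention", {
    img <- matrix(1, 16, 16)
    mask <- matrix(FALSE, 16, 16); mask[3:4, 3:7] <- TRUE
    v <- intensity_features(img, mask, pixel_size = 1)
    expect_equal(unname(v[c("int_mean", "int_sd", "int_total")]), c(1, 0, 10))

    img[mask] <- rep(c(0, 2), 5)
    v <- intensity_features(img, mask, pixel_size = 1)
    expect_equal(unname(v["int_mean"]), 1)
    expect_equal(unname(v["int_sd"]), 1)  # population, not sample
    expect_equal(unname(v["density"]), 10 / 10)
})

test_that("lobe counting finds known lobe placements", {
    # three overlapping disks at known centres -> 3 distance-transform maxima
    n <- 40L
    mk <- matrix(FALSE, n, n)
    ctrs <- rbind(c(14, 14), c(14, 27), c(26, 20))
    for (k in 1:3) {
        d2 <- outer(seq_len(n) - ctrs[k, 1], seq_len(n) - ctrs[k, 2],
                    function(i, j) i^2 + j^2)
        mk <- mk | d2 <= 36
    }
    m <- suppressWarnings(morphology_features(mk, pixel_size = 1,
                                              lobe_min_sep = 4L))
    expect_equal(m[["lobe_count"]], 3)
    # a single disk has exactly one
    expect_equal(morphology_features(disk_mask(8L), 1)[["lobe_count"]], 1)
})

test_that("secondary-channel readout averages inside each object", {
    labels <- matrix(0L, 64, 64)
    labels[10:15, 10:15] <- 1L; labels[40:45, 40:45] <- 2L
    sec <- matrix(0, 64, 64); sec[40:45, 40:45] <- 300
    out <- secondary_channel_intensity(labels, sec)
    expect_equal(out$secondary_mean, c(0, 300))
    # dilation on a uniform field leaves means unchanged
    u <- matrix(55, 64, 64)
    expect_equal(secondary_channel_intensity(labels, u, dilate_px = 0L)$secondary_mean,
                 secondary_channel_intensity(labels, u, dilate_px = 2L)$secondary_mean)
    expect_error(secondary_channel_intensity(labels, matrix(0, 32, 32)),
                 "shape")
})

test_that("feature extraction is fast enough for screening", {
    sim <- simulate_field(250, c(0.4, 0.5, 0.1), width = 768L, height = 768L,
                          seed = 99)
    seg <- segment_nuclei(sim$image)
    t0 <- proc.time()
    feats <- extract_features(sim$image, seg)
    elapsed <- (proc.time() - t0)[["elapsed"]]
    expect_gt(nrow(feats), 200)
    # 1,000 cells in < 60 s implies < 15 s for ~250
    expect_lt(elapsed * 4, 60)
    expect_true(all(is.finite(as.matrix(feats[, -(1:2)]))))
    expect_true(all(feats$form_factor <= 1.1))
})
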