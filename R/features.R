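## Multiparametric per-object features: morphology, intensity, density and
## texture (Haralick/GLCM, Gabor bank, spots/edges/ridges).

# Normalize an object specification to 1-based linear pixel indices.
.obj_index <- function(obj, dims) {
    if (is.logical(obj)) {
        if (!all(dim(obj) == dims)) stop("object mask shape mismatch")
        which(obj)
    } else if (is.numeric(obj)) {
        idx <- as.integer(obj)
        if (length(idx) && (min(idx) < 1L || max(idx) > prod(dims)))
            stop("object pixel indices out of range")
        idx
    } else stop("obj must be a logical mask or linear pixel indices")
}

#' Gray-level co-occurrence matrix of one object
#'
#' Intensities inside the object are min-max quantized to `levels` gray
#' bins (a constant object maps every pixel to bin 0), and pairs of
#' co-occurring bins are counted for each spatial offset. Each offset's
#' matrix is normalized to sum 1. Quantizing on the per-object min-max
#' makes the downstream Haralick features invariant to affine intensity
#' rescaling.
#'
#' @param img numeric matrix (one channel of one field).
#' @param obj logical mask (same shape as `img`) or 1-based linear pixel
#'   indices of the object.
#' @param levels number of gray bins (>= 2).
#' @param offsets list of integer `c(drow, dcol)` pixel offsets.
#' @param symmetric logical; count each pair in both directions (default).
#' @return `levels x levels x length(offsets)` array, each slice summing
#'   to 1 (all-zero slice if an offset yields no pairs).
#' @export
glcm <- function(img, obj, levels = 32L,
                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                 symmetric = TRUE) {
    if (levels < 2L) stop("levels must be >= 2")
    if (!length(offsets)) stop("offsets must be non-empty")
    idx <- .obj_index(obj, dim(img))
    if (length(idx) < 2L) stop("object must contain at least 2 pixels")
    nr <- nrow(img)
    v <- img[idx]
    mn <- min(v); mx <- max(v)
    bin <- matrix(NA_integer_, nrow(img), ncol(img))
    bin[idx] <- if (mx > mn)
        pmin(levels - 1L, as.integer(floor((img[idx] - mn) / (mx - mn) * levels)))
    else 0L
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    out <- array(0, dim = c(levels, levels, length(offsets)))
    for (k in seq_along(offsets)) {
        off <- offsets[[k]]
        r2 <- rows + off[1L]; c2 <- cols + off[2L]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(img)
        if (any(ok)) {
            b1 <- bin[idx[ok]]
            b2 <- bin[cbind(r2[ok], c2[ok])]
            ok2 <- !is.na(b2)
            b1 <- b1[ok2]; b2 <- b2[ok2]
            if (length(b1)) {
                counts <- tabulate(b1 * levels + b2 + 1L, nbins = levels^2)
                m <- matrix(counts, levels, levels, byrow = TRUE)
                if (symmetric) m <- m + t(m)
                if (sum(m) > 0) out[, , k] <- m / sum(m)
            }
        }
    }
    attr(out, "offsets") <- offsets
    out
}

#' Haralick texture features from a co-occurrence array
#'
#' Computes contrast, correlation, energy (angular second moment),
#' homogeneity and entropy for each offset slice and averages them over
#' offsets. Entropy uses the natural logarithm with the convention
#' 0 * ln 0 = 0; correlation is defined as 0 when either marginal standard
#' deviation is 0 (e.g. a constant object).
#'
#' @param p array from [glcm()] (or a single normalized matrix).
#' @return named numeric vector `har_contrast`, `har_correlation`,
#'   `har_energy`, `har_homogeneity`, `har_entropy`.
#' @export
haralick_features <- function(p) {
    if (is.matrix(p)) p <- array(p, dim = c(dim(p), 1L))
    levels <- dim(p)[1L]
    i <- matrix(seq_len(levels) - 1L, levels, levels)
    j <- t(i)
    acc <- numeric(5)
    nk <- dim(p)[3L]
    for (k in seq_len(nk)) {
        pk <- p[, , k]
        s <- sum(pk)
        if (s <= 0) next  # empty offset contributes zeros
        contrast <- sum(pk * (i - j)^2)
        pi_m <- rowSums(pk); pj_m <- colSums(pk)
        mui <- sum((seq_len(levels) - 1L) * pi_m)
        muj <- sum((seq_len(levels) - 1L) * pj_m)
        sdi <- sqrt(sum((seq_len(levels) - 1L - mui)^2 * pi_m))
        sdj <- sqrt(sum((seq_len(levels) - 1L - muj)^2 * pj_m))
        correlation <- if (sdi > 0 && sdj > 0)
            sum((i - mui) * (j - muj) * pk) / (sdi * sdj) else 0
        energy <- sum(pk^2)
        homogeneity <- sum(pk / (1 + (i - j)^2))
        nz <- pk[pk > 0]
        entropy <- -sum(nz * log(nz))
        acc <- acc + c(contrast, correlation, energy, homogeneity, entropy)
    }
    setNames(acc / nk, c("har_contrast", "har_correlation", "har_energy",
                         "har_homogeneity", "har_entropy"))
}

#' Build a complex Gabor kernel
#'
#' Oriented sinusoid under a Gaussian envelope. The even (cosine) part is
#' made exactly DC-free by subtracting an envelope-weighted offset, so a
#' constant image yields zero response magnitude.
#'
#' @param frequency spatial frequency in cycles/pixel, in (0, 0.5].
#' @param theta orientation in radians (0 = wave vector along image rows,
#'   i.e. maximal response to gratings varying down the rows).
#' @param sigma Gaussian envelope sd in pixels; default `0.56 / frequency`
#'   (about one octave bandwidth).
#' @return list with matrices `even`, `odd` and the kernel radius.
#' @export
gabor_kernel <- function(frequency, theta, sigma = 0.56 / frequency) {
    if (frequency <= 0 || frequency > 0.5)
        stop("frequency must be in (0, 0.5] cycles/pixel")
    r <- ceiling(2.5 * sigma)
    x <- seq(-r, r)
    X <- matrix(x, 2 * r + 1, 2 * r + 1)          # row coordinate
    Y <- t(X)                                      # column coordinate
    xr <- X * cos(theta) + Y * sin(theta)
    env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
    even <- env * cos(2 * pi * frequency * xr)
    odd <- env * sin(2 * pi * frequency * xr)
    even <- even - env * sum(even) / sum(env)      # exact zero DC
    list(even = even, odd = odd, radius = r,
         frequency = frequency, theta = theta)
}

.default_frequencies <- c(0.15, 0.30)
.default_orientations <- c(0, 45, 90, 135) * pi / 180

#' Gabor-bank texture features of one object
#'
#' Convolves the image with a bank of complex Gabor kernels (default 2
#' frequencies x 4 orientations) and reports, per kernel, the mean and
#' population sd of the response magnitude over the object's pixels.
#'
#' @inheritParams glcm
#' @param frequencies cycles/pixel in (0, 0.5].
#' @param orientations radians.
#' @return named numeric vector, `gab_f<freq>_o<deg>_mean` / `_sd` per
#'   (frequency, orientation) pair.
#' @export
gabor_features <- function(img, obj,
                           frequencies = .default_frequencies,
                           orientations = .default_orientations) {
    if (!length(frequencies) || !length(orientations))
        stop("Gabor bank must contain at least one frequency and orientation")
    idx <- .obj_index(obj, dim(img))
    if (!length(idx)) stop("object is empty")
    labels <- matrix(0L, nrow(img), ncol(img))
    labels[idx] <- 1L
    maps <- .gabor_magnitude_maps(img, labels > 0L, frequencies, orientations)
    out <- numeric(0)
    for (nm in names(maps)) {
        v <- maps[[nm]][idx]
        out[paste0(nm, "_mean")] <- mean(v)
        out[paste0(nm, "_sd")] <- sqrt(mean((v - mean(v))^2))
    }
    out
}

# Magnitude maps for the whole bank, evaluated only where eval_mask is TRUE.
.gabor_magnitude_maps <- function(img, eval_mask, frequencies, orientations) {
    fgidx <- which(eval_mask)
    vecs <- .gabor_magnitude_vecs(img, fgidx, frequencies, orientations)
    lapply(vecs, function(v) {
        m <- matrix(0, nrow(img), ncol(img))
        m[fgidx] <- v
        m
    })
}

# Same bank, but returns response-magnitude vectors at fgidx only.
.gabor_magnitude_vecs <- function(img, fgidx, frequencies, orientations) {
    ev <- matrix(0L, nrow(img), ncol(img))
    ev[fgidx] <- 1L
    vecs <- list()
    for (f in frequencies) for (th in orientations) {
        k <- gabor_kernel(f, th)
        re <- cpp_conv2_masked(img, k$even, ev)[fgidx]
        im <- cpp_conv2_masked(img, k$odd, ev)[fgidx]
        nm <- sprintf("gab_f%03d_o%03d", round(1000 * f),
                      round(th * 180 / pi) %% 180)
        vecs[[nm]] <- sqrt(re^2 + im^2)
    }
    vecs
}

# Sampled 1-D Gaussian and derivative kernels. The smoothing kernel is
# normalized to sum 1; the second-derivative kernel is offset-corrected to
# sum exactly 0 so derivative features vanish on constant images.
.gauss_kernels <- function(sigma, radius = ceiling(4 * sigma)) {
    x <- seq(-radius, radius)
    g <- exp(-x^2 / (2 * sigma^2))
    g <- g / sum(g)
    g1 <- -x / sigma^2 * g
    g1 <- g1 - mean(g1)        # antisymmetric already; exact zero sum
    g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
    g2 <- g2 - mean(g2)
    list(g = g, g1 = g1, g2 = g2)
}

# Scale-normalized derivative response maps at one scale. With fgidx given,
# returns vectors at those pixels only (the convolutions are full-field).
.ser_maps <- function(img, sigma, fgidx = NULL) {
    k <- .gauss_kernels(sigma)
    gx <- cpp_conv_sep(img, k$g1, k$g)   # d/drow
    gy <- cpp_conv_sep(img, k$g, k$g1)   # d/dcol
    hxx <- cpp_conv_sep(img, k$g2, k$g)
    hyy <- cpp_conv_sep(img, k$g, k$g2)
    hxy <- cpp_conv_sep(img, k$g1, k$g1)
    if (!is.null(fgidx)) {
        gx <- gx[fgidx]; gy <- gy[fgidx]
        hxx <- hxx[fgidx]; hyy <- hyy[fgidx]; hxy <- hxy[fgidx]
    }
    s2 <- sigma^2
    tr <- s2 * (hxx + hyy)               # scale-normalized Laplacian
    disc <- sqrt(pmax(0, (hxx - hyy)^2 + 4 * hxy^2)) * s2
    l1 <- (tr + disc) / 2
    l2 <- (tr - disc) / 2
    # blobness: positive part of the scale-normalized Hessian determinant
    # (both principal curvatures bending the same way); zero on straight
    # ridges, where the raw squared Laplacian would tie with the ridge
    # measure
    list(log2 = 4 * pmax(0, l1 * l2),
         grad2 = s2 * (gx^2 + gy^2),
         ridge2 = (abs(l1) - abs(l2))^2)
}

#' Spots / edges / ridges (SER) texture energies of one object
#'
#' Scale-space derivative energies inside the object, one triple per scale:
#' `spot` is the mean positive part of the scale-normalized Hessian
#' determinant (x4; equal to the squared scale-normalized Laplacian on an
#' isotropic blob, zero on straight ridges), `edge` the mean squared
#' scale-normalized gradient magnitude, and `ridge` the mean squared
#' difference of Hessian eigenvalue magnitudes (large for line-like
#' structure, near zero for blobs). Each energy is divided by the squared
#' mean object intensity for illumination invariance.
#'
#' @inheritParams glcm
#' @param scales Gaussian sigmas in pixels (> 0).
#' @return named numeric vector `ser_s<scale>_spot` / `_edge` / `_ridge`.
#' @export
ser_features <- function(img, obj, scales = c(1, 2)) {
    if (!length(scales) || any(scales <= 0))
        stop("scales must be positive Gaussian sigmas")
    idx <- .obj_index(obj, dim(img))
    if (!length(idx)) stop("object is empty")
    mu <- mean(img[idx])
    norm <- if (mu > 0) mu^2 else 1
    out <- numeric(0)
    for (s in scales) {
        m <- .ser_maps(img, s)
        tag <- sprintf("ser_s%g", s)
        out[paste0(tag, "_spot")] <- mean(m$log2[idx]) / norm
        out[paste0(tag, "_edge")] <- mean(m$grad2[idx]) / norm
        out[paste0(tag, "_ridge")] <- mean(m$ridge2[idx]) / norm
    }
    out
}

# Weighted border-configuration perimeter estimator: each object pixel is
# classified by its 4- and 8-neighbourhood occupancy (code
# 1 + 2*n4 + 10*ndiag) and contributes a weight calibrated for smooth
# contours (straight runs 1, diagonal connectors sqrt(2), mixed steps
# (1+sqrt(2))/2). Accurate to a few percent on disks; axis-aligned
# rectangles come out ~10% short.
.perimeter_px <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    m <- matrix(FALSE, nr + 2L, nc + 2L)
    m[2:(nr + 1L), 2:(nc + 1L)] <- mask
    core <- m[2:(nr + 1L), 2:(nc + 1L)]
    n4full <- m[1:nr, 2:(nc + 1L)] + m[3:(nr + 2L), 2:(nc + 1L)] +
              m[2:(nr + 1L), 1:nc] + m[2:(nr + 1L), 3:(nc + 2L)]
    border <- core & n4full < 4L          # object minus its 4-erosion
    b <- matrix(FALSE, nr + 2L, nc + 2L)
    b[2:(nr + 1L), 2:(nc + 1L)] <- border
    n4 <- b[1:nr, 2:(nc + 1L)] + b[3:(nr + 2L), 2:(nc + 1L)] +
          b[2:(nr + 1L), 1:nc] + b[2:(nr + 1L), 3:(nc + 2L)]
    nd <- b[1:nr, 1:nc] + b[1:nr, 3:(nc + 2L)] +
          b[3:(nr + 2L), 1:nc] + b[3:(nr + 2L), 3:(nc + 2L)]
    code <- (1L + 2L * n4 + 10L * nd)[border]
    w <- numeric(50L)
    w[c(5L, 7L, 15L, 17L, 25L, 27L)] <- 1
    w[c(21L, 33L)] <- sqrt(2)
    w[c(13L, 23L)] <- (1 + sqrt(2)) / 2
    # 0.95: classical calibration of step-count estimators on smooth
    # contours (digital disks come out ~1% high with it, axis-aligned
    # rectangles ~10-15% low)
    0.95 * sum(w[code])
}

# Convex hull area of a pixel set, with a half-perimeter lattice correction
# so a convex mask has solidity close to 1.
.hull_area_px <- function(rows, cols) {
    if (length(rows) < 3L) return(length(rows))
    pts <- unique(cbind(rows, cols))
    if (nrow(pts) < 3L) return(nrow(pts))
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    hx <- pts[h, 1L]; hy <- pts[h, 2L]
    n <- length(h)
    area <- abs(sum(hx * hy[c(2:n, 1L)] - hx[c(2:n, 1L)] * hy)) / 2
    per <- sum(sqrt(diff(c(hx, hx[1L]))^2 + diff(c(hy, hy[1L]))^2))
    area + per / 2 + 1
}

#' Morphological features of one object
#'
#' Area and perimeter are reported in physical units. The perimeter uses a
#' weighted border-pixel estimator that is accurate on smooth contours (a
#' rasterized disk has form factor ~1) but mildly underestimates axis-
#' aligned polygons. `form_factor = 4*pi*A/P^2` is capped at 1.1 with a
#' warning (discretization can push round objects slightly above 1).
#' `lobe_count` counts smoothed distance-transform local maxima separated
#' by at least `lobe_min_sep` pixels — 3-5 for a lobulated resting
#' neutrophil nucleus, 1 for condensed or diffuse nuclei.
#'
#' @param obj logical mask of the object (its bounding box or the full
#'   field).
#' @param pixel_size micrometres per pixel.
#' @param lobe_min_sep minimum separation between lobe maxima, pixels.
#' @param lobe_smooth sd (pixels) of the Gaussian applied to the distance
#'   transform before peak finding.
#' @return named numeric vector: `area_um2`, `perimeter_um`, `form_factor`,
#'   `solidity`, `eq_diameter_um`, `lobe_count`.
#' @export
morphology_features <- function(obj, pixel_size = 0.6, lobe_min_sep = 3L,
                                lobe_smooth = 1) {
    if (!is.logical(obj)) stop("obj must be a logical mask")
    n <- sum(obj)
    if (n == 0L) stop("empty object")
    area <- n * pixel_size^2
    per_px <- .perimeter_px(obj)
    perimeter <- per_px * pixel_size
    ff <- if (per_px > 0) 4 * pi * n / per_px^2 else 1
    if (ff > 1.1) {
        warning("form_factor ", signif(ff, 3), " capped at 1.1")
        ff <- 1.1
    }
    w <- which(obj, arr.ind = TRUE)
    sol <- min(1, n / .hull_area_px(w[, 1L], w[, 2L]))
    c(area_um2 = area, perimeter_um = perimeter, form_factor = ff,
      solidity = sol,
      eq_diameter_um = 2 * sqrt(area / pi),
      lobe_count = .lobe_count(obj, lobe_min_sep, lobe_smooth))
}

# Morphology minus the lobe count (which extract_features computes in one
# field-level pass). msk is the bounding-box submask; r, cc the global
# pixel coordinates.
.morph_core <- function(msk, r, cc, pixel_size) {
    n <- sum(msk)
    area <- n * pixel_size^2
    per_px <- .perimeter_px(msk)
    ff <- min(1.1, if (per_px > 0) 4 * pi * n / per_px^2 else 1)
    sol <- min(1, n / .hull_area_px(r, cc))
    c(area_um2 = area, perimeter_um = per_px * pixel_size,
      form_factor = ff, solidity = sol,
      eq_diameter_um = 2 * sqrt(area / pi))
}

# Lobe counts for every object of a label image in one pass: smoothed
# distance-transform local maxima, assigned to objects by label.
.lobe_count_field <- function(labels, min_sep = 3L, smooth = 1) {
    mask <- labels > 0L
    d <- EBImage::distmap(mask)
    g <- .gauss_kernels(smooth)$g
    d <- cpp_conv_sep(d, g, g)
    win <- 2L * as.integer(min_sep) + 1L
    dmax <- EBImage::dilate(d, EBImage::makeBrush(win, "box"))
    fgidx <- which(mask)
    lab_v <- labels[fgidx]
    ids <- sort(unique(lab_v))
    maxd <- vapply(split(d[fgidx], lab_v), max, numeric(1))
    is_peak <- d[fgidx] >= dmax[fgidx] - 1e-9 &
        d[fgidx] > 0.35 * maxd[match(lab_v, ids)]
    pk <- matrix(FALSE, nrow(labels), ncol(labels))
    pk[fgidx[is_peak]] <- TRUE
    pl <- EBImage::bwlabel(pk)
    comp <- pl[fgidx[is_peak]]
    obj <- lab_v[is_peak]
    counts <- tapply(comp, obj, function(x) length(unique(x)))
    out <- setNames(rep(1, length(ids)), as.character(ids))
    out[names(counts)] <- pmax(1, counts)
    as.list(out)
}

# Count local maxima of the smoothed in-object distance transform.
.lobe_count <- function(mask, min_sep = 3L, smooth = 1) {
    nr <- nrow(mask); nc <- ncol(mask)
    pad <- 2L
    m <- matrix(0, nr + 2L * pad, nc + 2L * pad)
    m[pad + seq_len(nr), pad + seq_len(nc)] <- mask
    d <- EBImage::distmap(m)
    d <- cpp_conv_sep(d, .gauss_kernels(smooth)$g, .gauss_kernels(smooth)$g)
    win <- 2L * as.integer(min_sep) + 1L
    dmax <- EBImage::dilate(d, EBImage::makeBrush(win, "box"))
    peaks <- (d >= dmax - 1e-9) & (m > 0) & (d > 0.35 * max(d))
    max(1L, max(EBImage::bwlabel(peaks)))
}

#' Intensity and density features of one object
#'
#' Mean, population standard deviation, maximum and total of the in-object
#' pixel intensities (native units), plus `density` = total intensity per
#' square micrometre.
#'
#' @inheritParams glcm
#' @param pixel_size micrometres per pixel (for the density denominator).
#' @return named numeric vector `int_mean`, `int_sd`, `int_max`,
#'   `int_total`, `density`.
#' @export
intensity_features <- function(img, obj, pixel_size = 0.6) {
    idx <- .obj_index(obj, dim(img))
    if (!length(idx)) stop("empty object")
    v <- img[idx]
    mu <- mean(v)
    c(int_mean = mu,
      int_sd = sqrt(mean((v - mu)^2)),
      int_max = max(v),
      int_total = sum(v),
      density = sum(v) / (length(v) * pixel_size^2))
}

#' Mean secondary-channel intensity per object
#'
#' Reads out a secondary stain (e.g. anti-MPO immunofluorescence) inside
#' each nuclear object, optionally after dilating the mask to capture
#' signal just outside the chromatin boundary.
#'
#' @param objects a `labeled_objects` (see [segment_nuclei()]) or an
#'   integer label image.
#' @param img a `field_image` with `channel == "secondary"`, or a numeric
#'   matrix.
#' @param dilate_px dilation radius in pixels (0 = none).
#' @return data.frame with `cell_id` and `secondary_mean`.
#' @export
secondary_channel_intensity <- function(objects, img, dilate_px = 0L) {
    labels <- if (inherits(objects, "labeled_objects"))
        objects$label_image else objects
    px <- if (inherits(img, "field_image")) {
        if (img$channel != "secondary")
            stop("expected a secondary-channel image, got '", img$channel, "'")
        img$pixels
    } else img
    if (!all(dim(labels) == dim(px)))
        stop("label image and secondary image shapes differ")
    if (dilate_px > 0L) {
        brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
        labels <- EBImage::dilate(labels, brush)
    }
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids))
        return(data.frame(cell_id = integer(0), secondary_mean = numeric(0)))
    sums <- rowsum(px[labels > 0L], labels[labels > 0L])
    ns <- rowsum(rep(1, sum(labels > 0L)), labels[labels > 0L])
    data.frame(cell_id = as.integer(rownames(sums)),
               secondary_mean = as.numeric(sums / ns))
}

#' Extract the full multiparametric feature table for one field
#'
#' Computes, for every segmented object, the morphology, intensity/density,
#' Haralick, Gabor and SER features on the nuclear channel. Filter
#' responses are evaluated only at object pixels, which keeps screening
#' runs fast on sparse fields.
#'
#' @param img a nuclear-channel `field_image` (or numeric matrix).
#' @param objects a `labeled_objects` from [segment_nuclei()], or an
#'   integer label image.
#' @param glcm_levels gray bins for the co-occurrence matrix.
#' @param frequencies,orientations Gabor bank (cycles/pixel, radians).
#' @param scales SER scales (pixel sigmas).
#' @param pixel_size micrometres per pixel; taken from `img` when it is a
#'   `field_image`.
#' @return data.frame, one row per object: `cell_id`, `touches_border`,
#'   then the feature columns in fixed order.
#' @export
extract_features <- function(img, objects, glcm_levels = 32L,
                             frequencies = .default_frequencies,
                             orientations = .default_orientations,
                             scales = c(1, 2), pixel_size = NULL) {
    if (inherits(img, "field_image")) {
        if (is.null(pixel_size)) pixel_size <- img$pixel_size
        px <- img$pixels
    } else px <- img
    if (is.null(pixel_size)) pixel_size <- 0.6
    labels <- if (inherits(objects, "labeled_objects"))
        objects$label_image else objects
    if (!all(dim(labels) == dim(px)))
        stop("label image and intensity image shapes differ")
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids)) return(.empty_feature_table())
    fgidx <- which(labels > 0L)
    lab_v <- labels[fgidx]
    gvecs <- .gabor_magnitude_vecs(px, fgidx, frequencies, orientations)
    svecs <- lapply(scales, function(s) .ser_maps(px, s, fgidx))
    lobes <- .lobe_count_field(labels)
    idx_by_id <- split(fgidx, lab_v)
    pos_by_id <- split(seq_along(fgidx), lab_v)
    nr <- nrow(px)
    rows <- lapply(seq_along(ids), function(k) {
        id <- ids[k]
        idx <- idx_by_id[[k]]
        pos <- pos_by_id[[k]]
        r <- (idx - 1L) %% nr + 1L
        cc <- (idx - 1L) %/% nr + 1L
        r0 <- max(1L, min(r) - 2L); r1 <- min(nr, max(r) + 2L)
        c0 <- max(1L, min(cc) - 2L); c1 <- min(ncol(px), max(cc) + 2L)
        sub <- px[r0:r1, c0:c1, drop = FALSE]
        msk <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
        msk[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
        morph <- .morph_core(msk, r, cc, pixel_size)
        morph["lobe_count"] <- lobes[[as.character(id)]] %||% 1
        inten <- intensity_features(px, idx, pixel_size)
        har <- haralick_features(glcm(sub, msk, levels = glcm_levels))
        nrm <- if (inten[["int_mean"]] > 0) inten[["int_mean"]]^2 else 1
        ser <- unlist(lapply(seq_along(scales), function(s) {
            tag <- sprintf("ser_s%g", scales[s])
            m <- svecs[[s]]
            setNames(c(mean(m$log2[pos]), mean(m$grad2[pos]),
                       mean(m$ridge2[pos])) / nrm,
                     paste0(tag, c("_spot", "_edge", "_ridge")))
        }))
        gab <- unlist(lapply(names(gvecs), function(nm) {
            gv <- gvecs[[nm]][pos]
            setNames(c(mean(gv), sqrt(mean((gv - mean(gv))^2))),
                     paste0(nm, c("_mean", "_sd")))
        }))
        c(morph, inten, har, gab, ser)
    })
    out <- as.data.frame(do.call(rbind, rows))
    tb <- if (inherits(objects, "labeled_objects"))
        objects$objects$touches_border[match(ids, objects$objects$id)]
    else rep(FALSE, length(ids))
    cbind(data.frame(cell_id = as.integer(ids), touches_border = tb), out)
}

.empty_feature_table <- function() {
    data.frame(cell_id = integer(0), touches_border = logical(0))
}

#' Names of the feature columns used by the default classifier
#' @param scales,frequencies,orientations see [extract_features()].
#' @return character vector of feature column names.
#' @export
feature_names <- function(frequencies = .default_frequencies,
                          orientations = .default_orientations,
                          scales = c(1, 2)) {
    gab <- unlist(lapply(frequencies, function(f)
        lapply(orientations, function(th)
            paste0(sprintf("gab_f%03d_o%03d", round(1000 * f),
                           round(th * 180 / pi) %% 180),
                   c("_mean", "_sd")))))
    ser <- unlist(lapply(scales, function(s)
        paste0(sprintf("ser_s%g", s), c("_spot", "_edge", "_ridge"))))
    c("area_um2", "perimeter_um", "form_factor", "solidity",
      "eq_diameter_um", "lobe_count", "int_mean", "int_sd", "int_max",
      "int_total", "density", "har_contrast", "har_correlation",
      "har_energy", "har_homogeneity", "har_entropy", gab, ser)
}
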