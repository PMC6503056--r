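## Nuclear segmentation of the Hoechst channel. The pipeline must keep a
## lysed, spread NETotic chromatin region as a single object while still
## splitting touching compact nuclei, so watershed splitting is gated on a
## compactness (solidity) and area heuristic.

#' Segment nuclei in a nuclear-channel field
#'
#' Pipeline: Gaussian smoothing, top-hat background subtraction (grayscale
#' opening with a disc), global Otsu threshold (or a fixed value), hole
#' filling, connected-component labeling, optional distance-transform
#' watershed splitting of compact objects, an area filter, and flagging of
#' border-touching objects. Deterministic for fixed input and parameters.
#'
#' Watershed splitting is applied only to objects that look like fused
#' compact nuclei (solidity above `split_solidity` and area below
#' `split_max_area`), so diffuse NETotic regions are never shattered.
#' Fused pairs of round nuclei measure solidity ~0.8 (single nuclei
#' ~0.95, spread NETotic chromatin with filaments ~0.7 and large), hence
#' the default solidity floor of 0.75 combined with an area cutoff just
#' below the NETotic range; the watershed depth tolerance keeps lobed
#' single nuclei intact.
#'
#' @param img a nuclear-channel `field_image`.
#' @param smooth_sigma Gaussian smoothing sd, pixels.
#' @param bg_radius top-hat structuring disc radius, micrometres.
#' @param threshold `"otsu"` or a fixed numeric intensity (applied to the
#'   smoothed, background-subtracted image).
#' @param min_threshold absolute floor on the threshold (camera units);
#'   prevents Otsu from splitting pure noise on empty fields.
#' @param min_area,max_area object area window, um^2.
#' @param refine logical; grow each Otsu-detected seed out to an
#'   object-relative boundary (`boundary_frac` of its own peak intensity).
#'   A single global threshold cannot trace both a bright condensed
#'   nucleus and a dim spread NETotic region; the per-object boundary
#'   makes object extent independent of what else is in the field.
#'   Contested support between adjacent seeds is divided by intensity-
#'   guided propagation.
#' @param boundary_frac fraction of the per-object peak (background-
#'   subtracted) defining the object boundary.
#' @param split logical; split touching compact nuclei by watershed.
#' @param split_solidity solidity above which an object is a split
#'   candidate.
#' @param split_max_area area (um^2) below which an object is a split
#'   candidate; diffuse NETotic regions exceed it.
#' @param watershed_tolerance minimum distance-transform depth (pixels)
#'   between merged peaks for a split.
#' @param drop_border logical; drop objects touching the field border
#'   (they are still counted in `n_border_dropped`).
#' @return object of class `labeled_objects`: `label_image` (integer
#'   matrix, 0 = background, labels consecutive from 1), `objects`
#'   (data.frame `id`, `n_px`, `area_um2`, `touches_border`, bounding box
#'   `r0`,`r1`,`c0`,`c1` in 0-based pixel coordinates), `pixel_size`,
#'   `n_border_dropped`.
#' @export
segment_nuclei <- function(img, smooth_sigma = 1.5, bg_radius = 15,
                           threshold = "otsu", min_threshold = 100,
                           min_area = 15, max_area = 500, refine = TRUE,
                           boundary_frac = 0.15, split = TRUE,
                           split_solidity = 0.75, split_max_area = 90,
                           watershed_tolerance = 2, drop_border = TRUE) {
    stopifnot(inherits(img, "field_image"))
    if (img$channel != "nuclear")
        stop("segment_nuclei expects the nuclear channel, got '",
             img$channel, "'")
    if (min_area >= max_area)
        stop("min_area must be < max_area")
    ps <- img$pixel_size
    px <- img$pixels
    g <- .gauss_kernels(smooth_sigma)$g
    sm <- cpp_conv_sep(px, g, g)
    r_px <- max(3L, round(bg_radius / ps))
    brush <- EBImage::makeBrush(2L * r_px + 1L, "disc")
    mx0 <- max(sm, 1)
    bg <- EBImage::opening(sm / mx0, brush) * mx0  # grayscale ops want [0,1]
    th_img <- sm - bg
    thr <- if (identical(threshold, "otsu")) {
        mx <- max(th_img)
        if (mx <= 0) Inf else EBImage::otsu(th_img / mx, range = c(0, 1),
                                            levels = 2^16) * mx
    } else as.numeric(threshold)
    thr <- max(thr, min_threshold)
    mask <- th_img > thr
    mask <- EBImage::fillHull(mask)
    labels <- EBImage::bwlabel(mask)
    min_px <- min_area / ps^2
    max_px <- max_area / ps^2
    labels <- .filter_area(labels, min_px, 64 * max_px)
    if (refine) {
        # boundary tracing uses a lightly smoothed image: heavy smoothing
        # deflates peaks and pushes the relative isophote outward
        gl <- .gauss_kernels(max(0.5, smooth_sigma / 2))$g
        th_light <- cpp_conv_sep(px, gl, gl) - bg
        labels <- .refine_boundaries(labels, th_light, min_threshold,
                                     boundary_frac)
    }
    labels <- .filter_area(labels, min_px, max_px)
    if (split)
        labels <- .split_compact(labels, ps, split_solidity, split_max_area,
                                 watershed_tolerance, min_px)
    .finalize_objects(labels, ps, drop_border)
}

# Grow each seed object to its object-relative boundary: every pixel of the
# support mask (background-subtracted signal above min_threshold) is
# assigned to a seed by intensity-guided propagation, then each object
# keeps its assigned pixels above boundary_frac of its own peak, restricted
# to the connected component containing the peak.
.refine_boundaries <- function(labels, th_img, min_threshold, boundary_frac) {
    nseed <- max(labels)
    if (nseed == 0L) return(labels)
    support <- th_img > min_threshold | labels > 0L
    prop <- EBImage::propagate(th_img, labels, mask = support)
    prop <- matrix(as.integer(round(prop)), nrow(labels), ncol(labels))
    seed_idx <- which(labels > 0L)
    peaks <- rep(0, nseed)
    pk <- vapply(split(th_img[seed_idx], labels[seed_idx]), max, numeric(1))
    peaks[as.integer(names(pk))] <- pk
    peak_pos <- rep(NA_integer_, nseed)
    ord <- order(labels[seed_idx], th_img[seed_idx], decreasing = c(FALSE, TRUE),
                 method = "radix")
    first <- !duplicated(labels[seed_idx][ord])
    peak_pos[labels[seed_idx][ord][first]] <- seed_idx[ord][first]
    keep <- prop > 0L & th_img > boundary_frac * peaks[pmax(prop, 1L)]
    out <- matrix(0L, nrow(labels), ncol(labels))
    out[keep] <- prop[keep]
    # drop satellites disconnected from each object's peak
    cc <- EBImage::bwlabel(out > 0L)
    comp_of_peak <- rep(0L, nseed)
    ok <- !is.na(peak_pos) & out[ifelse(is.na(peak_pos), 1L, peak_pos)] > 0L
    comp_of_peak[ok] <- cc[peak_pos[ok]]
    good <- out > 0L & cc == comp_of_peak[pmax(out, 1L)] & comp_of_peak[pmax(out, 1L)] > 0L
    out[!good] <- 0L
    out
}

# Remove components outside the pixel-area window, keep labels dense later.
.filter_area <- function(labels, min_px, max_px) {
    if (max(labels) == 0L) return(labels)
    cnt <- tabulate(labels[labels > 0L], nbins = max(labels))
    bad <- which(cnt < min_px | cnt > max_px)
    if (length(bad)) labels[labels %in% bad] <- 0L
    labels
}

# Watershed-split compact (high-solidity, small) objects on their padded
# bounding boxes, seeded by smoothed distance-transform maxima.
.split_compact <- function(labels, ps, sol_min, area_max_um, tol, min_px) {
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids)) return(labels)
    nr <- nrow(labels)
    idx_all <- which(labels > 0L)
    by_id <- split(idx_all, labels[idx_all])
    next_label <- max(ids) + 1L
    g <- .gauss_kernels(1)$g
    for (id in ids) {
        idx <- by_id[[as.character(id)]]
        if (length(idx) * ps^2 >= area_max_um) next
        r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
        r0 <- min(r); c0 <- min(cc)
        sub <- matrix(FALSE, max(r) - r0 + 3L, max(cc) - c0 + 3L)
        sub[cbind(r - r0 + 2L, cc - c0 + 2L)] <- TRUE
        sol <- length(idx) / .hull_area_px(r, cc)
        if (sol <= sol_min) next
        d <- EBImage::distmap(sub)
        d <- cpp_conv_sep(d, g, g)
        w <- EBImage::watershed(d * sub, tolerance = tol, ext = 1L)
        nseg <- max(w)
        if (nseg < 2L) next
        segs <- tabulate(w[w > 0L], nbins = nseg)
        if (any(segs < min_px)) next
        wl <- w[cbind(r - r0 + 2L, cc - c0 + 2L)]
        keep <- wl > 0L
        labels[idx] <- 0L
        labels[idx[keep]] <- next_label + wl[keep] - 1L
        next_label <- next_label + nseg
    }
    labels
}

# Relabel consecutively, compute bounding boxes and border flags.
.finalize_objects <- function(labels, ps, drop_border) {
    nr <- nrow(labels); nc <- ncol(labels)
    ids <- sort(unique(labels[labels > 0L]))
    n_border_dropped <- 0L
    if (length(ids)) {
        idx_all <- which(labels > 0L)
        lv <- labels[idx_all]
        r <- (idx_all - 1L) %% nr + 1L; cc <- (idx_all - 1L) %/% nr + 1L
        touches <- vapply(split(r == 1L | r == nr, lv), any, logical(1)) |
                   vapply(split(cc == 1L | cc == nc, lv), any, logical(1))
        if (drop_border && any(touches)) {
            drop_ids <- as.integer(names(touches))[touches]
            n_border_dropped <- length(drop_ids)
            keep <- !(lv %in% drop_ids)
            labels[idx_all[!keep]] <- 0L
            idx_all <- idx_all[keep]; lv <- lv[keep]
            r <- r[keep]; cc <- cc[keep]
            ids <- setdiff(ids, drop_ids)
            touches <- touches[as.character(ids)]
        }
    }
    if (!length(ids)) {
        return(structure(list(label_image = matrix(0L, nr, nc),
                              objects = data.frame(id = integer(0),
                                                   n_px = integer(0),
                                                   area_um2 = numeric(0),
                                                   touches_border = logical(0),
                                                   r0 = integer(0), r1 = integer(0),
                                                   c0 = integer(0), c1 = integer(0)),
                              pixel_size = ps,
                              n_border_dropped = n_border_dropped),
                         class = "labeled_objects"))
    }
    new_id <- match(lv, ids)
    out_labels <- matrix(0L, nr, nc)
    out_labels[idx_all] <- new_id
    obj <- data.frame(
        id = seq_along(ids),
        n_px = as.integer(tabulate(new_id, nbins = length(ids))),
        touches_border = as.logical(touches),
        r0 = as.integer(vapply(split(r, new_id), min, numeric(1))) - 1L,
        r1 = as.integer(vapply(split(r, new_id), max, numeric(1))) - 1L,
        c0 = as.integer(vapply(split(cc, new_id), min, numeric(1))) - 1L,
        c1 = as.integer(vapply(split(cc, new_id), max, numeric(1))) - 1L)
    obj$area_um2 <- obj$n_px * ps^2
    obj <- obj[, c("id", "n_px", "area_um2", "touches_border",
                   "r0", "r1", "c0", "c1")]
    structure(list(label_image = out_labels, objects = obj, pixel_size = ps,
                   n_border_dropped = n_border_dropped),
              class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
    cat(sprintf("<labeled_objects> %d objects (%d border-dropped), %d x %d px\n",
                nrow(x$objects), x$n_border_dropped,
                nrow(x$label_image), ncol(x$label_image)))
    invisible(x)
}

#' Match segmented objects to simulator ground truth
#'
#' Greedy one-to-one matching of predicted objects to ground-truth cells by
#' descending pixel overlap; a pair is accepted as a true positive when its
#' Jaccard index (|intersection| / |union|) reaches `jaccard_min`.
#' Unmatched predictions are false positives, unmatched truth cells are
#' misses.
#'
#' @param pred a `labeled_objects` or integer label image.
#' @param truth_labels integer ground-truth label image (e.g. from
#'   [simulate_field()]).
#' @param jaccard_min minimum Jaccard for a valid match.
#' @return list: `pairs` (data.frame `pred_id`, `truth_id`, `overlap`,
#'   `jaccard`), `precision`, `recall`, `mean_jaccard`.
#' @export
match_to_truth <- function(pred, truth_labels, jaccard_min = 0.3) {
    pl <- if (inherits(pred, "labeled_objects")) pred$label_image else pred
    if (!all(dim(pl) == dim(truth_labels)))
        stop("prediction and truth label images have different shapes")
    np <- length(unique(pl[pl > 0L]))
    nt <- length(unique(truth_labels[truth_labels > 0L]))
    empty <- data.frame(pred_id = integer(0), truth_id = integer(0),
                        overlap = integer(0), jaccard = numeric(0))
    if (np == 0L || nt == 0L)
        return(list(pairs = empty, precision = if (np) 0 else NA_real_,
                    recall = if (nt) 0 else NA_real_,
                    mean_jaccard = NA_real_))
    both <- pl > 0L & truth_labels > 0L
    ov <- as.data.frame(table(pred = pl[both], truth = truth_labels[both]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0L, ]
    ov$pred <- as.integer(ov$pred); ov$truth <- as.integer(ov$truth)
    sz_p <- tabulate(pl[pl > 0L], nbins = max(pl))
    sz_t <- tabulate(truth_labels[truth_labels > 0L], nbins = max(truth_labels))
    ov$jaccard <- ov$Freq / (sz_p[ov$pred] + sz_t[ov$truth] - ov$Freq)
    ov <- ov[order(-ov$Freq), ]
    used_p <- integer(0); used_t <- integer(0)
    keep <- logical(nrow(ov))
    for (i in seq_len(nrow(ov))) {
        if (ov$pred[i] %in% used_p || ov$truth[i] %in% used_t) next
        if (ov$jaccard[i] < jaccard_min) next
        keep[i] <- TRUE
        used_p <- c(used_p, ov$pred[i]); used_t <- c(used_t, ov$truth[i])
    }
    pairs <- data.frame(pred_id = ov$pred[keep], truth_id = ov$truth[keep],
                        overlap = ov$Freq[keep], jaccard = ov$jaccard[keep])
    list(pairs = pairs,
         precision = nrow(pairs) / np,
         recall = nrow(pairs) / nt,
         mean_jaccard = if (nrow(pairs)) mean(pairs$jaccard) else NA_real_)
}
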