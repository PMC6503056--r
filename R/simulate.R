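## Seeded synthetic-plate simulator: renders Hoechst-channel nuclei for the
## three phenotypes (lobulated resting, spread lytic-NETotic, condensed
## apoptotic), assembles fields and plates with ground truth, and generates
## ROS / TMRM kinetic traces.

#' Default phenotype rendering parameters
#'
#' Encodes the assay's phenomenology: a resting neutrophil nucleus is a
#' 3-5-lobed object of roughly 30-50 um^2; a lytic NETotic nucleus is a
#' single grossly enlarged, dim, diffuse chromatin region with an irregular
#' filamentous margin (`chromatin_spread` times the resting area); an
#' apoptotic nucleus is smaller than resting but markedly brighter and
#' compact. Intensities are 16-bit camera units.
#'
#' @param chromatin_spread NETotic area enlargement factor (>= 1).
#' @return named list of per-phenotype parameter lists.
#' @export
phenotype_presets <- function(chromatin_spread = 3.8) {
    p <- list(
        resting = list(phenotype = "resting", area_mean = 42, area_sd = 6,
                       peak_intensity = 3000, lobe_range = c(3L, 5L),
                       texture_granularity = 0.25),
        netotic = list(phenotype = "netotic",
                       area_mean = 42 * chromatin_spread,
                       area_sd = 42 * chromatin_spread * 0.25,
                       area_min = 2 * 42,  # lytic spread is >= 2x resting
                       peak_intensity = 1100,
                       chromatin_spread = chromatin_spread,
                       n_filaments = c(4L, 8L),
                       texture_granularity = 0.45),
        apoptotic = list(phenotype = "apoptotic", area_mean = 24, area_sd = 4,
                         peak_intensity = 6500, texture_granularity = 0.15))
    stopifnot(p$apoptotic$area_mean < p$resting$area_mean,
              p$resting$area_mean < p$netotic$area_mean,
              p$apoptotic$peak_intensity > p$resting$peak_intensity,
              p$netotic$peak_intensity < p$resting$peak_intensity)
    p
}

# Fraction of the peak that defines the ground-truth chromatin mask.
.mask_frac <- 0.15

# sigma (px) of a single Gaussian whose area above .mask_frac of peak is A px.
.sigma_for_area <- function(area_px) sqrt(area_px / (2 * pi * log(1 / .mask_frac)))

#' Render one synthetic nucleus
#'
#' Draws a noise-free intensity patch and its ground-truth chromatin mask
#' for one phenotype. Resting nuclei are sums of 3-5 partially overlapping
#' anisotropic Gaussian lobes; NETotic nuclei are a large dim diffuse core
#' with curvilinear filament strokes at the margin; apoptotic nuclei are a
#' single small bright blob. The mask is the set of pixels above 10% of
#' the patch peak. Deterministic for a fixed seed.
#'
#' @param params one element of [phenotype_presets()].
#' @param pixel_size micrometres per pixel.
#' @param seed RNG seed (NULL = use current stream).
#' @return list: `patch` (numeric matrix), `mask` (logical), `phenotype`.
#' @export
render_nucleus <- function(params, pixel_size = 0.6, seed = NULL) {
    if (is.null(params$phenotype) || !params$phenotype %in% .phenotypes)
        stop("unknown phenotype: ", params$phenotype)
    with_seed(seed, {
        area_um <- max(params$area_min %||% (params$area_mean * 0.4),
                       rnorm(1, params$area_mean, params$area_sd))
        area_px <- area_um / pixel_size^2
        grain <- params$texture_granularity %||% 0.25
        amp <- params$peak_intensity
        blobs <- switch(params$phenotype,
            resting = {
                k <- sample(seq(params$lobe_range[1L], params$lobe_range[2L]), 1L)
                s <- .sigma_for_area(area_px / k) * 1.35
                ring <- s * 1.5
                ang0 <- runif(1, 0, 2 * pi)
                do.call(rbind, lapply(seq_len(k), function(i) {
                    a <- ang0 + 2 * pi * (i - 1) / k + rnorm(1, 0, 0.25)
                    rr <- ring * runif(1, 0.8, 1.2)
                    c(rr * cos(a), rr * sin(a),
                      s * runif(1, 0.85, 1.15), s * runif(1, 0.7, 1.0),
                      runif(1, 0, pi), amp * runif(1, 1 - grain, 1 + grain))
                }))
            },
            netotic = {
                s <- .sigma_for_area(area_px * 1.3)
                core <- rbind(c(0, 0, s, s * runif(1, 0.85, 1), runif(1, 0, pi),
                                amp))
                nsub <- 4L
                sub <- do.call(rbind, lapply(seq_len(nsub), function(i) {
                    a <- runif(1, 0, 2 * pi); rr <- s * runif(1, 0.3, 0.9)
                    c(rr * cos(a), rr * sin(a), s * runif(1, 0.35, 0.6),
                      s * runif(1, 0.3, 0.5), runif(1, 0, pi),
                      amp * grain * runif(1, 0.5, 1.5))
                }))
                nf <- sample(seq(params$n_filaments[1L], params$n_filaments[2L]), 1L)
                fil <- do.call(rbind, lapply(seq_len(nf), function(i) {
                    a <- runif(1, 0, 2 * pi)
                    len <- s * runif(1, 1.2, 2.2)
                    steps <- max(3L, ceiling(len / 1.5))
                    pos <- c(0.8 * s * cos(a), 0.8 * s * sin(a))
                    dirv <- c(cos(a), sin(a))
                    t(vapply(seq_len(steps), function(j) {
                        a2 <- atan2(dirv[2], dirv[1]) + rnorm(1, 0, 0.35)
                        dirv <<- c(cos(a2), sin(a2))
                        pos <<- pos + dirv * 1.5
                        c(pos[1], pos[2], 1.3, 1.0, a2,
                          amp * 0.45 * (1 - j / (steps + 1)))
                    }, numeric(6)))
                }))
                rbind(core, sub, fil)
            },
            apoptotic = {
                s <- .sigma_for_area(area_px)
                rbind(c(0, 0, s * runif(1, 0.95, 1.05), s * runif(1, 0.8, 1),
                        runif(1, 0, pi), amp),
                      c(runif(1, -s, s) * 0.4, runif(1, -s, s) * 0.4,
                        s * 0.5, s * 0.4, runif(1, 0, pi), amp * grain))
            })
        ext <- ceiling(max(abs(blobs[, 1:2])) + 4 * max(blobs[, 3]))
        n <- 2L * ext + 1L
        blobs[, 1L] <- blobs[, 1L] + ext
        blobs[, 2L] <- blobs[, 2L] + ext
        patch <- cpp_render_blobs(n, n, blobs)
        mask <- patch > .mask_frac * max(patch)
        # keep only the component containing the peak (stray filament tips
        # must not create detached truth objects)
        lab <- EBImage::bwlabel(mask)
        peak <- which.max(patch)
        if (lab[peak] > 0) mask <- lab == lab[peak]
        list(patch = patch, mask = mask,
             halo = patch > 0.05 * max(patch),  # low isophote: the dim skirt
             phenotype = params$phenotype)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one microscope field with ground truth
#'
#' Places `n_cells` nuclei (phenotypes drawn independently with the given
#' fractions) with rejection of excessive mask overlap, then adds a
#' background offset, Poisson shot noise and Gaussian read noise, and
#' quantizes to 16-bit. The ground truth records every cell's phenotype and
#' mask.
#'
#' @param n_cells number of nuclei (>= 0).
#' @param fractions length-3 numeric `(resting, netotic, apoptotic)` summing
#'   to 1.
#' @param width,height field size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param background additive background offset (camera units).
#' @param read_noise_sd Gaussian read noise sd (camera units).
#' @param shot_noise logical; apply Poisson noise to background + signal.
#' @param max_overlap maximum tolerated fraction of a new nucleus's mask
#'   overlapping already-placed nuclei; candidate positions are re-drawn up
#'   to 40 times and the least-overlapping candidate is used.
#' @param presets phenotype presets (see [phenotype_presets()]).
#' @param seed RNG seed.
#' @param well_id,field_index,time metadata stamped on the output image.
#' @return list: `image` (a nuclear `field_image`), `truth` (data.frame
#'   `cell_id`, `phenotype`, `row`, `col`, `area_px`), `truth_labels`
#'   (integer matrix; 0 = background, cell_id elsewhere).
#' @export
simulate_field <- function(n_cells, fractions = c(0.98, 0.01, 0.01),
                           width = 1024L, height = 1024L, pixel_size = 0.6,
                           background = 200, read_noise_sd = 30,
                           shot_noise = TRUE, max_overlap = 0.05,
                           presets = phenotype_presets(), seed = NULL,
                           well_id = "A01", field_index = 0L, time = 0) {
    if (n_cells < 0) stop("n_cells must be >= 0")
    if (length(fractions) != 3L || any(fractions < -1e-9) ||
        abs(sum(fractions) - 1) > 1e-6)
        stop("fractions must be 3 non-negative numbers summing to 1")
    fractions <- pmax(fractions, 0)
    with_seed(seed, {
        canvas <- matrix(0, height, width)
        truth_labels <- matrix(0L, height, width)
        occupied <- matrix(FALSE, height, width)
        labels <- if (n_cells > 0)
            sample(.phenotypes, n_cells, replace = TRUE, prob = fractions)
        else character(0)
        truth <- vector("list", n_cells)
        for (i in seq_len(n_cells)) {
            nuc <- render_nucleus(presets[[labels[i]]], pixel_size)
            np <- nrow(nuc$patch)
            if (np >= height - 4L || np >= width - 4L) next
            best <- NULL; best_ov <- Inf
            for (try in 1:40) {
                r0 <- sample.int(height - np - 2L, 1L) + 1L
                c0 <- sample.int(width - np - 2L, 1L) + 1L
                # reject on overlap of the dim skirts, which is what bridges
                # adjacent nuclei after thresholding
                ov <- sum(occupied[r0:(r0 + np - 1L), c0:(c0 + np - 1L)] &
                          nuc$halo) / sum(nuc$mask)
                if (ov < best_ov) { best_ov <- ov; best <- c(r0, c0) }
                if (ov <= max_overlap) break
            }
            r0 <- best[1L]; c0 <- best[2L]
            cpp_paste_add(canvas, nuc$patch, r0 - 1L, c0 - 1L)
            sub_r <- r0:(r0 + np - 1L); sub_c <- c0:(c0 + np - 1L)
            occ <- occupied[sub_r, sub_c]
            tl <- truth_labels[sub_r, sub_c]
            newpx <- nuc$mask & tl == 0L
            tl[newpx] <- i
            truth_labels[sub_r, sub_c] <- tl
            occupied[sub_r, sub_c] <- occ | nuc$halo
            ctr <- colMeans(which(nuc$mask, arr.ind = TRUE))
            truth[[i]] <- data.frame(cell_id = i, phenotype = labels[i],
                                     row = r0 - 1L + ctr[1L] - 1,
                                     col = c0 - 1L + ctr[2L] - 1,
                                     area_px = sum(nuc$mask))
        }
        lambda <- canvas + background
        px <- if (shot_noise)
            matrix(rpois(length(lambda), lambda), height, width)
        else lambda
        if (read_noise_sd > 0)
            px <- px + matrix(rnorm(length(px), 0, read_noise_sd),
                              height, width)
        px <- pmin(pmax(round(px), 0), 65535)
        truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
        if (is.null(truth))
            truth <- data.frame(cell_id = integer(0), phenotype = character(0),
                                row = numeric(0), col = numeric(0),
                                area_px = integer(0))
        list(image = field_image(px, "nuclear", pixel_size, well_id,
                                 field_index, time),
             truth = truth, truth_labels = truth_labels)
    })
}

#' Default stimulus / inhibition response law
#'
#' The per-well true NETotic fraction is
#' `baseline + (induced(t) - baseline) * (1 - inhibition(c))`.
#' `induced(t)` is a Hill-in-time curve per stimulus calibrated to the
#' assay's phenomenology: spontaneous NETosis ~1%, PMA reaching 70% at its
#' 210-min endpoint with a slow sigmoidal onset, ionomycin reaching 70% at
#' 90 min and already >60% by 45 min. `inhibition(c)` is a Hill curve in
#' compound concentration, `max_inhibition / (1 + (ec50/c)^hill)`.
#'
#' @param baseline spontaneous NETotic fraction.
#' @param pma,ionomycin lists with `fmax`, `t50` (min), `hill`.
#' @param t_max upper end of the law's time domain (min).
#' @return object of class `response_law`.
#' @export
response_law <- function(baseline = 0.01,
                         pma = list(fmax = 0.72, t50 = 64, hill = 3),
                         ionomycin = list(fmax = 0.72, t50 = 15, hill = 2),
                         t_max = 240) {
    structure(list(baseline = baseline, pma = pma, ionomycin = ionomycin,
                   t_max = t_max), class = "response_law")
}

#' Stimulus-induced NETotic fraction at time t
#' @param law a [response_law()].
#' @param stimulus `"none"`, `"PMA"` or `"ionomycin"`.
#' @param t time in minutes, within the law's domain.
#' @return fraction in [0, 1].
#' @export
induced_frac <- function(law, stimulus, t) {
    if (any(t < 0) || any(t > law$t_max))
        stop("timepoint ", paste(t[t < 0 | t > law$t_max], collapse = ", "),
             " outside the response law's domain [0, ", law$t_max, "] min")
    stimulus <- match.arg(stimulus, .stimuli)
    if (stimulus == "none") return(rep(law$baseline, length(t)))
    p <- if (stimulus == "PMA") law$pma else law$ionomycin
    x <- (t / p$t50)^p$hill
    pmax(law$baseline, p$fmax * x / (1 + x))
}

#' Hill inhibition of induction by a compound
#' @param inh list with `ec50` (uM), `hill`, `max_inhibition`; NULL means
#'   inactive (returns 0).
#' @param conc concentration in uM (>= 0).
#' @return inhibition fraction in [0, 1], monotone non-decreasing in `conc`.
#' @export
hill_inhibition <- function(inh, conc) {
    if (is.null(inh)) return(rep(0, length(conc)))
    ifelse(conc <= 0, 0,
           inh$max_inhibition / (1 + (inh$ec50 / conc)^inh$hill))
}

#' Default compound-effect table for the simulator
#'
#' A "capsaicin-like" full inhibitor (EC50 1.5 uM, Hill 2, complete
#' inhibition) used for dose-response recovery; any compound absent from
#' the list is inactive.
#' @return named list of inhibition parameter lists.
#' @export
compound_effects <- function() {
    list(capsaicin_like = list(ec50 = 1.5, hill = 2, max_inhibition = 1))
}

#' True NETotic fraction of one layout well
#' @param law a [response_law()].
#' @param well one-row data.frame from a `plate_layout`.
#' @param compounds named list of inhibition parameters
#'   (see [compound_effects()]).
#' @return fraction in [0, 1].
#' @export
well_true_fraction <- function(law, well, compounds = compound_effects()) {
    f_ind <- induced_frac(law, well$stimulus, well$timepoint_min)
    inh <- if (nzchar(well$compound_id))
        hill_inhibition(compounds[[well$compound_id]], well$compound_conc)
    else 0
    law$baseline + (f_ind - law$baseline) * (1 - inh)
}

#' Simulate all fields of one well
#'
#' Applies the response law to the well's treatment, jitters the true
#' fraction with a tight Beta-distributed inter-well effect (concentration
#' `jitter_kappa`; the screening plates behind this assay had very small
#' control-well spread, cf. Z' ~0.9), then simulates `n_fields` fields.
#' A small constant apoptotic fraction is mixed in.
#'
#' @param well one-row data.frame from a `plate_layout`.
#' @param law a [response_law()].
#' @param compounds named list of compound inhibition parameters.
#' @param n_fields fields per well.
#' @param cells_per_field nuclei per field.
#' @param apoptotic_frac constant apoptotic fraction.
#' @param jitter_kappa Beta concentration of the inter-well jitter
#'   (larger = tighter); 0 disables jitter.
#' @param seed RNG seed.
#' @param ... forwarded to [simulate_field()] (field geometry, noise).
#' @return list: `fields` (list of [simulate_field()] outputs), `f_true`
#'   (jittered true NETotic fraction), `f_nominal`.
#' @export
simulate_well <- function(well, law = response_law(),
                          compounds = compound_effects(), n_fields = 4L,
                          cells_per_field = 500L, apoptotic_frac = 0.02,
                          jitter_kappa = 1500, seed = NULL, ...) {
    with_seed(seed, {
        f_nom <- well_true_fraction(law, well, compounds)
        f <- if (jitter_kappa > 0)
            rbeta(1, f_nom * jitter_kappa, (1 - f_nom) * jitter_kappa)
        else f_nom
        fracs <- c(1 - f - apoptotic_frac, f, apoptotic_frac)
        fields <- lapply(seq_len(n_fields) - 1L, function(k)
            simulate_field(cells_per_field, fracs, well_id = well$well_id,
                           field_index = k, time = well$timepoint_min, ...))
        list(fields = fields, f_true = f, f_nominal = f_nom)
    })
}

#' Simulate a whole plate to disk
#'
#' Writes, per well, one 16-bit nuclear TIFF per field plus a ground-truth
#' cell table, and a plate-level manifest (JSON) recording the seed and
#' calibration. Per-well seeds are derived deterministically from `seed`.
#'
#' @param layout a `plate_layout`.
#' @param dir output directory (created if needed).
#' @inheritParams simulate_well
#' @return invisibly, a data.frame with per-well `well_id`, `f_true`,
#'   `f_nominal` and file names.
#' @export
simulate_plate <- function(layout, dir, law = response_law(),
                           compounds = compound_effects(), n_fields = 4L,
                           cells_per_field = 500L, seed = 1L, ...) {
    stopifnot(inherits(layout, "plate_layout"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(seq_len(nrow(layout)), function(i) {
        well <- layout[i, ]
        sim <- simulate_well(well, law, compounds, n_fields, cells_per_field,
                             seed = child_seed(seed, i), ...)
        files <- vapply(sim$fields, function(fd) {
            fn <- sprintf("%s_f%02d_nuclear.tif", well$well_id,
                          fd$image$field_index)
            write_image(fd$image, file.path(dir, fn))
            fn
        }, character(1))
        truth <- do.call(rbind, lapply(sim$fields, function(fd)
            cbind(well_id = well$well_id,
                  field_index = fd$image$field_index, fd$truth)))
        write.csv(truth, file.path(dir, sprintf("%s_truth.csv", well$well_id)),
                  row.names = FALSE)
        data.frame(well_id = well$well_id, f_true = sim$f_true,
                   f_nominal = sim$f_nominal,
                   files = paste(files, collapse = ";"))
    })
    out <- do.call(rbind, rows)
    jsonlite::write_json(list(seed = seed, n_fields = n_fields,
                              cells_per_field = cells_per_field,
                              wells = out$well_id),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
    write.csv(out, file.path(dir, "plate_truth.csv"), row.names = FALSE)
    invisible(out)
}

#' Kinetic channel presets
#'
#' ROS (DCF) fold-change follows `1 + (A - 1)(1 - exp(-t/tau))`: the PMA
#' preset plateaus at 6-fold with tau = 20 min (95% of plateau at
#' -tau ln 0.05 = 59.9 min); vehicle and ionomycin presets stay near 1.
#' TMRM accumulation is `1 + d * M * (1 - exp(-t/tau))` where `d` scales
#' with mitochondrial polarization: 1 for vehicle (intact), 0.2 for
#' uncoupled/depolarized mitochondria (CCCP, ionomycin, alexidine).
#'
#' @return nested list with `ros` and `tmrm` preset parameters.
#' @export
kinetic_presets <- function() {
    list(ros = list(pma = list(A = 6, tau = 20),
                    vehicle = list(A = 1.05, tau = 60),
                    ionomycin = list(A = 1.1, tau = 60)),
         tmrm = list(vehicle = list(d = 1, M = 5, tau = 25),
                     cccp = list(d = 0.2, M = 5, tau = 25),
                     ionomycin = list(d = 0.2, M = 5, tau = 25),
                     alexidine = list(d = 0.2, M = 5, tau = 25)))
}

.make_trace <- function(value, timepoints, noise_sd, channel) {
    structure(data.frame(time = timepoints, value = value),
              class = c("kinetic_trace", "data.frame"), channel = channel,
              noise_sd = noise_sd)
}

#' Simulate a cytosolic-ROS (DCF) fold-change trace
#' @param preset `"pma"`, `"vehicle"` or `"ionomycin"`.
#' @param timepoints sorted minutes within [0, 120].
#' @param noise_sd additive Gaussian noise per timepoint (fold units).
#' @param seed RNG seed.
#' @return a `kinetic_trace` data.frame with `time`, `value`.
#' @export
simulate_ros_trace <- function(preset = "pma", timepoints = seq(0, 120, 5),
                               noise_sd = 0.05, seed = NULL) {
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (is.unsorted(timepoints, strictly = TRUE) ||
        any(timepoints < 0) || any(timepoints > 120))
        stop("timepoints must be strictly increasing within [0, 120] min")
    p <- kinetic_presets()$ros[[match.arg(preset, c("pma", "vehicle",
                                                    "ionomycin"))]]
    with_seed(seed, {
        v <- 1 + (p$A - 1) * (1 - exp(-timepoints / p$tau))
        if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
        .make_trace(v, timepoints, noise_sd, "ros")
    })
}

#' Simulate a TMRM mitochondrial-accumulation trace
#' @param preset `"vehicle"`, `"cccp"`, `"ionomycin"` or `"alexidine"`.
#' @param timepoints sorted minutes within [0, 60].
#' @inheritParams simulate_ros_trace
#' @return a `kinetic_trace` data.frame with `time`, `value`.
#' @export
simulate_tmrm_trace <- function(preset = "vehicle", timepoints = seq(0, 60, 5),
                                noise_sd = 0.05, seed = NULL) {
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (is.unsorted(timepoints, strictly = TRUE) ||
        any(timepoints < 0) || any(timepoints > 60))
        stop("timepoints must be strictly increasing within [0, 60] min")
    p <- kinetic_presets()$tmrm[[match.arg(preset, c("vehicle", "cccp",
                                                     "ionomycin",
                                                     "alexidine"))]]
    with_seed(seed, {
        v <- 1 + p$d * p$M * (1 - exp(-timepoints / p$tau))
        if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
        .make_trace(v, timepoints, noise_sd, "tmrm")
    })
}
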