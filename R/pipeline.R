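## End-to-end pipeline: simulate or load a well, segment every field,
## extract features, classify, and summarize. These wrappers keep only one
## field in memory at a time so whole-plate screens stay within desk-scale
## memory.

#' Segment and profile one field
#'
#' @param img a nuclear-channel `field_image`.
#' @param seg_params list of overrides for [segment_nuclei()].
#' @param ... forwarded to [extract_features()].
#' @return list: `objects` (a `labeled_objects`), `cells` (feature
#'   data.frame with `well_id` and `field_index` columns).
#' @export
analyze_field <- function(img, seg_params = list(), ...) {
    objs <- do.call(segment_nuclei, c(list(img = img), seg_params))
    cells <- extract_features(img, objs, ...)
    if (nrow(cells)) {
        cells <- cbind(data.frame(well_id = img$well_id,
                                  field_index = img$field_index), cells)
    } else {
        cells <- cbind(data.frame(well_id = character(0),
                                  field_index = integer(0)), cells)
    }
    list(objects = objs, cells = cells)
}

#' Build a labeled training set from the simulator
#'
#' Simulates balanced-mixture fields at the default screening density,
#' segments them, matches the detected objects to the ground truth and
#' labels each matched object with its true phenotype — the stand-in for
#' the human-curated training set a real screen would use. Training at
#' application density matters: crowding changes texture features (a
#' neighbour's dim skirt adds intensity gradients), so a classifier
#' trained on isolated nuclei would be miscalibrated on real fields.
#'
#' @param n_per_class target number of labeled cells per phenotype.
#' @param cells_per_field nuclei per training field.
#' @param presets phenotype presets.
#' @param seed RNG seed.
#' @param width,height training field size, pixels.
#' @param pixel_size micrometres per pixel.
#' @return data.frame of features plus a `phenotype` column.
#' @export
make_training_set <- function(n_per_class = 300L, cells_per_field = 500L,
                              presets = phenotype_presets(), seed = 1L,
                              width = 1024L, height = 1024L,
                              pixel_size = 0.6) {
    got <- setNames(c(0L, 0L, 0L), .phenotypes)
    out <- list()
    k <- 0L
    # alternate balanced and resting-heavy compositions so every class is
    # seen both crowded by bright resting nuclei and among its own kind
    mixes <- list(rep(1 / 3, 3), c(0.78, 0.15, 0.07))
    while (any(got < n_per_class) && k < 60L) {
        k <- k + 1L
        sim <- simulate_field(cells_per_field, mixes[[k %% 2L + 1L]],
                              width = width, height = height,
                              pixel_size = pixel_size, presets = presets,
                              seed = child_seed(seed, k))
        an <- analyze_field(sim$image)
        m <- match_to_truth(an$objects, sim$truth_labels)
        if (!nrow(m$pairs)) next
        cells <- an$cells[match(m$pairs$pred_id, an$cells$cell_id), ]
        cells$phenotype <- sim$truth$phenotype[match(m$pairs$truth_id,
                                                     sim$truth$cell_id)]
        cells <- cells[!cells$touches_border, , drop = FALSE]
        for (ph in .phenotypes) {
            sub <- cells[cells$phenotype == ph, , drop = FALSE]
            take <- min(nrow(sub), n_per_class - got[[ph]])
            if (take > 0L) {
                out[[length(out) + 1L]] <- sub[seq_len(take), ]
                got[[ph]] <- got[[ph]] + take
            }
        }
    }
    if (any(got < n_per_class))
        warning("collected only ", paste(got, collapse = "/"),
                " training cells per class")
    do.call(rbind, out)
}

#' Train the default phenotype classifier from simulator ground truth
#'
#' Convenience wrapper: [make_training_set()] followed by
#' [train_classifier()].
#'
#' @inheritParams make_training_set
#' @inheritParams train_classifier
#' @return a `net_classifier`.
#' @export
train_default_classifier <- function(n_per_class = 300L, seed = 1L,
                                     kind = "rlda",
                                     presets = phenotype_presets()) {
    cells <- make_training_set(n_per_class = n_per_class, seed = seed,
                               presets = presets)
    train_classifier(cells, kind = kind, seed = seed)
}

#' Simulate and analyze one well end to end
#'
#' @param well one-row data.frame from a `plate_layout`.
#' @param model a `net_classifier`.
#' @param law,compounds,presets simulator configuration.
#' @param n_fields,cells_per_field well geometry.
#' @param seed RNG seed.
#' @param ... forwarded to [simulate_well()] (noise, jitter, geometry).
#' @return list: `cells` (classified feature table), `f_true`
#'   (the simulator's jittered true NETotic fraction), `f_nominal`,
#'   `match` (per-field detection precision/recall averaged).
#' @export
run_well <- function(well, model, law = response_law(),
                     compounds = compound_effects(),
                     presets = phenotype_presets(), n_fields = 4L,
                     cells_per_field = 500L, seed = 1L, ...) {
    sim <- simulate_well(well, law, compounds, n_fields, cells_per_field,
                         presets = presets, seed = seed, ...)
    cells <- list(); prec <- rec <- numeric(0)
    for (fd in sim$fields) {
        an <- analyze_field(fd$image)
        m <- match_to_truth(an$objects, fd$truth_labels)
        prec <- c(prec, m$precision); rec <- c(rec, m$recall)
        cells[[length(cells) + 1L]] <- an$cells
    }
    cells <- .bind_cells(cells)
    cells <- classify_cells(model, cells)
    list(cells = cells, f_true = sim$f_true, f_nominal = sim$f_nominal,
         match = c(precision = mean(prec, na.rm = TRUE),
                   recall = mean(rec, na.rm = TRUE)))
}

#' Run a full simulated screen through the pipeline
#'
#' Simulates every layout well (deterministic per-well seeds derived from
#' `seed`), runs segmentation, feature extraction and classification, and
#' returns the per-well summary table with the simulator's true fractions
#' attached for recovery checks.
#'
#' @inheritParams run_well
#' @param layout a `plate_layout`.
#' @param progress print a line per well.
#' @return data.frame: layout columns plus `n_cells`, phenotype fractions,
#'   `pct_netotic`, `f_true`, `f_nominal`, `precision`, `recall`.
#' @export
run_screen <- function(layout, model, law = response_law(),
                       compounds = compound_effects(),
                       presets = phenotype_presets(), n_fields = 4L,
                       cells_per_field = 500L, seed = 1L,
                       progress = FALSE, ...) {
    stopifnot(inherits(layout, "plate_layout"))
    rows <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
        well <- layout[i, ]
        rw <- run_well(well, model, law, compounds, presets, n_fields,
                       cells_per_field, seed = child_seed(seed, i), ...)
        s <- summarize_wells(rw$cells, plate_layout(well))
        s$f_true <- rw$f_true
        s$f_nominal <- rw$f_nominal
        s$precision <- rw$match[["precision"]]
        s$recall <- rw$match[["recall"]]
        rows[[i]] <- s
        if (progress)
            message(sprintf("well %s: n=%d pct_netotic=%.1f (true %.1f)",
                            well$well_id, s$n_cells, s$pct_netotic,
                            100 * rw$f_true))
    }
    do.call(rbind, rows)
}

#' Build a simple control + dose-series layout
#'
#' Convenience generator for simulated experiments: `n_neg` DMSO
#' negative-control wells, `n_pos` stimulated positive-control wells, and
#' an optional compound dose series (each dose replicated).
#'
#' @param n_neg,n_pos numbers of control wells.
#' @param stimulus `"PMA"` or `"ionomycin"` for positive/test wells.
#' @param timepoint endpoint in minutes (defaults: PMA 210, ionomycin 90).
#' @param compound_id,doses,n_rep optional dose series (uM).
#' @return a `plate_layout`.
#' @export
control_layout <- function(n_neg = 0L, n_pos = 0L, stimulus = "PMA",
                           timepoint = NULL, compound_id = NULL,
                           doses = numeric(0), n_rep = 1L) {
    stimulus <- match.arg(stimulus, c("PMA", "ionomycin"))
    if (is.null(timepoint)) timepoint <- if (stimulus == "PMA") 210 else 90
    stim_conc <- if (stimulus == "PMA") 100 else 5
    rows <- list()
    add <- function(role, stim, sc, cid, cc, rep)
        rows[[length(rows) + 1L]] <<- data.frame(
            role = role, stimulus = stim, stimulus_conc = sc,
            compound_id = cid, compound_conc = cc,
            timepoint_min = timepoint, replicate = rep)
    for (i in seq_len(n_neg)) add("negative_control", "none", 0, "", 0, i)
    for (i in seq_len(n_pos)) add("positive_control", stimulus, stim_conc,
                                  "", 0, i)
    if (!is.null(compound_id))
        for (d in doses) for (r in seq_len(n_rep))
            add("test", stimulus, stim_conc, compound_id, d, r)
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$well_id <- sprintf("%s%02d", LETTERS[(seq_len(n) - 1L) %/% 12L + 1L],
                          (seq_len(n) - 1L) %% 12L + 1L)
    plate_layout(df[, c("well_id", "role", "stimulus", "stimulus_conc",
                        "compound_id", "compound_conc", "timepoint_min",
                        "replicate")])
}
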