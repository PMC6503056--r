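test_that("rendering is deterministic for a fixed seed", {
    p <- phenotype_presets()
    a <- render_nucleus(p$resting, seed = 5)
    b <- render_nucleus(p$resting, seed = 5)
    expect_identical(a$patch, b$patch)
    expect_identical(a$mask, b$mask)
    expect_error(render_nucleus(list(phenotype = "zombie")), "unknown")
})

test_that("phenotype geometry and intensity orderings hold over many renders", {
    p <- phenotype_presets()
    stats <- sapply(c("resting", "netotic", "apoptotic"), function(ph) {
        area <- inten <- numeric(60)
        for (i in 1:60) {
            nuc <- render_nucleus(p[[ph]], seed = i)
            area[i] <- sum(nuc$mask)
            inten[i] <- mean(nuc$patch[nuc$mask])
        }
        c(area = mean(area), inten = mean(inten))
    })
    # netotic chromatin covers > 2x the resting mean area
    expect_gt(stats["area", "netotic"], 2 * stats["area", "resting"])
    expect_lt(stats["area", "apoptotic"], stats["area", "resting"])
    # apoptotic condensed chromatin is brighter, NETotic dimmer
    expect_gt(stats["inten", "apoptotic"], stats["inten", "resting"])
    expect_lt(stats["inten", "netotic"], stats["inten", "resting"])
})

test_that("simulate_field honours counts, fractions and determinism", {
    empty <- simulate_field(0, c(1, 0, 0), seed = 1)
    expect_equal(nrow(empty$truth), 0L)
    expect_true(all(empty$truth_labels == 0L))

    pure <- simulate_field(200, c(1, 0, 0), seed = 2)
    expect_equal(nrow(pure$truth), 200L)
    expect_true(all(pure$truth$phenotype == "resting"))

    a <- simulate_field(50, c(0.5, 0.4, 0.1), seed = 3)
    b <- simulate_field(50, c(0.5, 0.4, 0.1), seed = 3)
    expect_identical(a$image$pixels, b$image$pixels)
    expect_identical(a$truth, b$truth)

    expect_error(simulate_field(10, c(0.7, 0.7, 0.1)), "sum")
    expect_error(simulate_field(-1, c(1, 0, 0)), "n_cells")
})

test_that("empirical phenotype fractions follow the multinomial law", {
    fr <- c(0.3, 0.6, 0.1)
    counts <- matrix(0, 0, 3)
    for (s in 1:25) {
        sim <- simulate_field(400, fr, width = 512L, height = 512L,
                              seed = 100 + s)
        tab <- table(factor(sim$truth$phenotype,
                            c("resting", "netotic", "apoptotic")))
        counts <- rbind(counts, as.numeric(tab))
    }
    tot <- colSums(counts); n <- sum(tot)
    se <- sqrt(fr * (1 - fr) / n)
    expect_true(all(abs(tot / n - fr) < 3 * se + 0.005))
})

test_that("the response law reproduces its calibration anchors", {
    law <- response_law()
    # stimulated induction reaches ~70% at each stimulus endpoint
    expect_equal(induced_frac(law, "PMA", 210), 0.70, tolerance = 0.01)
    expect_equal(induced_frac(law, "ionomycin", 90), 0.70, tolerance = 0.01)
    # ionomycin is fast: > 60% already at 45 min; PMA is slow
    expect_gt(induced_frac(law, "ionomycin", 45), 0.60)
    expect_lt(induced_frac(law, "PMA", 45), 0.30)
    expect_equal(induced_frac(law, "none", 120), law$baseline)
    expect_error(induced_frac(law, "PMA", 500), "domain")
    # monotone in time
    tt <- seq(0, 210, 15)
    expect_true(all(diff(induced_frac(law, "PMA", tt)) >= 0))
})

test_that("Hill inhibition and the well mixture law agree with arithmetic", {
    inh <- list(ec50 = 1.5, hill = 2, max_inhibition = 1)
    expect_equal(hill_inhibition(inh, 0), 0)
    expect_equal(hill_inhibition(inh, 1.5), 0.5)
    expect_equal(hill_inhibition(inh, 1e6), 1, tolerance = 1e-6)
    cc <- c(0.1, 0.5, 1, 2, 5, 10)
    expect_true(all(diff(hill_inhibition(inh, cc)) > 0))

    law <- response_law()
    well <- data.frame(well_id = "A01", role = "test", stimulus = "PMA",
                       stimulus_conc = 100, compound_id = "capsaicin_like",
                       compound_conc = 1.5, timepoint_min = 210,
                       replicate = 1L)
    f <- well_true_fraction(law, well)
    f_ind <- induced_frac(law, "PMA", 210)
    expect_equal(f, law$baseline + 0.5 * (f_ind - law$baseline))
    # full inhibition limit
    well$compound_conc <- 1e9
    expect_equal(well_true_fraction(law, well), law$baseline,
                 tolerance = 1e-6)
    # negative-control wells sit at baseline
    neg <- control_layout(n_neg = 3L)
    for (i in 1:3)
        expect_equal(well_true_fraction(law, neg[i, ]), law$baseline)
})

test_that("increasing inhibitor concentration never increases the true fraction", {
    law <- response_law()
    lay <- control_layout(stimulus = "PMA", compound_id = "capsaicin_like",
                          doses = c(0, 0.3, 1, 1.5, 3, 5, 10))
    f <- vapply(seq_len(nrow(lay)), function(i)
        well_true_fraction(law, lay[i, ]), numeric(1))
    expect_true(all(diff(f) <= 1e-12))
})

test_that("kinetic presets hit their anchors and closed-form t95", {
    tr <- simulate_ros_trace("pma", noise_sd = 0, seed = 1)
    expect_equal(tr$value[tr$time == 0], 1.0)
    expect_equal(max(tr$value), 1 + 5 * (1 - exp(-120 / 20)),
                 tolerance = 1e-9)
    # 95%-of-plateau time: -tau * log(0.05) = 59.91 min for tau = 20
    t95 <- -20 * log(0.05)
    expect_equal(t95, 59.91, tolerance = 1e-3)
    expect_equal(min(tr$time[tr$value >= 1 + 5 * 0.95]), 60)

    veh <- simulate_ros_trace("vehicle", noise_sd = 0)
    expect_lt(max(veh$value), 1.1)

    tm <- simulate_tmrm_trace("vehicle", noise_sd = 0)
    dep <- simulate_tmrm_trace("cccp", noise_sd = 0)
    expect_lt(dep$value[nrow(dep)] / tm$value[nrow(tm)], 0.5)
    expect_error(simulate_ros_trace("pma", noise_sd = -1), "noise_sd")
    expect_error(simulate_ros_trace("pma", timepoints = c(5, 0, 10)))
})

test_that("plate simulation writes images, truth and manifest to disk", {
    dir <- withr::local_tempdir()
    lay <- control_layout(n_neg = 1L, n_pos = 1L, stimulus = "ionomycin")
    out <- simulate_plate(lay, dir, n_fields = 1L, cells_per_field = 40L,
                          seed = 4)
    expect_equal(nrow(out), 2L)
    expect_true(file.exists(file.path(dir, "manifest.json")))
    tif <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
    expect_length(tif, 2L)
    img <- read_image(tif[1], "nuclear")
    expect_equal(dim(img$pixels), c(1024L, 1024L))
    # positive ionomycin well carries the induced fraction, negative the baseline
    expect_lt(out$f_nominal[out$well_id == lay$well_id[1]], 0.02)
    expect_gt(out$f_nominal[out$well_id == lay$well_id[2]], 0.6)
})
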