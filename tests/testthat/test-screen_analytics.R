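test_that("zprime matches its closed form and limits", {
    # zero-variance limit
    z <- zprime(rep(70, 4), rep(1, 4))
    expect_equal(z$z_prime, 1.0)
    # hand evaluation: 1 - 3*(4 + 0.5)/68.5
    pos <- c(66, 70, 74); neg <- c(1, 1.5, 2)
    expect_equal(sd(pos), 4); expect_equal(sd(neg), 0.5)
    z <- zprime(pos, neg)
    expect_equal(z$z_prime, 1 - 13.5 / 68.5, tolerance = 1e-12)
    expect_equal(z$z_prime, 0.80292, tolerance = 1e-4)
    # random inputs against direct arithmetic
    set.seed(77)
    for (i in 1:5) {
        p <- runif(6, 50, 90); n <- runif(6, 0, 10)
        z <- zprime(p, n)
        expect_equal(z$z_prime,
                     1 - 3 * (sd(p) + sd(n)) / abs(mean(p) - mean(n)))
        expect_lte(z$z_prime, 1)
    }
    # degenerate separation
    z <- zprime(c(5, 6, 7), c(5, 6, 7))
    expect_true(z$failed)
    expect_true(is.na(z$z_prime))
    expect_error(zprime(70, c(1, 2)), "2 wells")
})

test_that("hit calling applies strict thresholds and averages replicates", {
    wells <- data.frame(compound_id = c("a", "b", "c", "d", "d"),
                        pct_netotic = c(45, 8, 50, 60, 40))
    hits <- call_hits(wells)
    expect_equal(hits$active[hits$compound_id == "a"], TRUE)
    expect_equal(hits$strong[hits$compound_id == "a"], FALSE)
    expect_true(all(hits[hits$compound_id == "b", c("active", "strong")] == TRUE))
    # exactly 50 is NOT active (strict below)
    expect_false(hits$active[hits$compound_id == "c"])
    # replicates averaged: (60+40)/2 = 50 -> not active
    expect_equal(hits$pct_netotic[hits$compound_id == "d"], 50)
    expect_false(hits$active[hits$compound_id == "d"])
    # strong implies active at any threshold pair
    expect_true(all(!hits$strong | hits$active))
    expect_error(call_hits(data.frame(compound_id = "x", pct_netotic = 120)),
                 "0, 100")

    # monotone non-increasing hit count in the active threshold
    set.seed(3)
    w <- data.frame(compound_id = letters[1:20],
                    pct_netotic = runif(20, 0, 100))
    counts <- vapply(c(20, 40, 60, 80),
                     function(th) sum(call_hits(w, th)$active), numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("4PL fits recover exact parameters and flag degeneracy", {
    conc <- c(0, 0.1, 0.3, 1, 2, 3, 5, 10)
    resp <- 1 + (70 - 1) / (1 + (conc / 2)^2)
    fit <- fit_dose_response(conc, resp)
    expect_true(fit$converged)
    expect_equal(fit$bottom, 1, tolerance = 1e-6)
    expect_equal(fit$top, 70, tolerance = 1e-6)
    expect_equal(fit$ec50, 2, tolerance = 1e-6)
    expect_equal(fit$hill, 2, tolerance = 1e-6)
    expect_false(fit$extrapolated)

    flat <- fit_dose_response(conc, rep(42, length(conc)))
    expect_true(flat$degenerate)
    expect_true(is.na(flat$ec50))

    expect_error(fit_dose_response(c(0, 1, 2), c(1, 2, 3)), "4 distinct")
})

test_that("4PL multi-start agreement: exact data is recovered from any start", {
    # steep and shallow curves, noise-free
    for (hill in c(0.8, 3)) for (ec50 in c(0.5, 4)) {
        conc <- c(0, 0.2, 0.5, 1, 2, 5, 10)
        resp <- 5 + 60 / (1 + (conc / ec50)^hill)
        fit <- fit_dose_response(conc, resp)
        expect_equal(fit$ec50, ec50, tolerance = 1e-5)
        expect_equal(fit$hill, hill, tolerance = 1e-4)
    }
})

test_that("EC50 recovery from a seeded noisy synthetic dose series", {
    # capsaicin-like preset through the response law at the well level
    law <- response_law()
    inh <- compound_effects()$capsaicin_like
    doses <- c(0, 0.5, 1, 2, 5, 10)
    set.seed(424)
    conc <- rep(doses, each = 3)
    truth <- 100 * vapply(conc, function(cc) {
        f <- induced_frac(law, "PMA", 210)
        law$baseline + (f - law$baseline) * (1 - hill_inhibition(inh, cc))
    }, numeric(1))
    resp <- truth + rnorm(length(conc), 0, 3)
    fit <- fit_dose_response(conc, resp)
    expect_true(fit$converged)
    expect_gte(fit$ec50, 1); expect_lte(fit$ec50, 2)
})

test_that("kinetic summaries recover plateau and steady-state time", {
    tm <- seq(0, 120, 5)
    tr <- data.frame(time = tm, value = 1 + 5 * (1 - exp(-tm / 20)))
    s <- summarize_kinetics(tr)
    expect_equal(s$plateau, 6, tolerance = 1e-6)
    # closed form -tau ln 0.05 = 59.91 -> first sample at 60 min
    expect_equal(s$t_steady, 60)
    expect_equal(s$peak_fold, max(tr$value), tolerance = 1e-9)

    const <- data.frame(time = tm, value = rep(3, length(tm)))
    s0 <- summarize_kinetics(const)
    expect_equal(s0$peak_fold, 1)
    expect_equal(s0$t_steady, 0)

    expect_error(summarize_kinetics(data.frame(time = c(0, 10, 5, 20, 30),
                                               value = 1:5)), "sorted")
    expect_error(summarize_kinetics(tr[1:3, ]), "5 timepoints")
})

test_that("baseline-relative kinetics report the stimulated/unstimulated ratio", {
    pma <- simulate_ros_trace("pma", noise_sd = 0)
    veh <- simulate_ros_trace("vehicle", noise_sd = 0)
    s <- summarize_kinetics(pma, baseline = veh)
    expect_gt(s$peak_fold, 5)
    expect_lt(s$peak_fold, 6.5)

    tmv <- simulate_tmrm_trace("vehicle", noise_sd = 0)
    tmd <- simulate_tmrm_trace("cccp", noise_sd = 0)
    sv <- summarize_kinetics(tmv); sd_ <- summarize_kinetics(tmd)
    expect_lt(sd_$final_value / sv$final_value, 0.5)
})

test_that("ANOVA + Dunnett handles identical groups and flags real shifts", {
    vals <- rep(c(1, 2, 3), 3)
    grp <- rep(c("ctrl", "a", "b"), each = 3)
    out <- compare_groups(vals, grp, "ctrl", n_mc = 2e4, seed = 2)
    expect_equal(out$f, 0)
    expect_false(any(out$comparisons$reject))

    # all-constant input: F defined as 0, no rejections
    out0 <- compare_groups(rep(5, 9), grp, "ctrl", n_mc = 2e4, seed = 2)
    expect_equal(out0$f, 0)
    expect_false(any(out0$comparisons$reject))

    set.seed(11)
    vals <- c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 6))
    grp <- rep(c("ctrl", "a", "b"), each = 8)
    out <- compare_groups(vals, grp, "ctrl", n_mc = 5e4, seed = 3)
    expect_true(out$comparisons$reject[out$comparisons$group == "b"])
    expect_error(compare_groups(vals, grp, "zz"), "zz")
})

test_that("the Monte-Carlo Dunnett critical value is close to the t-based bound", {
    # k = 1 comparison reduces to an ordinary two-sample t test: the
    # Dunnett critical value must match qt within Monte-Carlo error
    cr <- dunnett_crit(10, 10, alpha = 0.05, n_mc = 2e5, seed = 4)
    expect_equal(cr$crit, qt(0.975, 18), tolerance = 0.02)
    # more comparisons widen the bound
    cr3 <- dunnett_crit(10, c(10, 10, 10), alpha = 0.05, n_mc = 1e5, seed = 4)
    expect_gt(cr3$crit, cr$crit)
})
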