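# Synthetic, cheaply separable feature tables for classifier unit tests;
# the full imaging pipeline is exercised in test-acceptance.R.
make_blobs <- function(n, centers, sd = 0.5, seed = 1) {
    set.seed(seed)
    out <- do.call(rbind, lapply(names(centers), function(k) {
        mu <- centers[[k]]
        data.frame(area_um2 = rnorm(n, mu[1], sd * 10),
                   int_mean = rnorm(n, mu[2], sd * 100),
                   har_contrast = rnorm(n, mu[3], sd),
                   phenotype = k)
    }))
    out
}

test_that("a separable two-cluster problem is learned perfectly", {
    cells <- make_blobs(50, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8)))
    model <- train_classifier(cells, features = c("area_um2", "int_mean",
                                                  "har_contrast"), seed = 3)
    expect_equal(model$cv_accuracy, 1.0)
    pred <- classify_cells(model, cells)
    # training examples fed back: the discriminant reproduces every
    # training label; the lytic gate may additionally flag the marginal
    # ~10% of netotic cells below its percentile bounds (by construction)
    disc <- ifelse(pred$score_netotic >= pred$score_resting,
                   "netotic", "resting")
    expect_equal(disc, cells$phenotype)
    expect_equal(pred$phenotype_call[!pred$net_like_nonlytic],
                 cells$phenotype[!pred$net_like_nonlytic])
    expect_lte(mean(pred$net_like_nonlytic), 0.12)
})

test_that("identical class distributions score at chance level", {
    set.seed(9)
    n <- 250
    cells <- data.frame(area_um2 = rnorm(2 * n, 100, 20),
                        int_mean = rnorm(2 * n, 1500, 200),
                        har_contrast = rnorm(2 * n, 15, 3),
                        phenotype = rep(c("resting", "apoptotic"), each = n))
    model <- train_classifier(cells, features = c("area_um2", "int_mean",
                                                  "har_contrast"), seed = 5)
    expect_lt(abs(model$cv_accuracy - 0.5), 0.10)
})

test_that("training validates inputs and drops degenerate features", {
    cells <- make_blobs(30, list(resting = c(40, 2500, 20)))
    expect_error(train_classifier(cells), "2 classes")
    two <- make_blobs(4, list(resting = c(40, 2500, 20),
                              netotic = c(160, 1000, 8)))
    expect_error(train_classifier(two), "10 examples")

    cells <- make_blobs(30, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8)))
    cells$dead_feature <- 7
    expect_warning(
        model <- train_classifier(cells,
                                  features = c("area_um2", "int_mean",
                                               "dead_feature"), seed = 2),
        "zero-variance")
    expect_false("dead_feature" %in% model$features)
})

test_that("classify is deterministic, pure, and names missing features", {
    cells <- make_blobs(40, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8)))
    model <- train_classifier(cells, features = c("area_um2", "int_mean",
                                                  "har_contrast"), seed = 7)
    a <- classify_cells(model, cells)
    b <- classify_cells(model, cells)
    expect_identical(a, b)
    expect_error(classify_cells(model, cells[, c("area_um2", "int_mean")]),
                 "har_contrast")
})

test_that("the lytic gate relabels small NET-like cells and never raises pct_netotic", {
    cells <- make_blobs(40, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8)))
    model <- train_classifier(cells, features = c("area_um2", "int_mean",
                                                  "har_contrast"), seed = 7)
    # a cell with a netotic signature but area below the gate minimum
    probe <- data.frame(area_um2 = model$gate$area_min - 20,
                        int_mean = 1000, har_contrast = 8)
    out <- classify_cells(model, probe)
    expect_false(out$phenotype_call == "netotic")
    expect_true(out$net_like_nonlytic)

    # relabeling can only decrease the netotic fraction
    pred <- classify_cells(model, cells)
    raw_net <- sum(pmax(pred$score_netotic, -Inf) >=
                   pmax(pred$score_resting, -Inf))
    expect_lte(sum(pred$phenotype_call == "netotic"), raw_net)
})

test_that("classifier JSON serialization round-trips losslessly", {
    cells <- make_blobs(40, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8),
                                 apoptotic = c(25, 6000, 40)))
    model <- train_classifier(cells, features = c("area_um2", "int_mean",
                                                  "har_contrast"), seed = 7)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_classifier(model, tmp)
    back <- read_classifier(tmp)
    expect_equal(back$center, model$center)
    expect_equal(back$gate$area_min, model$gate$area_min)
    p1 <- classify_cells(model, cells)
    p2 <- classify_cells(back, cells)
    expect_equal(p1$phenotype_call, p2$phenotype_call)
    expect_equal(p1$score_netotic, p2$score_netotic)
})

test_that("the logistic alternative also separates the phenotypes", {
    cells <- make_blobs(60, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8),
                                 apoptotic = c(25, 6000, 40)))
    model <- train_classifier(cells, kind = "logistic",
                              features = c("area_um2", "int_mean",
                                           "har_contrast"), seed = 7)
    expect_gte(model$cv_accuracy, 0.95)
})

test_that("well summaries compute fractions, exclusions and errors correctly", {
    lay <- control_layout(n_neg = 2L)
    cells <- data.frame(well_id = rep(lay$well_id[1], 100),
                        phenotype_call = rep(c("netotic", "resting"),
                                             c(70, 30)),
                        touches_border = FALSE,
                        net_like_nonlytic = FALSE)
    s <- summarize_wells(cells, lay)
    expect_equal(s$pct_netotic[1], 70)
    expect_equal(s$n_cells[2], 0L)
    expect_true(is.na(s$pct_netotic[2]))
    # fractions sum to 1 where cells exist
    expect_equal(s$frac_resting[1] + s$frac_netotic[1] + s$frac_apoptotic[1],
                 1)

    # all-resting well: 0%
    cells$phenotype_call <- "resting"
    expect_equal(summarize_wells(cells, lay)$pct_netotic[1], 0)

    # border and gated cells leave the denominator
    cells$phenotype_call <- rep(c("netotic", "resting"), c(70, 30))
    cells$touches_border[1:10] <- TRUE
    cells$net_like_nonlytic[11:20] <- TRUE
    s <- summarize_wells(cells, lay)
    expect_equal(s$n_cells[1], 80L)

    cells$well_id[1] <- "Z99"
    expect_error(summarize_wells(cells, lay), "Z99")
})

test_that("the regularized discriminant agrees with an independent LDA", {
    skip_if_not_installed("MASS")
    cells <- make_blobs(60, list(resting = c(40, 2500, 20),
                                 netotic = c(160, 1000, 8),
                                 apoptotic = c(25, 6000, 40)), sd = 2)
    feats <- c("area_um2", "int_mean", "har_contrast")
    model <- train_classifier(cells, features = feats, lambda = 0,
                              cv_folds = 0L, seed = 1)
    s <- netquant:::.predict_scores(model, as.matrix(cells[, feats]))
    mine <- model$classes[max.col(s, ties.method = "first")]
    ref <- MASS::lda(cells[, feats], grouping = cells$phenotype)
    theirs <- as.character(predict(ref, cells[, feats])$class)
    expect_equal(mine, theirs)
})
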