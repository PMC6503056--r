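## Phenotype classification: resting / NETotic / apoptotic. A regularized
## linear discriminant on standardized features is the default; a
## multinomial-logistic alternative is available. A "lytic gate" enforces
## the assay's rule that only lytic NET formation counts as NETotic: a
## NETotic call must be a large, texturally homogeneous chromatin region.

#' Train the phenotype classifier
#'
#' Standardizes the features, fits either a regularized linear discriminant
#' (class means + shrunken pooled covariance, default) or a multinomial
#' logistic model, derives the lytic gate from the NETotic training class
#' (minimum area = 5th percentile of NETotic areas; maximum texture
#' heterogeneity = 95th percentile of NETotic Haralick contrast) and
#' reports stratified 5-fold cross-validated accuracy.
#'
#' @param cells data.frame with feature columns and a `phenotype` label
#'   column (levels among resting / netotic / apoptotic or any >= 2
#'   classes).
#' @param kind `"rlda"` (regularized linear discriminant) or `"logistic"`.
#' @param features feature column names; defaults to the intersection of
#'   [feature_names()] with `names(cells)`.
#' @param lambda shrinkage of the pooled covariance toward a scaled
#'   identity, in [0, 1].
#' @param cv_folds folds for cross-validation (0 disables).
#' @param seed RNG seed for fold assignment (recorded in the model).
#' @return object of class `net_classifier`.
#' @export
train_classifier <- function(cells, kind = c("rlda", "logistic"),
                             features = NULL, lambda = 0.1, cv_folds = 5L,
                             seed = 1L) {
    kind <- match.arg(kind)
    if (!"phenotype" %in% names(cells)) stop("cells must have a phenotype column")
    y <- as.character(cells$phenotype)
    classes <- sort(unique(y))
    if (length(classes) < 2L) stop("need at least 2 classes to train")
    if (any(table(y) < 10L))
        stop("need at least 10 examples per class")
    if (is.null(features))
        features <- intersect(feature_names(), names(cells))
    features <- unique(features)
    if (!length(features)) stop("no usable feature columns found")
    X <- as.matrix(cells[, features, drop = FALSE])
    if (any(!is.finite(X))) stop("non-finite feature values")
    sds <- apply(X, 2L, sd)
    if (any(sds == 0)) {
        drop <- features[sds == 0]
        warning("dropping zero-variance features: ",
                paste(drop, collapse = ", "))
        features <- features[sds > 0]
        if (!length(features)) stop("all features have zero variance")
        X <- X[, features, drop = FALSE]
    }
    fit <- .fit_model(X, y, classes, kind, lambda)
    gate <- if ("netotic" %in% classes) {
        net <- cells[y == "netotic", ]
        list(area_min = as.numeric(quantile(net$area_um2, 0.05)),
             contrast_max = as.numeric(quantile(net$har_contrast, 0.95)))
    } else list(area_min = -Inf, contrast_max = Inf)
    cv_acc <- if (cv_folds >= 2L)
        .cv_accuracy(X, y, classes, kind, lambda, cv_folds, seed)
    else NA_real_
    structure(list(kind = kind, features = features,
                   center = fit$center, scale = fit$scale,
                   classes = classes, priors = fit$priors,
                   coef = fit$coef, gate = gate,
                   cv_accuracy = cv_acc, cv_seed = seed, lambda = lambda),
              class = "net_classifier")
}

# Fit on raw X; returns standardization + per-class linear score blocks
# (score_k(x) = a_k . z + b_k on standardized z).
.fit_model <- function(X, y, classes, kind, lambda) {
    center <- colMeans(X)
    scale <- apply(X, 2L, sd)
    Z <- sweep(sweep(X, 2L, center), 2L, scale, "/")
    priors <- as.numeric(table(factor(y, classes))) / length(y)
    if (kind == "rlda") {
        p <- ncol(Z)
        mus <- t(vapply(classes, function(k)
            colMeans(Z[y == k, , drop = FALSE]), numeric(p)))
        Sw <- matrix(0, p, p)
        for (k in seq_along(classes)) {
            Zk <- Z[y == classes[k], , drop = FALSE]
            Sw <- Sw + crossprod(sweep(Zk, 2L, mus[k, ]))
        }
        Sw <- Sw / (nrow(Z) - length(classes))
        Sl <- (1 - lambda) * Sw + lambda * mean(diag(Sw)) * diag(p)
        W <- solve(Sl)
        coef <- lapply(seq_along(classes), function(k) {
            a <- as.numeric(W %*% mus[k, ])
            list(a = a, b = -0.5 * sum(mus[k, ] * a) + log(priors[k]))
        })
        names(coef) <- classes
    } else {
        df <- data.frame(.y = factor(y, classes), Z)
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = 300, MaxNWts = 5000)
        B <- coef(fit)
        if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
        coef <- vector("list", length(classes))
        names(coef) <- classes
        coef[[1L]] <- list(a = rep(0, ncol(Z)), b = 0)
        for (k in 2:length(classes))
            coef[[k]] <- list(a = as.numeric(B[k - 1L, -1L]),
                              b = as.numeric(B[k - 1L, 1L]))
    }
    list(center = center, scale = scale, priors = priors, coef = coef)
}

.predict_scores <- function(model_like, X) {
    Z <- sweep(sweep(X, 2L, model_like$center), 2L, model_like$scale, "/")
    s <- vapply(model_like$coef, function(cf)
        as.numeric(Z %*% cf$a) + cf$b, numeric(nrow(Z)))
    if (nrow(Z) == 1L) s <- matrix(s, nrow = 1L,
                                   dimnames = list(NULL, names(model_like$coef)))
    s
}

.cv_accuracy <- function(X, y, classes, kind, lambda, folds, seed) {
    with_seed(seed, {
        fold <- integer(length(y))
        for (k in classes) {
            i <- which(y == k)
            fold[i] <- sample(rep_len(seq_len(folds), length(i)))
        }
        correct <- 0L
        for (f in seq_len(folds)) {
            tr <- fold != f
            fit <- .fit_model(X[tr, , drop = FALSE], y[tr], classes, kind,
                              lambda)
            s <- .predict_scores(fit, X[!tr, , drop = FALSE])
            pred <- classes[max.col(s, ties.method = "first")]
            correct <- correct + sum(pred == y[!tr])
        }
        correct / length(y)
    })
}

#' @export
print.net_classifier <- function(x, ...) {
    cat(sprintf("<net_classifier> %s, %d features, classes: %s\n",
                x$kind, length(x$features), paste(x$classes, collapse = ", ")))
    if (is.finite(x$cv_accuracy))
        cat(sprintf("  5-fold CV accuracy: %.3f\n", x$cv_accuracy))
    cat(sprintf("  lytic gate: area >= %.1f um2, Haralick contrast <= %.2f\n",
                x$gate$area_min, x$gate$contrast_max))
    invisible(x)
}

#' Classify cells into resting / NETotic / apoptotic
#'
#' Assigns each cell the argmax discriminant class. A cell whose argmax is
#' NETotic but which fails the lytic gate (area below the gate minimum or
#' Haralick contrast above the gate maximum — i.e. NET-like but not a
#' lysed, spread, homogeneous chromatin region) is relabeled to its
#' runner-up class and flagged `net_like_nonlytic`. Pure function of
#' (model, features).
#'
#' @param model a `net_classifier`.
#' @param cells data.frame carrying every model feature column.
#' @return `cells` with added columns `phenotype_call`, one score column
#'   per class (`score_<class>`), and `net_like_nonlytic`.
#' @export
classify_cells <- function(model, cells) {
    stopifnot(inherits(model, "net_classifier"))
    missing_f <- setdiff(model$features, names(cells))
    if (length(missing_f))
        stop("cells are missing model features: ",
             paste(missing_f, collapse = ", "))
    if (nrow(cells) == 0L) {
        cells$phenotype_call <- character(0)
        for (k in model$classes) cells[[paste0("score_", k)]] <- numeric(0)
        cells$net_like_nonlytic <- logical(0)
        return(cells)
    }
    X <- as.matrix(cells[, model$features, drop = FALSE])
    s <- .predict_scores(model, X)
    ord <- t(apply(s, 1L, order, decreasing = TRUE))
    call <- model$classes[ord[, 1L]]
    runner <- model$classes[ord[, 2L]]
    flag <- rep(FALSE, nrow(cells))
    if ("netotic" %in% model$classes) {
        is_net <- call == "netotic"
        fails <- is_net & (cells$area_um2 < model$gate$area_min |
                           cells$har_contrast > model$gate$contrast_max)
        call[fails] <- runner[fails]
        flag <- fails
    }
    cells$phenotype_call <- call
    for (k in seq_along(model$classes))
        cells[[paste0("score_", model$classes[k])]] <- s[, k]
    cells$net_like_nonlytic <- flag
    cells
}

#' Summarize classified cells per well
#'
#' The assay's primary readout: per well, the number of analyzed cells and
#' the fraction of each phenotype, with `pct_netotic = 100 * netotic / n`.
#' Border-touching cells are excluded from `n` by default, and so are
#' cells the lytic gate relabeled (`net_like_nonlytic`): such cells sit in
#' an ambiguous transition zone (NET-like signature without full lytic
#' spread) and counting them as any one class biases the readout. Set
#' `exclude_gated = FALSE` to count them as their runner-up class instead.
#'
#' @param cells data.frame from [classify_cells()] with a `well_id` column.
#' @param layout a `plate_layout`; every `well_id` in `cells` must appear
#'   in it. Wells with no cells get `n_cells = 0` and NA fractions.
#' @param exclude_border drop border-touching cells from the denominator.
#' @param exclude_gated drop lytic-gate-relabeled cells entirely.
#' @return data.frame, one row per layout well: layout columns plus
#'   `n_cells`, `frac_resting`, `frac_netotic`, `frac_apoptotic`,
#'   `pct_netotic`.
#' @export
summarize_wells <- function(cells, layout, exclude_border = TRUE,
                            exclude_gated = TRUE) {
    stopifnot(inherits(layout, "plate_layout"))
    unknown <- setdiff(unique(cells$well_id), layout$well_id)
    if (length(unknown))
        stop("cells reference wells absent from the layout: ",
             paste(unknown, collapse = ", "))
    if (exclude_border && "touches_border" %in% names(cells))
        cells <- cells[!cells$touches_border, ]
    if (exclude_gated && "net_like_nonlytic" %in% names(cells))
        cells <- cells[!cells$net_like_nonlytic, ]
    out <- as.data.frame(layout)
    out$n_cells <- 0L
    out$frac_resting <- out$frac_netotic <- out$frac_apoptotic <- NA_real_
    for (i in seq_len(nrow(out))) {
        w <- cells[cells$well_id == out$well_id[i], ]
        n <- nrow(w)
        out$n_cells[i] <- n
        if (n > 0L) {
            tab <- table(factor(w$phenotype_call, .phenotypes))
            out$frac_resting[i] <- tab[["resting"]] / n
            out$frac_netotic[i] <- tab[["netotic"]] / n
            out$frac_apoptotic[i] <- tab[["apoptotic"]] / n
        }
    }
    out$pct_netotic <- 100 * out$frac_netotic
    out
}

#' Serialize a classifier to JSON
#' @param model a `net_classifier`.
#' @param path output path.
#' @export
write_classifier <- function(model, path) {
    stopifnot(inherits(model, "net_classifier"))
    jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a classifier written by [write_classifier()]
#' @param path JSON path.
#' @return a `net_classifier`.
#' @export
read_classifier <- function(path) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    m$coef <- lapply(m$coef, function(cf)
        list(a = as.numeric(cf$a), b = as.numeric(cf$b)))
    m$features <- as.character(m$features)
    m$classes <- as.character(m$classes)
    m$center <- setNames(as.numeric(unlist(m$center)), m$features)
    m$scale <- setNames(as.numeric(unlist(m$scale)), m$features)
    structure(m, class = "net_classifier")
}
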