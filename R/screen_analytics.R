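## Screen-level statistics: Z' plate QC, hit calling, 4-parameter logistic
## dose-response fits, kinetic-trace summaries, and one-way ANOVA with
## Monte-Carlo Dunnett comparisons against a control group.

#' Z' screening-window factor
#'
#' `Z' = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|` with sample (n-1)
#' standard deviations, computed from per-well percent-NETotic values of
#' the positive- and negative-control arms. A Z' above 0.5 indicates an
#' excellent assay window. When the two arms have equal means the window
#' is undefined and the result is flagged as a failure with `z_prime = NA`.
#'
#' @param pos,neg numeric vectors of per-well readouts (>= 2 wells each).
#' @return object of class `zprime_result`: `mu_p`, `sigma_p`, `mu_n`,
#'   `sigma_n`, `z_prime`, `failed`.
#' @export
zprime <- function(pos, neg) {
    if (length(pos) < 2L || length(neg) < 2L)
        stop("need at least 2 wells per control arm")
    mu_p <- mean(pos); mu_n <- mean(neg)
    sigma_p <- sd(pos); sigma_n <- sd(neg)
    failed <- mu_p == mu_n
    z <- if (failed) NA_real_ else 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)
    structure(list(mu_p = mu_p, sigma_p = sigma_p, mu_n = mu_n,
                   sigma_n = sigma_n, z_prime = z, failed = failed),
              class = "zprime_result")
}

#' @export
print.zprime_result <- function(x, ...) {
    if (x$failed)
        cat("<zprime_result> FAILED: control arms have equal means\n")
    else
        cat(sprintf("<zprime_result> Z' = %.4f (pos %.2f +/- %.2f, neg %.2f +/- %.2f)\n",
                    x$z_prime, x$mu_p, x$sigma_p, x$mu_n, x$sigma_n))
    invisible(x)
}

#' Call screening hits from per-compound percent-NETotic values
#'
#' Replicate wells of the same compound are averaged (arithmetic mean)
#' before thresholding. A compound is `active` when its percent NETotic is
#' strictly below `active_threshold` and `strong` when strictly below
#' `strong_threshold`. The default of 50 encodes a 30% reduction of an
#' ~70% induction rate; 10 marks near-complete inhibition.
#'
#' @param wells data.frame with `compound_id` and `pct_netotic` (and
#'   optionally `role`; only `test` wells are used when present).
#' @param active_threshold,strong_threshold percent-NETotic cutoffs.
#' @return data.frame `compound_id`, `pct_netotic` (replicate mean),
#'   `n_wells`, `active`, `strong`, sorted by ascending `pct_netotic`.
#' @export
call_hits <- function(wells, active_threshold = 50, strong_threshold = 10) {
    if (strong_threshold > active_threshold)
        stop("strong_threshold must be <= active_threshold")
    if ("role" %in% names(wells)) wells <- wells[wells$role == "test", ]
    if (!nrow(wells)) stop("no test wells to call hits on")
    if (any(!is.finite(wells$pct_netotic)) ||
        any(wells$pct_netotic < 0 | wells$pct_netotic > 100))
        stop("pct_netotic values must lie in [0, 100]")
    agg <- aggregate(pct_netotic ~ compound_id, data = wells, FUN = mean)
    n <- aggregate(pct_netotic ~ compound_id, data = wells, FUN = length)
    agg$n_wells <- n$pct_netotic[match(agg$compound_id, n$compound_id)]
    agg$active <- agg$pct_netotic < active_threshold
    agg$strong <- agg$pct_netotic < strong_threshold
    agg[order(agg$pct_netotic), ]
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `R(c) = bottom + (top - bottom) / (1 +
#' (c/ec50)^hill)` with multi-start Levenberg-Marquardt initialization.
#' Zero concentrations anchor the top plateau (the model evaluates to
#' `top` at c = 0 for positive Hill coefficients). An EC50 outside the
#' tested concentration range times [0.1, 10] is flagged as extrapolated;
#' a flat response is flagged degenerate with no EC50.
#'
#' @param conc concentrations in uM (>= 0; >= 4 distinct values).
#' @param resp responses (percent NETotic).
#' @param weights optional least-squares weights.
#' @return object of class `dose_response_fit`: `bottom`, `top`, `ec50`,
#'   `hill`, `residuals`, `converged`, `degenerate`, `extrapolated`,
#'   `vcov`.
#' @export
fit_dose_response <- function(conc, resp, weights = NULL) {
    if (length(conc) != length(resp)) stop("conc and resp lengths differ")
    if (any(conc < 0)) stop("concentrations must be >= 0")
    if (length(unique(conc)) < 4L)
        stop("need at least 4 distinct concentrations")
    if (is.null(weights)) weights <- rep(1, length(resp))
    pos <- conc[conc > 0]
    if (!length(pos)) stop("need at least one positive concentration")
    out <- structure(list(bottom = NA_real_, top = NA_real_,
                          ec50 = NA_real_, hill = NA_real_,
                          residuals = rep(NA_real_, length(resp)),
                          converged = FALSE, degenerate = FALSE,
                          extrapolated = FALSE, vcov = NULL),
                     class = "dose_response_fit")
    if (diff(range(resp)) < 1e-9) {
        out$degenerate <- TRUE
        out$bottom <- out$top <- mean(resp)
        out$residuals <- resp - mean(resp)
        return(out)
    }
    lc <- log(conc)  # -Inf at c = 0 gives exactly the top plateau
    f4pl <- function(bottom, top, logec50, hill)
        bottom + (top - bottom) / (1 + exp(hill * (lc - logec50)))
    df <- data.frame(resp = resp, w = weights)
    starts <- expand.grid(
        logec50 = log(quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)),
        hill = c(0.7, 2, 4))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                resp ~ f4pl(bottom, top, logec50, hill), data = df,
                weights = df$w,
                start = list(bottom = min(resp), top = max(resp),
                             logec50 = starts$logec50[i],
                             hill = starts$hill[i]),
                lower = c(-Inf, -Inf, log(min(pos)) - 7, 0.05),
                upper = c(Inf, Inf, log(max(pos)) + 7, 20),
                control = minpack.lm::nls.lm.control(maxiter = 200,
                                                     ftol = 1e-14,
                                                     ptol = 1e-14)),
            error = function(e) NULL)
        if (is.null(fit)) next
        dev <- sum(weights * residuals(fit)^2)
        if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
    if (is.null(best)) return(out)  # no start converged: flagged fit
    cf <- coef(best$fit)
    bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
    ec50 <- exp(unname(cf["logec50"])); hill <- unname(cf["hill"])
    if (bottom > top) {  # canonical orientation: bottom <= top
        tmp <- bottom; bottom <- top; top <- tmp
        hill <- -hill
    }
    out$converged <- TRUE
    out$residuals <- as.numeric(residuals(best$fit))
    if (abs(top - bottom) < 1e-3 * max(1, abs(top))) {
        out$degenerate <- TRUE
        out$bottom <- bottom; out$top <- top
        return(out)
    }
    out$bottom <- bottom; out$top <- top
    out$ec50 <- ec50; out$hill <- hill
    out$extrapolated <- ec50 < 0.1 * min(pos) || ec50 > 10 * max(pos)
    out$vcov <- tryCatch(vcov(best$fit), error = function(e) NULL)
    out
}

#' @export
print.dose_response_fit <- function(x, ...) {
    if (x$degenerate)
        cat("<dose_response_fit> degenerate (flat response), no EC50\n")
    else if (!x$converged)
        cat("<dose_response_fit> did not converge\n")
    else
        cat(sprintf("<dose_response_fit> bottom %.3g, top %.3g, EC50 %.4g uM, hill %.3g%s\n",
                    x$bottom, x$top, x$ec50, x$hill,
                    if (x$extrapolated) " (extrapolated)" else ""))
    invisible(x)
}

#' Summarize a kinetic trace
#'
#' Estimates the plateau by fitting an exponential-approach curve
#' `v0 + (plateau - v0)(1 - exp(-t/tau))` (falling back to the mean of the
#' last 3 points when the fit fails), and reports `peak_fold` (maximum
#' relative to the t = 0 value, or the maximum pointwise ratio to a
#' baseline trace when one is supplied), `t_steady` (first timepoint
#' reaching `steady_frac` of the plateau, flagged unreached when never
#' attained), the final value, and the accumulation slope.
#'
#' @param trace a `kinetic_trace` (or data.frame with sorted `time`
#'   including 0, and `value`), >= 5 timepoints.
#' @param baseline optional baseline trace on the same time grid; the
#'   summary is then computed on the pointwise ratio trace/baseline.
#' @param steady_frac fraction of the plateau defining steady state.
#' @return object of class `kinetic_summary`: `peak_fold`, `plateau`,
#'   `t_steady`, `steady_reached`, `final_value`, `slope`, `tau`.
#' @export
summarize_kinetics <- function(trace, baseline = NULL, steady_frac = 0.95) {
    tm <- trace$time; v <- trace$value
    if (is.unsorted(tm, strictly = TRUE)) stop("timepoints must be sorted")
    if (length(tm) < 5L) stop("need at least 5 timepoints")
    if (!any(tm == 0)) stop("trace must include t = 0")
    if (!is.null(baseline)) {
        if (length(baseline$time) != length(tm) ||
            any(baseline$time != tm))
            stop("baseline trace must share the trace's time grid")
        v <- v / baseline$value
    }
    v0 <- v[tm == 0][1L]
    fit <- tryCatch({
        f <- minpack.lm::nlsLM(
            v ~ a + (P - a) * (1 - exp(-tm / tau)),
            start = list(a = v0, P = mean(tail(v, 3L)),
                         tau = max(tm) / 4),
            lower = c(-Inf, -Inf, 1e-3),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        coef(f)
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit[["P"]]) &&
        fit[["tau"]] < 100 * max(tm)) {
        plateau <- unname(fit[["P"]]); tau <- unname(fit[["tau"]])
    } else {
        plateau <- mean(tail(v, 3L)); tau <- NA_real_
    }
    hit <- which(v >= steady_frac * plateau)
    structure(list(peak_fold = max(v) / v0,
                   plateau = plateau,
                   t_steady = if (length(hit)) tm[hit[1L]] else NA_real_,
                   steady_reached = length(hit) > 0L,
                   final_value = v[length(v)],
                   slope = (v[length(v)] - v[1L]) / (tm[length(tm)] - tm[1L]),
                   tau = tau),
              class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
    cat(sprintf("<kinetic_summary> peak fold %.3g, plateau %.3g, t_steady %s min\n",
                x$peak_fold, x$plateau,
                if (x$steady_reached) sprintf("%g", x$t_steady) else "unreached"))
    invisible(x)
}

#' Monte-Carlo Dunnett critical value
#'
#' Simulates the null distribution of the maximum absolute Dunnett
#' statistic (each treatment group compared with the shared control, with
#' a pooled variance estimate) and returns its upper `alpha` quantile.
#' The shared control induces the characteristic positive correlation
#' between comparisons. Seeded and deterministic.
#'
#' @param n_control,n_groups control group size and vector of treatment
#'   group sizes.
#' @param alpha family-wise error rate.
#' @param n_mc Monte-Carlo draws (>= 1e5 recommended).
#' @param seed RNG seed.
#' @return list: `crit` (critical value), `maxabs` (the simulated draws,
#'   for p-value computation).
#' @export
dunnett_crit <- function(n_control, n_groups, alpha = 0.05, n_mc = 1e5,
                         seed = 1L) {
    k <- length(n_groups)
    df <- n_control + sum(n_groups) - (k + 1L)
    with_seed(seed, {
        z0 <- rnorm(n_mc, 0, sqrt(1 / n_control))
        s <- sqrt(stats::rchisq(n_mc, df) / df)
        tmat <- vapply(seq_len(k), function(i) {
            zi <- rnorm(n_mc, 0, sqrt(1 / n_groups[i]))
            (zi - z0) / (s * sqrt(1 / n_groups[i] + 1 / n_control))
        }, numeric(n_mc))
        maxabs <- do.call(pmax, c(as.data.frame(abs(tmat))))
        list(crit = as.numeric(quantile(maxabs, 1 - alpha)), maxabs = maxabs,
             df = df)
    })
}

#' One-way ANOVA with Dunnett comparisons against a control
#'
#' Runs a one-way ANOVA over the groups, then compares every treatment
#' group with the control using Dunnett statistics whose critical value is
#' obtained by seeded Monte Carlo from the null distribution (shared
#' control, pooled variance). A Kolmogorov-Smirnov normality check per
#' group is reported (and raised as a warning when it fails) but never
#' gates the analysis.
#'
#' @param values numeric vector of observations.
#' @param groups group identifier per observation.
#' @param control identifier of the control group.
#' @param alpha significance level.
#' @param n_mc Monte-Carlo draws for the Dunnett null.
#' @param seed RNG seed for the Monte Carlo.
#' @param crit optional precomputed output of [dunnett_crit()] (e.g. when
#'   scoring many same-shaped datasets).
#' @return list: `f`, `p`, `df`, `comparisons` (data.frame `group`,
#'   `diff`, `t`, `crit`, `p_adj`, `reject`), `normality` (data.frame
#'   `group`, `ks_p`).
#' @export
compare_groups <- function(values, groups, control, alpha = 0.05,
                           n_mc = 1e5, seed = 1L, crit = NULL) {
    groups <- as.character(groups)
    if (!control %in% groups)
        stop("control group '", control, "' not present")
    tab <- table(groups)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L)) stop("need at least 2 values per group")
    others <- setdiff(names(tab), control)
    norm <- do.call(rbind, lapply(names(tab), function(g) {
        x <- values[groups == g]
        p <- if (sd(x) > 0)
            suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm")$p.value)
        else NA_real_
        data.frame(group = g, ks_p = p)
    }))
    if (any(!is.na(norm$ks_p) & norm$ks_p < alpha))
        warning("Kolmogorov-Smirnov normality check failed for group(s): ",
                paste(norm$group[!is.na(norm$ks_p) & norm$ks_p < alpha],
                      collapse = ", "))
    if (var(values) == 0) {
        comp <- data.frame(group = others, diff = 0, t = 0,
                           crit = NA_real_, p_adj = 1, reject = FALSE)
        return(list(f = 0, p = 1, df = c(length(tab) - 1L,
                                         length(values) - length(tab)),
                    comparisons = comp, normality = norm))
    }
    fit <- aov(values ~ factor(groups))
    an <- anova(fit)
    mse <- an[["Mean Sq"]][2L]
    if (is.null(crit))
        crit <- dunnett_crit(tab[[control]], as.numeric(tab[others]),
                             alpha, n_mc, seed)
    mu0 <- mean(values[groups == control])
    comp <- do.call(rbind, lapply(others, function(g) {
        x <- values[groups == g]
        se <- sqrt(mse * (1 / length(x) + 1 / tab[[control]]))
        tt <- if (se > 0) (mean(x) - mu0) / se else 0
        data.frame(group = g, diff = mean(x) - mu0, t = tt,
                   crit = crit$crit,
                   p_adj = mean(crit$maxabs >= abs(tt)),
                   reject = abs(tt) > crit$crit)
    }))
    list(f = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
         df = an[["Df"]], comparisons = comp, normality = norm)
}
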