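# Module survival screening: SVD module eigengene, median split,
# Kaplan-Meier curves and the log-rank test with an observed/expected hazard
# ratio report (per-group hazard rates, 95% CI, signed z, two-tailed p),
# evaluated separately on training and test partitions.

#' Module eigengene by singular value decomposition
#'
#' Gene rows are standardized (zero mean, unit variance across samples);
#' the eigengene is the first right-singular vector of the standardized
#' gene-by-sample matrix (unit Euclidean norm, zero mean). Its sign is fixed
#' so that it correlates positively with the module's mean standardized
#' expression. `variance_explained` is the share of the first squared
#' singular value.
#'
#' @param expr genes-by-samples numeric matrix.
#' @param genes module member genes (>= 2 present in `expr`).
#' @param module_id integer id recorded in the result.
#' @return a [ModuleEigengene-class].
#' @export
moduleEigengene <- function(expr, genes, module_id = NA_integer_) {
    present <- intersect(genes, rownames(expr))
    if (length(present) < 2L)
        stop("module eigengene needs >= 2 module genes in the matrix")
    if (ncol(expr) < 3L)
        stop("module eigengene needs >= 3 samples")
    x <- expr[present, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " constant gene row(s) dropped")
        x <- x[sds > 0, , drop = FALSE]
        sds <- sds[sds > 0]
        if (nrow(x) < 2L)
            stop("fewer than 2 non-constant module genes remain")
    }
    xs <- (x - rowMeans(x)) / sds
    s <- svd(xs)
    me <- s$v[, 1L]
    ve <- s$d[1L]^2 / sum(s$d^2)
    anchor <- colMeans(xs)
    orient <- sum(me * anchor)
    if (orient < 0) me <- -me
    if (orient == 0 && me[which(me != 0)[1L]] < 0) me <- -me
    new("ModuleEigengene",
        module_id = as.integer(module_id),
        scores = setNames(me, colnames(expr)),
        variance_explained = ve,
        sign_anchor = "positive correlation with module mean expression")
}

#' Split samples at the median eigengene value
#'
#' Low group: scores strictly below the median; high group: at or above the
#' median (the median itself always goes high).
#'
#' @param me a [ModuleEigengene-class] or a named numeric vector of scores.
#' @return list with character vectors `low` and `high`.
#' @export
medianSplit <- function(me) {
    scores <- if (is(me, "ModuleEigengene")) eigengeneScores(me) else me
    if (is.null(names(scores)))
        stop("scores must be named by sample")
    med <- median(scores)
    low <- names(scores)[scores < med]
    high <- names(scores)[scores >= med]
    if (!length(low) || !length(high))
        stop("median split produced an empty group (degenerate scores)")
    list(low = low, high = high)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i). The curve is
#' reported at distinct event times only; with no events it is identically 1
#' (zero rows).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' @export
kmEstimate <- function(times, events) {
    if (length(times) == 0L)
        stop("kmEstimate needs at least one observation")
    if (any(times < 0) || any(!is.finite(times)))
        stop("times must be finite and non-negative")
    if (!all(events %in% c(0, 1)))
        stop("events must be 0 (censored) or 1 (death)")
    fit <- survival::survfit(
        survival::Surv(times, events) ~ 1, conf.type = "none")
    keep <- fit$n.event > 0
    data.frame(
        time = fit$time[keep],
        n_risk = fit$n.risk[keep],
        n_event = fit$n.event[keep],
        survival = fit$surv[keep],
        row.names = NULL)
}

#' Two-group log-rank test with hazard-ratio report
#'
#' Standard log-rank: at each distinct event time the observed events in
#' group A are compared with the hypergeometric expectation; `chi2` is the
#' squared standardized difference, `z = (O_A - E_A) / sqrt(V)` (signed, so a
#' positive z means excess events in group A), and the two-sided p comes from
#' the normal distribution. The per-group hazard rate is events per unit of
#' total follow-up time; the hazard ratio is the observed/expected ratio
#' (O_A/E_A)/(O_B/E_B) with a log-scale 95% CI
#' exp(log HR +/- 1.96 sqrt(1/E_A + 1/E_B)).
#'
#' @param times_a,events_a follow-up and event indicator, group A.
#' @param times_b,events_b same, group B.
#' @return list: `n_a`, `n_b`, `obs_a`, `exp_a`, `obs_b`, `exp_b`,
#'   `hazard_rate_a`, `hazard_rate_b`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `chi2`, `z`, `p`.
#' @export
logrankTest <- function(times_a, events_a, times_b, events_b) {
    if (!length(times_a) || !length(times_b))
        stop("both groups must be nonempty")
    if (sum(events_a) + sum(events_b) < 1)
        stop("log-rank test needs at least one event")
    df <- data.frame(
        time = c(times_a, times_b),
        event = c(events_a, events_b),
        grp = factor(rep(c("a", "b"), c(length(times_a), length(times_b))),
            levels = c("a", "b")))
    sd_fit <- survival::survdiff(
        survival::Surv(time, event) ~ grp, data = df)
    V <- sd_fit$var[1L, 1L]
    if (!is.finite(V) || V <= 0)
        stop("log-rank variance is zero (degenerate event pattern)")
    obs <- as.numeric(sd_fit$obs)
    expd <- as.numeric(sd_fit$exp)
    z <- (obs[1L] - expd[1L]) / sqrt(V)
    hr <- (obs[1L] / expd[1L]) / (obs[2L] / expd[2L])
    se_log <- sqrt(1 / expd[1L] + 1 / expd[2L])
    list(
        n_a = length(times_a), n_b = length(times_b),
        obs_a = obs[1L], exp_a = expd[1L],
        obs_b = obs[2L], exp_b = expd[2L],
        hazard_rate_a = obs[1L] / sum(times_a),
        hazard_rate_b = obs[2L] / sum(times_b),
        hazard_ratio = hr,
        ci_lower = exp(log(hr) - 1.96 * se_log),
        ci_upper = exp(log(hr) + 1.96 * se_log),
        chi2 = z^2,
        z = z,
        p = 2 * pnorm(-abs(z)))
}

#' Screen modules for survival association on two partitions
#'
#' For each module and each partition (training, test): compute the module
#' eigengene over the partition's samples, split at its median, and compare
#' the low (ME < median) vs high (ME >= median) groups with the log-rank
#' test. A module is called significant when its log-rank p < `alpha` in both
#' partitions; the full per-module report is returned regardless of the
#' verdict.
#'
#' @param modules list of [GeneModule-class].
#' @param expr_train,expr_test genes-by-samples matrices (columns restricted
#'   to samples with survival records are used).
#' @param surv_train,surv_test data.frames `sample_id`, `time`, `event`.
#' @param alpha per-partition significance level (default 0.05).
#' @return list with `results` (data.frame: one row per module x partition
#'   with the log-rank report columns) and `significant` (integer ids of
#'   modules with p < alpha in both partitions).
#' @export
evaluateModules <- function(modules, expr_train, surv_train,
                            expr_test, surv_test, alpha = 0.05) {
    if (!length(modules))
        return(list(results = data.frame(), significant = integer()))
    parts <- list(
        train = list(expr = expr_train, surv = surv_train),
        test = list(expr = expr_test, surv = surv_test))
    rows <- list()
    for (mod in modules) {
        genes <- moduleGenes(mod)
        skip <- FALSE
        mod_rows <- list()
        for (pn in names(parts)) {
            p <- parts[[pn]]
            ids <- intersect(colnames(p$expr), p$surv$sample_id)
            if (length(intersect(genes, rownames(p$expr))) < 2L) {
                warning("module ", moduleId(mod),
                    " skipped: genes absent from expression (", pn, ")")
                skip <- TRUE
                break
            }
            me <- moduleEigengene(p$expr[, ids, drop = FALSE], genes,
                module_id = moduleId(mod))
            grp <- medianSplit(me)
            s <- p$surv[match(ids, p$surv$sample_id), , drop = FALSE]
            lo <- s[s$sample_id %in% grp$low, , drop = FALSE]
            hi <- s[s$sample_id %in% grp$high, , drop = FALSE]
            lr <- logrankTest(lo$time, lo$event, hi$time, hi$event)
            mod_rows[[length(mod_rows) + 1L]] <- data.frame(
                module_id = moduleId(mod), partition = pn,
                n_low = lr$n_a, n_high = lr$n_b,
                variance_explained = varianceExplained(me),
                hazard_rate_low = lr$hazard_rate_a,
                hazard_rate_high = lr$hazard_rate_b,
                hazard_ratio = lr$hazard_ratio,
                ci_lower = lr$ci_lower, ci_upper = lr$ci_upper,
                chi2 = lr$chi2, z = lr$z, p = lr$p,
                stringsAsFactors = FALSE)
        }
        if (skip) next
        rows <- c(rows, mod_rows)
    }
    results <- do.call(rbind, rows)
    if (is.null(results)) results <- data.frame()
    significant <- integer()
    if (nrow(results)) {
        for (id in unique(results$module_id)) {
            sub <- results[results$module_id == id, ]
            if (all(c("train", "test") %in% sub$partition) &&
                all(sub$p < alpha))
                significant <- c(significant, id)
        }
    }
    list(results = results, significant = significant)
}
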