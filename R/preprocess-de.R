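# Differential expression on already-normalized log2 values: duplicate-row
# collapsing, empirical-Bayes moderated two-sample t, BH adjustment, and
# threshold filtering (|log2FC| > 2, adjusted p < 0.05 by default).

#' Collapse duplicate gene rows by averaging
#'
#' Rows sharing a gene identifier are replaced by their per-sample arithmetic
#' mean, so that each gene appears exactly once.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene IDs, possibly
#'   duplicated), samples in columns.
#' @return numeric matrix with unique rownames, genes in first-appearance
#'   order.
#' @examples
#' m <- rbind(G1 = c(2, 4), G1 = c(4, 6), G2 = c(1, 1))
#' collapseDuplicates(m)
#' @export
collapseDuplicates <- function(expr) {
    if (!is.matrix(expr) || nrow(expr) == 0L || ncol(expr) == 0L)
        stop("expr must be a non-empty genes-by-samples matrix")
    if (is.null(rownames(expr)))
        stop("expr must have gene identifiers as rownames")
    if (any(!is.finite(expr)))
        stop("expr must contain only finite values")
    ids <- rownames(expr)
    if (!anyDuplicated(ids)) return(expr)
    uniq <- unique(ids)
    grp <- factor(ids, levels = uniq)
    out <- apply(expr, 2L, function(col) tapply(col, grp, mean))
    out <- matrix(out, nrow = length(uniq),
        dimnames = list(uniq, colnames(expr)))
    out
}

# Newton inversion of the trigamma function (used by the moderated-t prior
# fit); y = trigamma(x), solved for x > 0.
.trigammaInverse <- function(y) {
    if (!is.finite(y) || y <= 0) return(Inf)
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in seq_len(50L)) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (abs(dif / x) < 1e-10) break
    }
    x
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per gene: log2 fold-change = mean(tumor) - mean(normal); the pooled
#' residual variance s2_g (df d_g = n_t + n_n - 2) is shrunk towards a prior
#' (d0, s0^2) fitted by moment-matching the scaled-F distribution of the
#' sample variances (via the mean and variance of log s2_g), giving
#' s2_tilde = (d0 s0^2 + d_g s2_g) / (d0 + d_g). The moderated statistic
#' t = log2FC / (s_tilde * sqrt(1/n_t + 1/n_n)) is referred to a t
#' distribution on d_g + d0 degrees of freedom (normal when d0 is infinite).
#'
#' Genes with zero variance in both classes cannot inform the fit: they are
#' excluded from the prior estimation, reported with their observed log2FC,
#' t = 0, p = 1, and flagged in the `flagged` column.
#'
#' @param expr numeric matrix, unique genes in rows, samples in columns.
#' @param sample_class character/factor named by (or aligned with) columns of
#'   `expr`, with levels "tumor" and "normal"; >= 2 samples per class.
#' @param prior_df optional override of the prior degrees of freedom d0;
#'   `prior_df = 0` reproduces the ordinary pooled two-sample t-test.
#' @return data.frame with columns `gene`, `log2fc`, `t_stat`, `p`, `flagged`
#'   plus attributes `prior_df` and `prior_var`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 20, 10,
#'     dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' cls <- rep(c("tumor", "normal"), each = 5)
#' head(moderatedT(m, cls))
#' @export
moderatedT <- function(expr, sample_class, prior_df = NULL) {
    cls <- as.character(sample_class)
    if (length(cls) != ncol(expr))
        stop("sample_class must have one entry per expression column")
    it <- cls == "tumor"; inn <- cls == "normal"
    nt <- sum(it); nn <- sum(inn)
    if (nt < 2L || nn < 2L)
        stop("need at least 2 samples per class")
    xt <- expr[, it, drop = FALSE]
    xn <- expr[, inn, drop = FALSE]
    mt <- rowMeans(xt); mn <- rowMeans(xn)
    lfc <- mt - mn
    d_g <- nt + nn - 2L
    ss <- rowSums((xt - mt)^2) + rowSums((xn - mn)^2)
    s2 <- ss / d_g

    ok <- s2 > 0
    if (!any(ok))
        stop("all genes have zero variance; cannot fit the variance prior")

    if (is.null(prior_df)) {
        # moment-matching of log s2_g: e_g is an unbiased estimate of
        # log(s0^2) shifted by the digamma terms of the scaled-F model
        z <- log(s2[ok])
        e <- z - digamma(d_g / 2) + log(d_g / 2)
        emean <- mean(e)
        evar <- var(e) - trigamma(d_g / 2)
        if (!is.finite(evar)) {
            warning("variance prior fit failed; using ordinary pooled t")
            d0 <- 0
            s02 <- mean(s2[ok])
        } else if (evar <= 0) {
            d0 <- Inf
            s02 <- exp(emean)
        } else {
            d0 <- 2 * .trigammaInverse(evar)
            s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        }
    } else {
        d0 <- prior_df
        s02 <- if (d0 > 0) mean(s2[ok]) else 0
    }

    s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else
        (d0 * s02 + d_g * s2) / (d0 + d_g)
    se <- sqrt(s2_tilde * (1 / nt + 1 / nn))
    tstat <- ifelse(se > 0, lfc / se, 0)
    df_tot <- d_g + d0
    p <- if (is.infinite(df_tot)) 2 * pnorm(-abs(tstat)) else
        2 * pt(-abs(tstat), df = df_tot)

    # zero-variance-in-both-classes genes: report means, no evidence
    tstat[!ok & se == 0] <- 0
    p[!ok & s2_tilde == 0] <- 1
    flagged <- !ok
    p[flagged] <- 1
    tstat[flagged] <- 0

    out <- data.frame(gene = rownames(expr), log2fc = lfc, t_stat = tstat,
        p = p, flagged = flagged, row.names = NULL,
        stringsAsFactors = FALSE)
    attr(out, "prior_df") <- d0
    attr(out, "prior_var") <- s02
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`:
#' step-up adjusted values, capped at 1, monotone in the p ordering.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted p-values, same order as input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Run the full differential-expression step
#'
#' Collapses duplicate gene rows, computes moderated t statistics, adjusts
#' p-values by BH, and labels each gene up/down/ns at the given thresholds.
#'
#' @inheritParams moderatedT
#' @param lfc_thr log2 fold-change threshold (strict inequality).
#' @param alpha adjusted-p threshold (strict inequality).
#' @return data.frame: `gene`, `log2fc`, `t_stat`, `p`, `p_adj`, `direction`.
#' @export
runDE <- function(expr, sample_class, lfc_thr = 2, alpha = 0.05,
                  prior_df = NULL) {
    expr <- collapseDuplicates(expr)
    res <- moderatedT(expr, sample_class, prior_df = prior_df)
    res$p_adj <- bhAdjust(res$p)
    res$direction <- "ns"
    res$direction[res$log2fc > lfc_thr & res$p_adj < alpha] <- "up"
    res$direction[res$log2fc < -lfc_thr & res$p_adj < alpha] <- "down"
    res
}

#' Filter differentially expressed genes
#'
#' Up-regulated: log2FC > `lfc_thr` and adjusted p < `alpha`; down-regulated:
#' log2FC < -`lfc_thr` and adjusted p < `alpha`. Inequalities are strict, so a
#' gene at exactly the threshold is excluded.
#'
#' @param results data.frame from [runDE()] (or [moderatedT()] with a `p_adj`
#'   column added).
#' @param lfc_thr log2 fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
filterDEGs <- function(results, lfc_thr = 2, alpha = 0.05) {
    if (is.null(results$p_adj))
        stop("results must contain a p_adj column (run bhAdjust first)")
    if (nrow(results) == 0L)
        return(list(up = character(), down = character()))
    up <- results$gene[results$log2fc > lfc_thr & results$p_adj < alpha]
    down <- results$gene[results$log2fc < -lfc_thr & results$p_adj < alpha]
    list(up = up, down = down)
}
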