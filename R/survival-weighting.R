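# Survival-stratified differential co-expression weighting of a scaffold
# network. Each scaffold edge (x, y) gets the statistic
#
#   D_xy = |Z(r_L) - Z(r_S)| / sqrt(1/(n_L - 3) + 1/(n_S - 3))
#
# where r_L and r_S are the Pearson correlations of x and y across the
# longer- and shorter-survival patients of a partition and Z is Fisher's
# variance-stabilizing transformation Z(r) = 0.5 * ln((1 + r) / (1 - r)).
# Under equal population correlations (bivariate normal data) D is
# asymptotically |N(0, 1)|, so a large D marks an edge whose co-expression
# differs between survival groups.

#' Randomly partition samples into training and test sets
#'
#' @param samples character vector of sample identifiers.
#' @param train_frac fraction assigned to training; |train| =
#'   round(train_frac * n).
#' @param seed integer seed; the partition is deterministic given it.
#' @return list with character vectors `train` and `test`.
#' @examples
#' splitTrainTest(paste0("s", 1:10), train_frac = 0.6, seed = 1L)
#' @export
splitTrainTest <- function(samples, train_frac = 0.6, seed = 1L) {
    if (train_frac <= 0 || train_frac >= 1)
        stop("train_frac must lie strictly in (0, 1)")
    n <- length(samples)
    n_train <- round(train_frac * n)
    set.seed(as.integer(seed))
    train <- sort(sample(samples, n_train))
    list(train = train, test = sort(setdiff(samples, train)))
}

#' Stratify samples into longer- and shorter-survival groups
#'
#' Shorter-survival: observed follow-up time strictly below the median over
#' the given samples; longer-survival: at or above the median. With
#' `rule = "median_event_time"` the median is taken over event (death) times
#' only, so censored follow-up does not move the cutoff.
#'
#' @param survival data.frame with columns `sample_id`, `time`, `event`.
#' @param samples sample identifiers to stratify (must all have records).
#' @param rule `"median_time"` (default) or `"median_event_time"`.
#' @return list with character vectors `longer`, `shorter` and counts `n_L`,
#'   `n_S`. Errors if either stratum has fewer than 4 samples (the Fisher
#'   variance 1/(n - 3) must be positive).
#' @export
stratifySurvival <- function(survival, samples = survival$sample_id,
                             rule = c("median_time", "median_event_time")) {
    rule <- match.arg(rule)
    idx <- match(samples, survival$sample_id)
    if (anyNA(idx))
        stop("no survival record for sample(s): ",
            paste(samples[is.na(idx)], collapse = ", "))
    tm <- survival$time[idx]
    if (any(!is.finite(tm)) || any(tm < 0))
        stop("survival times must be finite and non-negative")
    cut <- if (rule == "median_time") median(tm) else {
        ev <- survival$event[idx] == 1L
        if (!any(ev)) stop("median_event_time rule needs at least one event")
        median(tm[ev])
    }
    shorter <- samples[tm < cut]
    longer <- samples[tm >= cut]
    if (length(longer) < 4L || length(shorter) < 4L)
        stop("each survival stratum needs >= 4 samples (got ",
            length(longer), " longer, ", length(shorter), " shorter)")
    list(longer = longer, shorter = shorter,
        n_L = length(longer), n_S = length(shorter))
}

#' Fisher's Z transformation
#'
#' Z(r) = 0.5 * ln((1 + r) / (1 - r)); an odd, strictly increasing map making
#' sample correlations approximately normal with variance 1/(n - 3).
#'
#' @param r correlation(s) with |r| < 1.
#' @return transformed value(s).
#' @examples
#' fisherZ(0.5)   # 0.5 * log(3)
#' @export
fisherZ <- function(r) {
    if (any(!is.finite(r)) || any(abs(r) >= 1))
        stop("fisherZ requires |r| < 1")
    0.5 * log((1 + r) / (1 - r))
}

#' Differential co-expression edge weight
#'
#' The survival-stratified edge statistic
#' \eqn{D = |Z(r_L) - Z(r_S)| / \sqrt{1/(n_L-3) + 1/(n_S-3)}}. Equal
#' correlations in the two strata give D = 0; under the null of equal
#' population correlations D is asymptotically half-normal.
#'
#' @param r_L,r_S Pearson correlations in the longer/shorter stratum
#'   (|r| < 1).
#' @param n_L,n_S stratum sample sizes (> 3).
#' @return non-negative statistic (vectorized).
#' @examples
#' edgeWeight(0.5, 0, 103, 103)   # 3.8842
#' @export
edgeWeight <- function(r_L, r_S, n_L, n_S) {
    if (any(n_L <= 3) || any(n_S <= 3))
        stop("stratum sizes must exceed 3")
    abs(fisherZ(r_L) - fisherZ(r_S)) / sqrt(1 / (n_L - 3) + 1 / (n_S - 3))
}

# Pearson correlations for a set of gene pairs across a sample block,
# computed on the row-standardized matrix; constant genes give NA.
.pairCor <- function(expr, gx, gy, samples) {
    x <- expr[, samples, drop = FALSE]
    n <- ncol(x)
    mu <- rowMeans(x)
    xc <- x - mu
    ss <- sqrt(rowSums(xc^2))
    xs <- xc / ss   # rows with ss = 0 become NaN -> propagate to NA
    r <- rowSums(xs[gx, , drop = FALSE] * xs[gy, , drop = FALSE])
    r[!is.finite(r)] <- NA_real_
    r
}

#' Weight a scaffold network by differential co-expression
#'
#' For every scaffold edge, Pearson correlations are computed across the
#' longer-survival (`r_L`) and shorter-survival (`r_S`) samples, Fisher
#' Z-transformed, and combined into the edge statistic D (see
#' [edgeWeight()]). Edges incident to a gene with zero variance in either
#' stratum are dropped with a warning. Correlations numerically at +/- 1 are
#' clamped to +/-(1 - 1e-12) before the transformation.
#'
#' @param edges data.frame with columns `gene_x`, `gene_y` (an undirected
#'   simple edge list), or a list with an `edges` element of that form.
#' @param expr genes-by-samples numeric matrix containing every scaffold
#'   node and every stratified sample.
#' @param strata result of [stratifySurvival()].
#' @return a [WeightedNetwork-class].
#' @export
weightNetwork <- function(edges, expr, strata) {
    if (is.list(edges) && !is.data.frame(edges) && !is.null(edges$edges))
        edges <- edges$edges
    stopifnot(is.data.frame(edges), all(c("gene_x", "gene_y") %in%
        names(edges)))
    nodes <- sort(unique(c(edges$gene_x, edges$gene_y)))
    missing_genes <- setdiff(nodes, rownames(expr))
    if (length(missing_genes))
        stop("gene(s) absent from the expression matrix: ",
            paste(missing_genes, collapse = ", "))
    missing_samples <- setdiff(c(strata$longer, strata$shorter),
        colnames(expr))
    if (length(missing_samples))
        stop("stratified sample(s) absent from the expression matrix: ",
            paste(missing_samples, collapse = ", "))
    # canonical edge order for output determinism
    gx <- pmin(edges$gene_x, edges$gene_y)
    gy <- pmax(edges$gene_x, edges$gene_y)
    o <- order(gx, gy)
    gx <- gx[o]; gy <- gy[o]

    if (length(gx)) {
        r_L <- .pairCor(expr, gx, gy, strata$longer)
        r_S <- .pairCor(expr, gx, gy, strata$shorter)
    } else {
        r_L <- r_S <- numeric()
    }
    drop <- is.na(r_L) | is.na(r_S)
    if (any(drop)) {
        warning(sum(drop), " edge(s) dropped: zero variance in a stratum")
        gx <- gx[!drop]; gy <- gy[!drop]
        r_L <- r_L[!drop]; r_S <- r_S[!drop]
    }
    clamp <- 1 - 1e-12
    r_L <- pmin(pmax(r_L, -clamp), clamp)
    r_S <- pmin(pmax(r_S, -clamp), clamp)
    z_L <- fisherZ(r_L)
    z_S <- fisherZ(r_S)
    D <- abs(z_L - z_S) /
        sqrt(1 / (strata$n_L - 3) + 1 / (strata$n_S - 3))
    new("WeightedNetwork",
        nodes = nodes,
        edges = data.frame(gene_x = gx, gene_y = gy, r_L = r_L, r_S = r_S,
            z_L = z_L, z_S = z_S, D = D, stringsAsFactors = FALSE),
        n_long = as.integer(strata$n_L), n_short = as.integer(strata$n_S))
}
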