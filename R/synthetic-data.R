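# Planted-module benchmark generator.
#
# The generator emulates the data regime of a survival-weighted co-expression
# study: a modular interaction scaffold (planted-partition graph), log2
# expression in which planted modules are differentially co-expressed between
# a latent longer- and shorter-survival class, a tumor-vs-normal shift for DE
# genes, and exponential survival times whose log-hazard is linear in the
# survival-linked module's latent eigengene.

# Deterministic per-stage seed derived from the design seed; kept below 2^31.
.stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) %% 1e6) * 1009 +
        sum(utf8ToInt(stage))) %% 2147483647L
}

#' Construct a synthetic study design
#'
#' Defaults describe the benchmark used throughout the package: 100 genes of
#' which 50 sit in five planted modules of 10, a planted-partition scaffold
#' (p_in = 0.8, p_out = 0.05), strong within-module correlation in the
#' longer-survival class (r_long = 0.8) against weak correlation in the
#' shorter-survival class (r_short = 0.1), 200 tumor and 30 normal samples,
#' a 3-unit log2 shift for DE genes, and a unit log-hazard effect of the
#' survival-linked module eigengene on exponential survival times with light
#' (rate 0.02) exponential censoring.
#'
#' @param n_genes,n_tumor,n_normal counts of genes and samples.
#' @param module_sizes integer vector of planted module sizes.
#' @param p_in,p_out within-/between-module scaffold edge probabilities.
#' @param r_long,r_short planted within-module correlation per survival class.
#' @param de_lfc log2 fold-change of DE genes, tumor vs normal.
#' @param hazard_coef log-hazard per unit of the planted module eigengene.
#' @param baseline_hazard baseline event rate (> 0), abstract time units.
#' @param censor_rate exponential censoring rate (>= 0).
#' @param seed integer seed controlling all generator randomness.
#' @return a validated [SyntheticDesign-class] object.
#' @examples
#' design <- syntheticDesign(seed = 1L)
#' design
#' @export
syntheticDesign <- function(n_genes = 100L, n_tumor = 200L, n_normal = 30L,
                            module_sizes = rep(10L, 5L),
                            p_in = 0.8, p_out = 0.05,
                            r_long = 0.8, r_short = 0.1,
                            de_lfc = 3, hazard_coef = 1,
                            baseline_hazard = 0.1, censor_rate = 0.02,
                            seed = 1L) {
    new("SyntheticDesign",
        n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
        n_normal = as.integer(n_normal),
        module_sizes = as.integer(module_sizes),
        p_in = p_in, p_out = p_out, r_long = r_long, r_short = r_short,
        de_lfc = de_lfc, hazard_coef = hazard_coef,
        baseline_hazard = baseline_hazard, censor_rate = censor_rate,
        seed = as.integer(seed))
}

.geneNames <- function(n) sprintf("g%04d", seq_len(n))

.moduleAssignment <- function(design) {
    genes <- .geneNames(design@n_genes)
    assign <- rep(NA_integer_, design@n_genes)
    names(assign) <- genes
    pos <- 1L
    for (m in seq_along(design@module_sizes)) {
        sz <- design@module_sizes[m]
        assign[pos:(pos + sz - 1L)] <- m
        pos <- pos + sz
    }
    assign
}

#' Generate a planted-partition interaction scaffold
#'
#' Every pair of genes in the same planted module is connected with
#' probability `p_in`, every other pair with probability `p_out`; the result
#' is an undirected simple graph with no self loops, deterministic given the
#' design seed.
#'
#' @param design a [SyntheticDesign-class].
#' @return a list with elements `nodes` (character), `edges` (data.frame with
#'   columns `gene_x`, `gene_y`), and `truth` (list: `module_assignment`,
#'   `survival_module_id`, `de_genes`, `expected_hub`).
#' @examples
#' sc <- generateScaffold(syntheticDesign(seed = 7L))
#' nrow(sc$edges)
#' @export
generateScaffold <- function(design) {
    validObject(design)
    assign <- .moduleAssignment(design)
    genes <- names(assign)
    n <- length(genes)

    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- !is.na(assign[ij[, 1L]]) & !is.na(assign[ij[, 2L]]) &
        assign[ij[, 1L]] == assign[ij[, 2L]]
    prob <- ifelse(same, design@p_in, design@p_out)

    set.seed(.stageSeed(design@seed, "scaffold"))
    keep <- runif(nrow(ij)) < prob
    edges <- data.frame(
        gene_x = genes[ij[keep, 1L]],
        gene_y = genes[ij[keep, 2L]],
        stringsAsFactors = FALSE)
    # canonical order: gene_x < gene_y, rows sorted
    flip <- edges$gene_x > edges$gene_y
    tmp <- edges$gene_x[flip]
    edges$gene_x[flip] <- edges$gene_y[flip]
    edges$gene_y[flip] <- tmp
    edges <- edges[order(edges$gene_x, edges$gene_y), , drop = FALSE]
    rownames(edges) <- NULL

    surv_mod <- 1L
    mod_genes <- names(assign)[!is.na(assign) & assign == surv_mod]
    deg <- table(factor(c(edges$gene_x, edges$gene_y), levels = genes))
    hub <- mod_genes[order(-deg[mod_genes], mod_genes)][1L]

    list(
        nodes = genes,
        edges = edges,
        truth = list(
            module_assignment = assign,
            survival_module_id = surv_mod,
            de_genes = names(assign)[!is.na(assign)],
            expected_hub = hub))
}

#' Generate expression and survival data over a scaffold
#'
#' Tumor samples carry a one-factor Gaussian structure inside each planted
#' module: gene = sqrt(r) * f + sqrt(1 - r) * noise, with f the module's
#' per-sample latent factor, so every within-module gene pair has population
#' correlation r. The latent longer/shorter survival class is the median split
#' of the survival-linked module's factor; r = `r_long` in the longer class
#' and `r_short` in the shorter class. DE genes gain `de_lfc` in tumor
#' samples. Survival times are exponential with
#' log-hazard = log(baseline_hazard) + hazard_coef * f, censored by an
#' independent exponential clock at `censor_rate`. Normal samples are i.i.d.
#' Gaussian around the baseline level. All values sit on a log2-like scale
#' around a baseline of 8.
#'
#' @param design a [SyntheticDesign-class]; `r_long`, `r_short` must be in
#'   [0, 1) for the one-factor construction.
#' @param scaffold result of [generateScaffold()] for the same design.
#' @return list with `expr` (gene-by-sample numeric matrix), `sample_class`
#'   (named character, "tumor"/"normal"), `survival` (data.frame: `sample_id`,
#'   `time`, `event`), and `truth` (the scaffold truth plus `latent_factor`
#'   and `latent_class` for tumor samples).
#' @examples
#' design <- syntheticDesign(n_tumor = 40L, n_normal = 10L, seed = 3L)
#' ds <- generateDataset(design, generateScaffold(design))
#' dim(ds$expr)
#' @export
generateDataset <- function(design, scaffold) {
    validObject(design)
    if (design@r_long < 0 || design@r_long >= 1 ||
        design@r_short < 0 || design@r_short >= 1)
        stop("r_long/r_short: the one-factor construction needs r in [0, 1)")
    assign <- scaffold$truth$module_assignment
    genes <- names(assign)
    n_mod <- length(design@module_sizes)
    surv_mod <- scaffold$truth$survival_module_id
    baseline <- 8

    tumor_ids <- sprintf("T%03d", seq_len(design@n_tumor))
    normal_ids <- sprintf("N%03d", seq_len(design@n_normal))

    set.seed(.stageSeed(design@seed, "expression"))
    # per-sample latent module factors
    f <- matrix(rnorm(design@n_tumor * n_mod), design@n_tumor, n_mod)
    f_surv <- f[, surv_mod]
    long_class <- f_surv < median(f_surv)   # lower eigengene -> lower hazard
    r_sample <- ifelse(long_class, design@r_long, design@r_short)

    expr_t <- matrix(rnorm(length(genes) * design@n_tumor),
        length(genes), design@n_tumor, dimnames = list(genes, tumor_ids))
    for (m in seq_len(n_mod)) {
        rows <- which(!is.na(assign) & assign == m)
        # gene = sqrt(r) f/s_c + sqrt(1-r) eps, with r set by the sample's
        # survival class. Dividing by the class-conditional sd of the factor
        # keeps the within-class pairwise correlation exactly r: conditioning
        # the class on the survival module's own factor truncates that
        # factor's variance, which would otherwise dilute r. The factor is
        # rescaled, not centered, so it stays monotone in the hazard driver.
        s_c <- ifelse(long_class, sd(f[long_class, m]),
            sd(f[!long_class, m]))
        load_f <- sqrt(r_sample) / s_c
        load_e <- sqrt(1 - r_sample)
        expr_t[rows, ] <- t(t(expr_t[rows, , drop = FALSE]) * load_e) +
            matrix(rep(f[, m] * load_f, each = length(rows)),
                length(rows), design@n_tumor)
    }
    expr_t <- expr_t + baseline
    de <- scaffold$truth$de_genes
    expr_t[de, ] <- expr_t[de, ] + design@de_lfc

    expr_n <- matrix(rnorm(length(genes) * design@n_normal) + baseline,
        length(genes), design@n_normal, dimnames = list(genes, normal_ids))

    set.seed(.stageSeed(design@seed, "survival"))
    hz <- design@baseline_hazard * exp(design@hazard_coef * f_surv)
    if (any(!is.finite(hz)) || any(hz <= 0))
        stop("hazard_coef/baseline_hazard produce non-finite hazards")
    death <- rexp(design@n_tumor, rate = hz)
    cens <- if (design@censor_rate > 0)
        rexp(design@n_tumor, rate = design@censor_rate) else Inf
    time <- pmin(death, cens)
    if (any(!is.finite(time)))
        stop("hazard_coef/baseline_hazard produce non-finite survival times")
    survival <- data.frame(
        sample_id = tumor_ids,
        time = time,
        event = as.integer(death <= cens),
        stringsAsFactors = FALSE)

    truth <- scaffold$truth
    truth$latent_factor <- setNames(f_surv, tumor_ids)
    truth$latent_class <- setNames(
        ifelse(long_class, "longer", "shorter"), tumor_ids)

    list(
        expr = cbind(expr_t, expr_n),
        sample_class = setNames(
            c(rep("tumor", design@n_tumor), rep("normal", design@n_normal)),
            c(tumor_ids, normal_ids)),
        survival = survival,
        truth = truth)
}

#' Generate a synthetic gene-set collection
#'
#' Emits one gene set per planted module plus random background sets, for use
#' as a local over-representation library (GMT-style named list).
#'
#' @param scaffold result of [generateScaffold()].
#' @param n_random number of random background sets.
#' @param random_size size of each random set.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
syntheticGeneSets <- function(scaffold, n_random = 20L, random_size = 15L,
                              seed = 1L) {
    assign <- scaffold$truth$module_assignment
    sets <- lapply(sort(unique(assign[!is.na(assign)])), function(m)
        names(assign)[!is.na(assign) & assign == m])
    names(sets) <- sprintf("PLANTED_MODULE_%d", seq_along(sets))
    set.seed(.stageSeed(seed, "genesets"))
    rnd <- lapply(seq_len(n_random), function(i)
        sort(sample(names(assign), min(random_size, length(assign)))))
    names(rnd) <- sprintf("RANDOM_SET_%02d", seq_len(n_random))
    c(sets, rnd)
}
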