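#' @import methods
#' @importFrom stats cor median pchisq pnorm pt phyper quantile rbinom rexp
#'   rnorm runif sd setNames var p.adjust complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' SyntheticDesign: parameters of a planted-module benchmark dataset
#'
#' Describes a synthetic study: a planted-partition interaction scaffold, a
#' tumor/normal log2 expression matrix whose planted modules are differentially
#' co-expressed between longer- and shorter-survival patients, and exponential
#' survival times whose hazard depends on one planted module's eigengene.
#'
#' @slot n_genes total number of genes.
#' @slot n_tumor number of tumor samples (each with a survival record).
#' @slot n_normal number of normal samples (no survival record).
#' @slot module_sizes integer vector of planted module sizes (each >= 3).
#' @slot p_in within-module edge probability of the scaffold.
#' @slot p_out between-module (and background) edge probability.
#' @slot r_long pairwise correlation planted within modules in the
#'   longer-survival class.
#' @slot r_short same, in the shorter-survival class.
#' @slot de_lfc log2 fold-change added to DE genes in tumor samples.
#' @slot hazard_coef log-hazard increment per unit of the planted module
#'   eigengene.
#' @slot baseline_hazard baseline event rate per unit time (> 0).
#' @slot censor_rate independent exponential censoring rate (>= 0; 0 disables
#'   censoring).
#' @slot seed integer seed; all generator output is deterministic given it.
#' @seealso [syntheticDesign()], [generateScaffold()], [generateDataset()]
#' @export
setClass("SyntheticDesign",
    representation(
        n_genes = "integer", n_tumor = "integer", n_normal = "integer",
        module_sizes = "integer",
        p_in = "numeric", p_out = "numeric",
        r_long = "numeric", r_short = "numeric",
        de_lfc = "numeric", hazard_coef = "numeric",
        baseline_hazard = "numeric", censor_rate = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticDesign", function(object) {
    msgs <- character()
    if (sum(object@module_sizes) > object@n_genes)
        msgs <- c(msgs, "module_sizes: sum(module_sizes) must be <= n_genes")
    if (any(object@module_sizes < 3L))
        msgs <- c(msgs, "module_sizes: every planted module needs >= 3 genes")
    if (object@n_tumor < 10L)
        msgs <- c(msgs, "n_tumor: at least 10 tumor samples are required")
    if (object@p_in < 0 || object@p_in > 1)
        msgs <- c(msgs, "p_in: must lie in [0, 1]")
    if (object@p_out < 0 || object@p_out > object@p_in)
        msgs <- c(msgs, "p_out: must satisfy 0 <= p_out <= p_in")
    for (fld in c("r_long", "r_short"))
        if (abs(slot(object, fld)) > 1)
            msgs <- c(msgs, paste0(fld, ": correlation must lie in [-1, 1]"))
    if (object@baseline_hazard <= 0 || !is.finite(object@baseline_hazard))
        msgs <- c(msgs, "baseline_hazard: must be a finite rate > 0")
    if (object@censor_rate < 0 || !is.finite(object@censor_rate))
        msgs <- c(msgs, "censor_rate: must be a finite rate >= 0")
    if (!is.finite(object@hazard_coef))
        msgs <- c(msgs, "hazard_coef: must be finite")
    if (length(msgs)) msgs else TRUE
})

#' WeightedNetwork: a scaffold weighted by differential co-expression
#'
#' An undirected simple graph whose edges carry the survival-stratified
#' differential co-expression statistic
#' \eqn{D_{xy} = |Z(r_L) - Z(r_S)| / \sqrt{1/(n_L-3) + 1/(n_S-3)}}
#' together with the per-stratum Pearson correlations it was computed from.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `gene_x`, `gene_y`, `r_L`, `r_S`,
#'   `z_L`, `z_S`, `D`.
#' @slot n_long number of longer-survival samples used for `r_L`.
#' @slot n_short number of shorter-survival samples used for `r_S`.
#' @seealso [weightNetwork()], [edgeTable()], [nodeSet()]
#' @export
setClass("WeightedNetwork",
    representation(
        nodes = "character", edges = "data.frame",
        n_long = "integer", n_short = "integer"
    )
)

setValidity("WeightedNetwork", function(object) {
    msgs <- character()
    need <- c("gene_x", "gene_y", "r_L", "r_S", "z_L", "z_S", "D")
    if (!all(need %in% names(object@edges)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    e <- object@edges
    if (nrow(e)) {
        if (!all(c(e$gene_x, e$gene_y) %in% object@nodes))
            msgs <- c(msgs, "every edge endpoint must appear in nodes")
        if (any(e$gene_x == e$gene_y))
            msgs <- c(msgs, "self loops are not allowed")
        key <- paste(pmin(e$gene_x, e$gene_y), pmax(e$gene_x, e$gene_y))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate edges are not allowed")
        if (any(e$D < 0, na.rm = TRUE))
            msgs <- c(msgs, "edge weights D must be non-negative")
        if (any(abs(e$r_L) >= 1 | abs(e$r_S) >= 1, na.rm = TRUE))
            msgs <- c(msgs, "stratum correlations must lie strictly in (-1, 1)")
    }
    if (anyDuplicated(object@nodes))
        msgs <- c(msgs, "nodes must be unique")
    if (length(msgs)) msgs else TRUE
})

#' GeneModule: a (possibly overlapping) module of the weighted network
#'
#' A named node set together with its induced weighted edge list. Modules
#' detected by [detectModules()] may share nodes with one another.
#'
#' @slot id integer module identifier.
#' @slot genes character vector of member genes (>= 2).
#' @slot edges data.frame of induced edges (`gene_x`, `gene_y`, `D`).
#' @seealso [detectModules()], [moduleGenes()], [moduleEdges()]
#' @export
setClass("GeneModule",
    representation(id = "integer", genes = "character", edges = "data.frame")
)

setValidity("GeneModule", function(object) {
    msgs <- character()
    if (length(object@genes) < 2L)
        msgs <- c(msgs, "a module needs at least 2 genes")
    if (anyDuplicated(object@genes))
        msgs <- c(msgs, "module genes must be unique")
    if (nrow(object@edges) &&
        !all(c(object@edges$gene_x, object@edges$gene_y) %in% object@genes))
        msgs <- c(msgs, "edges must be induced by the module's genes")
    if (length(msgs)) msgs else TRUE
})

#' ModuleEigengene: the SVD summary profile of a module
#'
#' The first right-singular vector of the row-standardized gene-by-sample
#' expression submatrix of a module: a unit-norm, zero-mean per-sample score
#' that summarises the module's expression in one dimension.
#'
#' @slot module_id integer module identifier.
#' @slot scores named numeric vector of per-sample eigengene values.
#' @slot variance_explained fraction of total variance carried by the first
#'   singular value: \eqn{d_1^2 / \sum_k d_k^2}.
#' @slot sign_anchor description of the rule that fixed the eigengene sign.
#' @seealso [moduleEigengene()]
#' @export
setClass("ModuleEigengene",
    representation(
        module_id = "integer", scores = "numeric",
        variance_explained = "numeric", sign_anchor = "character"
    )
)

setValidity("ModuleEigengene", function(object) {
    msgs <- character()
    if (is.null(names(object@scores)))
        msgs <- c(msgs, "scores must be named by sample")
    if (abs(mean(object@scores)) > 1e-8)
        msgs <- c(msgs, "eigengene scores must have zero mean")
    if (object@variance_explained < 0 || object@variance_explained > 1 + 1e-12)
        msgs <- c(msgs, "variance_explained must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

# ---- generics ---------------------------------------------------------------

#' Node set of a network-like object
#' @param x a `WeightedNetwork` or `GeneModule`.
#' @return character vector of gene identifiers.
#' @export
setGeneric("nodeSet", function(x) standardGeneric("nodeSet"))

#' Edge table of a weighted network
#' @param x a `WeightedNetwork`.
#' @return data.frame with one row per edge.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Member genes of a module
#' @param x a `GeneModule`.
#' @return character vector.
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' Induced edges of a module
#' @param x a `GeneModule`.
#' @return data.frame (`gene_x`, `gene_y`, `D`).
#' @export
setGeneric("moduleEdges", function(x) standardGeneric("moduleEdges"))

#' Module identifier
#' @param x a `GeneModule` or `ModuleEigengene`.
#' @return integer id.
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' Per-sample eigengene scores
#' @param x a `ModuleEigengene`.
#' @return named numeric vector.
#' @export
setGeneric("eigengeneScores", function(x) standardGeneric("eigengeneScores"))

#' Variance explained by the first singular value
#' @param x a `ModuleEigengene`.
#' @return fraction in [0, 1].
#' @export
setGeneric("varianceExplained",
    function(x) standardGeneric("varianceExplained"))

#' @rdname nodeSet
#' @export
setMethod("nodeSet", "WeightedNetwork", function(x) x@nodes)

#' @rdname nodeSet
#' @export
setMethod("nodeSet", "GeneModule", function(x) x@genes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "WeightedNetwork", function(x) x@edges)

#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

#' @rdname moduleEdges
#' @export
setMethod("moduleEdges", "GeneModule", function(x) x@edges)

#' @rdname moduleId
#' @export
setMethod("moduleId", "GeneModule", function(x) x@id)

#' @rdname moduleId
#' @export
setMethod("moduleId", "ModuleEigengene", function(x) x@module_id)

#' @rdname eigengeneScores
#' @export
setMethod("eigengeneScores", "ModuleEigengene", function(x) x@scores)

#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "ModuleEigengene",
    function(x) x@variance_explained)

setMethod("show", "SyntheticDesign", function(object) {
    cat("SyntheticDesign:", object@n_genes, "genes,",
        object@n_tumor, "tumor +", object@n_normal, "normal samples\n")
    cat("  planted modules:", length(object@module_sizes),
        sprintf("(sizes %s)", paste(object@module_sizes, collapse = ",")), "\n")
    cat(sprintf("  scaffold p_in=%.3g p_out=%.3g | r_long=%.2f r_short=%.2f\n",
        object@p_in, object@p_out, object@r_long, object@r_short))
    cat(sprintf(
        "  de_lfc=%.2f hazard_coef=%.2f baseline=%.3g censor=%.3g seed=%d\n",
        object@de_lfc, object@hazard_coef, object@baseline_hazard,
        object@censor_rate, object@seed))
})

setMethod("show", "WeightedNetwork", function(object) {
    cat("WeightedNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges",
        sprintf("(strata n_L=%d, n_S=%d)\n", object@n_long, object@n_short))
    if (nrow(object@edges))
        cat(sprintf("  D: min %.3f, median %.3f, max %.3f\n",
            min(object@edges$D), median(object@edges$D), max(object@edges$D)))
})

setMethod("show", "GeneModule", function(object) {
    cat(sprintf("GeneModule %d: %d genes, %d edges\n",
        object@id, length(object@genes), nrow(object@edges)))
    cat(" ", paste(head(sort(object@genes), 8L), collapse = " "),
        if (length(object@genes) > 8L) "..." else "", "\n")
})

setMethod("show", "ModuleEigengene", function(object) {
    cat(sprintf(
        "ModuleEigengene (module %d): %d samples, %.1f%% variance explained\n",
        object@module_id, length(object@scores),
        100 * object@variance_explained))
})
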