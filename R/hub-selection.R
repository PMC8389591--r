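# Hub-gene nomination from a survival-significant module: weighted-degree and
# eigenvector centrality rankings, hypergeometric over-representation against
# a local gene-set collection, a four-way set intersection, and pairwise
# Spearman correlations between the nominated hubs.

#' Rank module genes by a weighted centrality
#'
#' Weighted degree is the sum of incident D weights; eigenvector centrality
#' is the principal eigenvector of the weighted adjacency matrix with
#' non-negative entries, rescaled to unit Euclidean norm. On a disconnected
#' module the eigenvector is computed on the largest connected component
#' (warning), other genes scoring 0. The top-k list is sorted by descending
#' score, ties broken lexicographically.
#'
#' @param module a [GeneModule-class] (or a data.frame edge list with columns
#'   `gene_x`, `gene_y`, `D`).
#' @param kind `"weighted_degree"` or `"eigenvector"`.
#' @param k size of the top list (default 10).
#' @return list: `kind`, `scores` (named numeric over all module genes),
#'   `top_k` (ordered character vector of length <= k).
#' @export
rankCentrality <- function(module, kind = c("weighted_degree", "eigenvector"),
                           k = 10L) {
    kind <- match.arg(kind)
    if (k < 1L) stop("k must be >= 1")
    if (is(module, "GeneModule")) {
        genes <- moduleGenes(module)
        edges <- moduleEdges(module)
    } else {
        edges <- module
        genes <- sort(unique(c(edges$gene_x, edges$gene_y)))
    }
    g <- igraph::graph_from_data_frame(
        edges[, c("gene_x", "gene_y")], directed = FALSE,
        vertices = data.frame(name = genes))
    igraph::E(g)$weight <- edges$D

    if (kind == "weighted_degree") {
        scores <- igraph::strength(g)
    } else {
        comp <- igraph::components(g)
        scores <- setNames(rep(0, length(genes)), genes)
        main <- which.max(comp$csize)
        if (comp$no > 1L) {
            warning("module is disconnected; eigenvector centrality ",
                "computed on the largest component")
            g <- igraph::induced_subgraph(g,
                which(comp$membership == main))
        }
        ev <- igraph::eigen_centrality(g,
            weights = igraph::E(g)$weight)$vector
        ev <- abs(ev)
        scores[names(ev)] <- ev / sqrt(sum(ev^2))
    }
    ord <- order(-scores, names(scores))
    list(kind = kind, scores = scores[ord],
        top_k = names(scores)[ord][seq_len(min(k, length(scores)))])
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the realized overlap between the query and the set within the
#' universe: p = P(X >= overlap), X ~ Hypergeom(universe, set, query). Sets
#' are intersected with the universe first; p-values are BH-adjusted across
#' sets and results sorted by p.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe background gene vector.
#' @return data.frame: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `p_adj`, `overlap_genes` (comma-separated).
#' @export
hypergeometricEnrichment <- function(query, gene_sets, universe) {
    if (!length(universe)) stop("universe must be nonempty")
    universe <- unique(universe)
    query <- intersect(unique(query), universe)
    rows <- lapply(names(gene_sets), function(nm) {
        gs <- intersect(unique(gene_sets[[nm]]), universe)
        ov <- intersect(query, gs)
        p <- phyper(length(ov) - 1L, length(gs),
            length(universe) - length(gs), length(query),
            lower.tail = FALSE)
        data.frame(set_name = nm, overlap = length(ov),
            set_size = length(gs), query_size = length(query),
            universe_size = length(universe), p = p,
            overlap_genes = paste(sort(ov), collapse = ","),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(set_name = character(), overlap = integer(),
            set_size = integer(), query_size = integer(),
            universe_size = integer(), p = numeric(), p_adj = numeric(),
            overlap_genes = character()))
    out$p_adj <- bhAdjust(out$p)
    out <- out[order(out$p, out$set_name),
        c("set_name", "overlap", "set_size", "query_size", "universe_size",
          "p", "p_adj", "overlap_genes")]
    rownames(out) <- NULL
    out
}

#' Genes of the top significant pathways
#'
#' Selects up to `top_n` sets with p < `alpha` (ordered by p) from an
#' enrichment result and returns the union of their member genes, optionally
#' restricted to a module's genes.
#'
#' @param enrichment data.frame from [hypergeometricEnrichment()].
#' @param gene_sets the named list the enrichment was computed from.
#' @param top_n number of significant sets retained (default 10).
#' @param alpha raw-p threshold (default 0.05).
#' @param restrict optional gene vector to intersect with (e.g. module
#'   genes).
#' @return character vector of genes.
#' @export
significantPathwayGenes <- function(enrichment, gene_sets, top_n = 10L,
                                    alpha = 0.05, restrict = NULL) {
    sig <- enrichment[enrichment$p < alpha, , drop = FALSE]
    sig <- head(sig, top_n)
    genes <- unique(unlist(gene_sets[sig$set_name], use.names = FALSE))
    if (!is.null(restrict)) genes <- intersect(genes, restrict)
    sort(genes)
}

#' Intersect candidate hub sets
#'
#' Exact multi-way intersection of the centrality top lists, the significant
#' pathway genes, and an external DEG list; order-free and deterministic.
#'
#' @param ... two or more character vectors.
#' @return sorted character vector of common genes.
#' @examples
#' intersectHubs(c("A", "B", "C"), c("A", "B", "X"), c("A", "B", "Y"))
#' @export
intersectHubs <- function(...) {
    sets <- list(...)
    if (!length(sets)) return(character())
    sort(Reduce(intersect, lapply(sets, unique)))
}

#' Pairwise correlations between hub genes
#'
#' Spearman (default) rank correlations of the hub genes across samples;
#' the matrix is symmetric with unit diagonal. Constant genes give NA rows
#' and columns with a warning.
#'
#' @param expr genes-by-samples matrix.
#' @param hubs hub gene names (present in `expr`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return correlation matrix (hubs x hubs).
#' @export
hubCorrelations <- function(expr, hubs,
                            method = c("spearman", "pearson")) {
    method <- match.arg(method)
    missing_genes <- setdiff(hubs, rownames(expr))
    if (length(missing_genes))
        stop("hub gene(s) absent from expression: ",
            paste(missing_genes, collapse = ", "))
    if (ncol(expr) < 3L) stop("need >= 3 samples")
    x <- t(expr[hubs, , drop = FALSE])
    const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
    cm <- suppressWarnings(cor(x, method = method))
    if (any(const)) {
        warning("constant gene(s), correlation undefined: ",
            paste(hubs[const], collapse = ", "))
        cm[const, ] <- NA_real_
        cm[, const] <- NA_real_
    }
    diag(cm) <- 1
    cm
}
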