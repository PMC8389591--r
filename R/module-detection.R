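# Overlapping community ("module") detection in the weighted network.
#
# Seed-expansion scheme over the D-weighted graph:
#   1. sort edges by descending weight;
#   2. the heaviest unvisited edge seeds a community;
#   3. greedily add the adjacent node with the largest positive gain in the
#      weighted fitness f(C) = W_in(C) / (W_in(C) + W_out(C))^alpha, where
#      W_in sums internal edge weights and W_out sums boundary edge weights;
#   4. prune members whose removal increases f (keeping the community
#      connected);
#   5. mark internal edges visited and repeat from 2.
# Nodes (not edges) may join several communities, which is what makes the
# covers overlapping. All ties are broken lexicographically on gene names so
# the result is deterministic and independent of input edge order.

# internal adjacency representation of a WeightedNetwork
.adjacency <- function(net) {
    e <- edgeTable(net)
    nodes <- nodeSet(net)
    adj <- vector("list", length(nodes))
    names(adj) <- nodes
    for (nd in nodes) adj[[nd]] <- numeric()
    for (i in seq_len(nrow(e))) {
        adj[[e$gene_x[i]]][e$gene_y[i]] <- e$D[i]
        adj[[e$gene_y[i]]][e$gene_x[i]] <- e$D[i]
    }
    list(adj = adj, strength = vapply(adj, sum, 0), edges = e)
}

#' Neighborhood proximity of two adjacent nodes
#'
#' P(u, v) = (w(u,v) + sum over common neighbors c of min(w(u,c), w(v,c))) /
#' min(s(u), s(v)), with s the weighted degree. A symmetric, non-negative
#' closeness measure: direct weight plus shared-neighborhood support,
#' normalized by the weaker endpoint.
#'
#' @param net a [WeightedNetwork-class].
#' @param u,v adjacent gene names.
#' @return non-negative proximity.
#' @export
nodeProximity <- function(net, u, v) {
    a <- .adjacency(net)
    wu <- a$adj[[u]]; wv <- a$adj[[v]]
    if (is.null(wu) || is.null(wv) || !(v %in% names(wu)))
        stop("nodeProximity is defined for adjacent node pairs only")
    common <- intersect(names(wu), names(wv))
    common <- setdiff(common, c(u, v))
    num <- wu[[v]] + sum(pmin(wu[common], wv[common]))
    num / min(a$strength[[u]], a$strength[[v]])
}

.fitness <- function(w_in, w_out, alpha) {
    if (w_in + w_out <= 0) return(0)
    w_in / (w_in + w_out)^alpha
}

# connectivity of `members` in the adjacency list
.isConnected <- function(adj, members) {
    if (length(members) <= 1L) return(TRUE)
    seen <- members[1L]
    frontier <- seen
    while (length(frontier)) {
        nxt <- unique(unlist(lapply(frontier, function(m)
            intersect(names(adj[[m]]), members)), use.names = FALSE))
        frontier <- setdiff(nxt, seen)
        seen <- c(seen, frontier)
    }
    length(seen) == length(members)
}

#' Detect overlapping modules in a weighted network
#'
#' Seed-expansion community detection (see the file-level description): each
#' community is a local maximum of the fitness
#' f(C) = W_in(C) / (W_in(C) + W_out(C))^alpha under single-node addition and
#' removal, communities may share nodes, and the output is deterministic
#' given the network (ties broken lexicographically).
#'
#' @param net a [WeightedNetwork-class].
#' @param alpha fitness resolution exponent (default 1).
#' @param min_nodes smallest community size emitted (default 2).
#' @return list of [GeneModule-class], ids in detection order.
#' @export
detectModules <- function(net, alpha = 1.0, min_nodes = 2L) {
    a <- .adjacency(net)
    e <- a$edges
    if (nrow(e) == 0L) return(list())
    ord <- order(-e$D, e$gene_x, e$gene_y)
    e <- e[ord, , drop = FALSE]
    visited <- rep(FALSE, nrow(e))
    ekey <- paste(e$gene_x, e$gene_y)
    covers <- list()

    for (i in seq_len(nrow(e))) {
        if (visited[i]) next
        C <- sort(c(e$gene_x[i], e$gene_y[i]))
        w_in <- e$D[i]
        w_out <- a$strength[e$gene_x[i]] + a$strength[e$gene_y[i]] -
            2 * e$D[i]
        f <- .fitness(w_in, w_out, alpha)

        repeat {
            changed <- FALSE
            # expansion: best single-node addition
            repeat {
                nb <- setdiff(unique(unlist(lapply(C, function(m)
                    names(a$adj[[m]])), use.names = FALSE)), C)
                if (!length(nb)) break
                nb <- sort(nb)
                gains <- vapply(nb, function(v) {
                    av <- sum(a$adj[[v]][intersect(names(a$adj[[v]]), C)])
                    bv <- a$strength[[v]] - av
                    .fitness(w_in + av, w_out - av + bv, alpha) - f
                }, 0)
                best <- which.max(gains)   # first max = lexicographic tie
                if (gains[best] <= 1e-12) break
                v <- nb[best]
                av <- sum(a$adj[[v]][intersect(names(a$adj[[v]]), C)])
                bv <- a$strength[[v]] - av
                w_in <- w_in + av
                w_out <- w_out - av + bv
                f <- .fitness(w_in, w_out, alpha)
                C <- sort(c(C, v))
                changed <- TRUE
            }
            # pruning: best single-node removal that keeps connectivity
            repeat {
                if (length(C) <= 2L) break
                gains <- vapply(C, function(m) {
                    rest <- setdiff(C, m)
                    if (!.isConnected(a$adj, rest)) return(-Inf)
                    am <- sum(a$adj[[m]][intersect(names(a$adj[[m]]), rest)])
                    .fitness(w_in - am,
                        w_out - (a$strength[[m]] - am) + am, alpha) - f
                }, 0)
                best <- which.max(gains)
                if (gains[best] <= 1e-12) break
                m <- C[best]
                rest <- setdiff(C, m)
                am <- sum(a$adj[[m]][intersect(names(a$adj[[m]]), rest)])
                w_in <- w_in - am
                w_out <- w_out - (a$strength[[m]] - am) + am
                f <- .fitness(w_in, w_out, alpha)
                C <- rest
                changed <- TRUE
            }
            if (!changed) break
        }

        # mark internal edges visited (the seed edge always, for progress)
        internal <- e$gene_x %in% C & e$gene_y %in% C
        visited[internal] <- TRUE
        visited[i] <- TRUE
        covers[[length(covers) + 1L]] <- C
    }

    covers <- covers[!duplicated(vapply(covers,
        function(x) paste(x, collapse = "\r"), ""))]
    covers <- covers[vapply(covers, length, 0L) >= min_nodes]

    lapply(seq_along(covers), function(k) {
        C <- covers[[k]]
        sub <- e[e$gene_x %in% C & e$gene_y %in% C,
            c("gene_x", "gene_y", "D"), drop = FALSE]
        sub <- sub[order(sub$gene_x, sub$gene_y), , drop = FALSE]
        rownames(sub) <- NULL
        new("GeneModule", id = k, genes = C, edges = sub)
    })
}

#' Filter modules by size
#'
#' Keeps modules with at least `min_size` nodes (default 6, i.e. strictly
#' more than five) or, with `criterion = "edges"`, at least `min_size`
#' induced edges.
#'
#' @param modules list of [GeneModule-class].
#' @param min_size smallest retained size.
#' @param criterion count nodes (default) or edges.
#' @return filtered list (original module ids preserved).
#' @export
filterModules <- function(modules, min_size = 6L,
                          criterion = c("nodes", "edges")) {
    criterion <- match.arg(criterion)
    keep <- vapply(modules, function(m)
        if (criterion == "nodes") length(moduleGenes(m)) >= min_size
        else nrow(moduleEdges(m)) >= min_size, TRUE)
    modules[keep]
}
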