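# Centrality rankings, hypergeometric over-representation, multi-set hub
# intersection, and Spearman hub correlations against brute-force oracles.

test_that("centralities match hand analysis on symmetric graphs", {
    tri <- methods::new("GeneModule", id = 1L, genes = c("a", "b", "c"),
        edges = data.frame(gene_x = c("a", "a", "b"),
            gene_y = c("b", "c", "c"), D = 1))
    deg <- rankCentrality(tri, "weighted_degree")
    expect_equal(unname(deg$scores), rep(2, 3))
    eig <- rankCentrality(tri, "eigenvector")
    expect_equal(unname(eig$scores), rep(1 / sqrt(3), 3), tolerance = 1e-9)

    star <- methods::new("GeneModule", id = 2L,
        genes = c("hub", paste0("l", 1:4)),
        edges = data.frame(gene_x = "hub", gene_y = paste0("l", 1:4), D = 1))
    degs <- rankCentrality(star, "weighted_degree")
    expect_equal(degs$scores[["hub"]], 4)
    expect_equal(unname(degs$scores[paste0("l", 1:4)]), rep(1, 4))
    expect_equal(degs$top_k[1], "hub")
    eigs <- rankCentrality(star, "eigenvector")
    expect_equal(names(which.max(eigs$scores)), "hub")
})

test_that("eigenvector centrality matches a dense eigendecomposition", {
    set.seed(12)
    genes <- paste0("v", 1:8)
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.6
    e <- data.frame(gene_x = pairs[keep, 1], gene_y = pairs[keep, 2],
        D = runif(sum(keep), 0.2, 3))
    mod <- methods::new("GeneModule", id = 1L,
        genes = sort(unique(c(e$gene_x, e$gene_y))), edges = e)
    res <- suppressWarnings(rankCentrality(mod, "eigenvector"))

    genes <- moduleGenes(mod)
    A <- matrix(0, length(genes), length(genes),
        dimnames = list(genes, genes))
    for (i in seq_len(nrow(e))) {
        A[e$gene_x[i], e$gene_y[i]] <- e$D[i]
        A[e$gene_y[i], e$gene_x[i]] <- e$D[i]
    }
    # restrict to the largest connected component, as the implementation does
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        A > 0, mode = "undirected"))
    main <- which(comp$membership == which.max(comp$csize))
    v <- abs(eigen(A[main, main])$vectors[, 1])
    v <- v / sqrt(sum(v^2))
    cosang <- abs(sum(res$scores[rownames(A)[main]] * v))
    expect_gt(cosang, 1 - 1e-8)
})

test_that("centrality ranking is equivariant under node relabeling", {
    set.seed(13)
    e <- data.frame(gene_x = c("a", "a", "b", "c"),
        gene_y = c("b", "c", "c", "d"), D = c(2, 1, 3, 0.5))
    mod <- methods::new("GeneModule", id = 1L, genes = c("a", "b", "c", "d"),
        edges = e)
    relab <- c(a = "w", b = "x", c = "y", d = "z")
    e2 <- data.frame(gene_x = unname(relab[e$gene_x]),
        gene_y = unname(relab[e$gene_y]), D = e$D)
    mod2 <- methods::new("GeneModule", id = 1L, genes = unname(relab),
        edges = e2)
    for (kind in c("weighted_degree", "eigenvector")) {
        s1 <- rankCentrality(mod, kind)$scores
        s2 <- rankCentrality(mod2, kind)$scores
        expect_equal(unname(s2[relab[names(s1)]]), unname(s1),
            tolerance = 1e-9)
    }
})

test_that("hypergeometric enrichment matches exact enumeration", {
    # query = set = universe: the only outcome, p = 1
    uni <- paste0("g", 1:6)
    r <- hypergeometricEnrichment(uni, list(S = uni), uni)
    expect_equal(r$p, 1)

    # universe 10, set 5, query 5, overlap 5 -> 1 / C(10,5)
    uni10 <- paste0("g", 1:10)
    r2 <- hypergeometricEnrichment(uni10[1:5], list(S = uni10[1:5]), uni10)
    expect_equal(r2$p, 1 / choose(10, 5), tolerance = 1e-12)
    expect_equal(r2$p, 1 / 252, tolerance = 1e-6)

    # zero overlap with positive expectation: tail includes >= 0, p = 1
    r3 <- hypergeometricEnrichment(uni10[1:5], list(S = uni10[6:10]), uni10)
    expect_equal(r3$p, 1)

    # random configurations vs combinatorial enumeration
    set.seed(40)
    for (i in 1:50) {
        u <- sample(5:12, 1)
        uni <- paste0("g", seq_len(u))
        gs <- sample(uni, sample(1:u, 1))
        q <- sample(uni, sample(1:u, 1))
        r <- hypergeometricEnrichment(q, list(S = gs), uni)
        expect_equal(r$p,
            enum_hypergeom_p(r$overlap, length(gs), length(q), u),
            tolerance = 1e-12)
    }
    expect_error(hypergeometricEnrichment("g1", list(S = "g1"), character()),
        "universe")
})

test_that("significant-pathway gene extraction respects p and top_n", {
    sets <- list(A = c("g1", "g2"), B = c("g3", "g4"), C = c("g5"))
    enr <- data.frame(set_name = c("A", "B", "C"), p = c(0.01, 0.2, 0.03))
    out <- significantPathwayGenes(enr, sets, top_n = 10L, alpha = 0.05)
    expect_setequal(out, c("g1", "g2", "g5"))
    out1 <- significantPathwayGenes(enr[order(enr$p), ], sets, top_n = 1L,
        alpha = 0.05)
    expect_setequal(out1, c("g1", "g2"))
    expect_setequal(significantPathwayGenes(enr, sets,
        restrict = c("g2", "g9")), "g2")
})

test_that("hub intersection is an exact multi-way set intersection", {
    expect_equal(intersectHubs(c("A", "B", "C", "D"), c("A", "B", "X"),
        c("A", "B", "Y"), c("A", "Z", "B")), c("A", "B"))
    expect_length(intersectHubs(character(), c("A", "B")), 0L)
    s <- c("p", "q", "r")
    expect_equal(intersectHubs(s, s, s, s), sort(s))
})

test_that("hub correlations are Spearman and match a rank-Pearson oracle", {
    set.seed(15)
    expr <- matrix(rnorm(2 * 50), 2, 50,
        dimnames = list(c("h1", "h2"), paste0("s", 1:50)))
    cm <- hubCorrelations(expr, c("h1", "h2"))
    oracle <- cor(rank(expr["h1", ]), rank(expr["h2", ]))
    expect_equal(cm["h1", "h2"], oracle, tolerance = 1e-12)
    expect_equal(diag(cm), c(h1 = 1, h2 = 1))
    expect_equal(cm, t(cm))

    # rank invariance under a monotone transform
    expr2 <- rbind(expr, h3 = exp(expr["h1", ]))
    cm2 <- hubCorrelations(expr2, c("h1", "h3"))
    expect_equal(cm2["h1", "h3"], 1)

    # constant gene: NA with a warning
    expr3 <- rbind(expr, h4 = rep(2, 50))
    expect_warning(cm3 <- hubCorrelations(expr3, c("h1", "h4")), "constant")
    expect_true(is.na(cm3["h1", "h4"]))
    expect_error(hubCorrelations(expr, c("h1", "nope")), "nope")
})
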