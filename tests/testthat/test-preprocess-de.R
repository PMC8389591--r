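# Differential expression: duplicate collapsing, the moderated t statistic
# (checked against its pooled-t limit, limma, and a type-I error simulation),
# BH adjustment against a brute-force step-up, and threshold filtering.

test_that("duplicate gene rows collapse to their per-sample mean", {
    m <- rbind(c(2, 4), c(4, 6), c(1, 1))
    rownames(m) <- c("G1", "G1", "G2")
    colnames(m) <- c("s1", "s2")
    out <- collapseDuplicates(m)
    expect_equal(out["G1", ], c(s1 = 3, s2 = 5))
    expect_equal(out["G2", ], c(s1 = 1, s2 = 1))

    # no duplicates: identity
    m2 <- m[c(1, 3), ]
    expect_identical(collapseDuplicates(m2), m2)

    # brute-force mean oracle on random duplicates
    set.seed(4)
    m3 <- matrix(rnorm(15), 3, 5,
        dimnames = list(rep("gX", 3), paste0("s", 1:5)))
    out3 <- collapseDuplicates(m3)
    manual <- vapply(seq_len(5), function(j) {
        tot <- 0
        for (i in 1:3) tot <- tot + m3[i, j]
        tot / 3
    }, 0)
    expect_equal(unname(out3["gX", ]), manual)

    expect_error(collapseDuplicates(matrix(numeric(), 0, 0)), "non-empty")
})

test_that("moderated t reduces to the pooled t when the prior df is zero", {
    set.seed(7)
    m <- matrix(rnorm(30 * 12), 30, 12,
        dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    cls <- rep(c("tumor", "normal"), each = 6)
    res <- moderatedT(m, cls, prior_df = 0)
    for (i in c(1, 13, 30)) {
        tt <- t.test(m[i, 1:6], m[i, 7:12], var.equal = TRUE)
        expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
        expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    }
})

test_that("a gene with identical class means gives t = 0 and p = 1", {
    set.seed(8)
    m <- matrix(rnorm(10 * 8), 10, 8,
        dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
    m[1, 5:8] <- m[1, 1:4]   # identical values in both classes
    cls <- rep(c("tumor", "normal"), each = 4)
    res <- moderatedT(m, cls)
    expect_equal(res$log2fc[1], 0)
    expect_equal(res$t_stat[1], 0)
    expect_equal(res$p[1], 1)
})

test_that("moderated t matches limma's empirical-Bayes implementation", {
    library(limma)
    set.seed(21)
    n_t <- 8L; n_n <- 6L
    m <- matrix(rnorm(300 * (n_t + n_n), sd = rep(sqrt(rchisq(300, 4) / 4),
        n_t + n_n)), 300, n_t + n_n,
        dimnames = list(paste0("g", 1:300), paste0("s", 1:(n_t + n_n))))
    cls <- c(rep("tumor", n_t), rep("normal", n_n))
    res <- moderatedT(m, cls)

    design <- cbind(Intercept = 1, tumor = as.integer(cls == "tumor"))
    fit <- eBayes(lmFit(m, design))
    expect_equal(res$log2fc, unname(fit$coefficients[, "tumor"]),
        tolerance = 1e-10)
    expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-3)
    expect_equal(res$t_stat, unname(fit$t[, "tumor"]), tolerance = 1e-6)
    expect_equal(res$p, unname(fit$p.value[, "tumor"]), tolerance = 1e-6)
})

test_that("moderated t controls the type-I error on null genes", {
    set.seed(31)
    hits <- 0L; total <- 0L
    for (rep in 1:100) {
        m <- matrix(rnorm(500 * 16), 500, 16,
            dimnames = list(paste0("g", 1:500), paste0("s", 1:16)))
        res <- moderatedT(m, rep(c("tumor", "normal"), each = 8))
        hits <- hits + sum(res$p < 0.05)
        total <- total + 500L
    }
    expect_lt(abs(hits / total - 0.05), 0.01)
})

test_that("moderated t p-values are invariant to within-class column order", {
    set.seed(12)
    m <- matrix(rnorm(20 * 10), 20, 10,
        dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    cls <- rep(c("tumor", "normal"), each = 5)
    a <- moderatedT(m, cls)
    b <- moderatedT(m[, c(5:1, 10:6)], cls)
    expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
        c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    set.seed(5)
    for (i in 1:1000) {
        p <- runif(sample(1:50, 1))
        expect_equal(bhAdjust(p), naive_bh(p), tolerance = 1e-14)
    }
})

test_that("DEG filtering uses strict thresholds and stays disjoint", {
    res <- data.frame(
        gene = c("a", "b", "c", "d"),
        log2fc = c(2.0, 2.5, -3, 0.1),
        p_adj = c(0.01, 0.01, 0.04, 0.001))
    out <- filterDEGs(res)
    expect_false("a" %in% out$up)      # boundary log2fc = 2 excluded
    expect_equal(out$up, "b")
    expect_equal(out$down, "c")
    expect_length(intersect(out$up, out$down), 0)

    empty <- filterDEGs(data.frame(gene = character(), log2fc = numeric(),
        p_adj = numeric()))
    expect_length(empty$up, 0)
    expect_length(empty$down, 0)
})

test_that("DEG counts are monotone in the thresholds", {
    set.seed(14)
    d <- syntheticDesign(n_genes = 60L, module_sizes = rep(10L, 3L),
        n_tumor = 40L, n_normal = 40L, de_lfc = 2.5, seed = 14L)
    ds <- generateDataset(d, generateScaffold(d))
    de <- runDE(ds$expr, ds$sample_class)
    counts_lfc <- vapply(c(0.5, 1, 2, 3), function(thr) {
        f <- filterDEGs(de, lfc_thr = thr)
        length(f$up) + length(f$down)
    }, 0)
    expect_true(all(diff(counts_lfc) <= 0))
    counts_alpha <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
        f <- filterDEGs(de, alpha = a)
        length(f$up) + length(f$down)
    }, 0)
    expect_true(all(diff(counts_alpha) <= 0))
})

test_that("planted DE genes are recovered with high power", {
    recalls <- vapply(1:20, function(s) {
        d <- syntheticDesign(n_genes = 40L, module_sizes = rep(10L, 3L),
            n_tumor = 50L, n_normal = 50L, de_lfc = 3, seed = s)
        sc <- generateScaffold(d)
        ds <- generateDataset(d, sc)
        de <- runDE(ds$expr, ds$sample_class)
        f <- filterDEGs(de)
        length(intersect(f$up, sc$truth$de_genes)) /
            length(sc$truth$de_genes)
    }, 0)
    expect_gte(mean(recalls), 29 / 30)
})
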