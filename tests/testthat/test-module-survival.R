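# Module eigengene (SVD), median split, Kaplan-Meier product-limit estimate
# and the log-rank report, against hand computations and naive-loop oracles.

test_that("rank-1 modules give variance_explained 1 and the shared profile", {
    set.seed(3)
    prof <- rnorm(20)
    m <- matrix(rep(prof, each = 5), 5, 20,
        dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
    m <- m * c(1, 2, 3, 4, 5) + c(0, 1, 2, 3, 4)   # same shape per row
    me <- moduleEigengene(m, paste0("g", 1:5), 1L)
    expect_equal(varianceExplained(me), 1, tolerance = 1e-12)
    std <- (prof - mean(prof)) / sd(prof)
    expect_equal(abs(cor(eigengeneScores(me), std)), 1, tolerance = 1e-12)
    expect_gt(cor(eigengeneScores(me), std), 0)   # sign anchored
})

test_that("two orthogonal equal-norm profiles split the variance evenly", {
    m <- rbind(g1 = c(1, 1, -1, -1), g2 = c(1, -1, 1, -1))
    colnames(m) <- paste0("s", 1:4)
    me <- moduleEigengene(m, c("g1", "g2"), 1L)
    expect_equal(varianceExplained(me), 0.5, tolerance = 1e-12)
})

test_that("the eigengene matches a brute-force eigendecomposition", {
    set.seed(10)
    m <- matrix(rnorm(10 * 50), 10, 50,
        dimnames = list(paste0("g", 1:10), paste0("s", 1:50)))
    me <- moduleEigengene(m, paste0("g", 1:10), 1L)
    xs <- t(scale(t(m)))
    ev <- eigen(crossprod(xs))$vectors[, 1]
    cosang <- abs(sum(eigengeneScores(me) * ev))
    expect_gt(cosang, 1 - 1e-10)
    expect_lt(abs(mean(eigengeneScores(me))), 1e-10)
    expect_equal(sum(eigengeneScores(me)^2), 1, tolerance = 1e-10)
})

test_that("the eigengene is invariant to gene row order", {
    set.seed(11)
    m <- matrix(rnorm(8 * 30), 8, 30,
        dimnames = list(paste0("g", 1:8), paste0("s", 1:30)))
    a <- moduleEigengene(m, paste0("g", 1:8), 1L)
    b <- moduleEigengene(m[sample(8), ], paste0("g", 1:8), 1L)
    expect_equal(eigengeneScores(a), eigengeneScores(b), tolerance = 1e-10)
})

test_that("constant gene rows are dropped, erroring when too few remain", {
    m <- rbind(g1 = rep(1, 10), g2 = rnorm(10), g3 = rnorm(10))
    colnames(m) <- paste0("s", 1:10)
    expect_warning(me <- moduleEigengene(m, paste0("g", 1:3), 1L), "constant")
    expect_s4_class(me, "ModuleEigengene")
    m2 <- rbind(g1 = rep(1, 10), g2 = rep(2, 10), g3 = rnorm(10))
    colnames(m2) <- paste0("s", 1:10)
    expect_error(suppressWarnings(moduleEigengene(m2, paste0("g", 1:3), 1L)),
        "fewer than 2")
})

test_that("the median split sends the median itself to the high group", {
    expect_equal(medianSplit(c(a = 1, b = 2, c = 3, d = 4)),
        list(low = c("a", "b"), high = c("c", "d")))
    expect_equal(medianSplit(c(a = 1, b = 2, c = 3)),
        list(low = "a", high = c("b", "c")))
    expect_error(medianSplit(c(a = 1, b = 1, c = 1)), "empty group")
})

test_that("the Kaplan-Meier estimate matches hand product-limit values", {
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

    km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km2$time, c(1, 3))
    expect_equal(km2$survival[km2$time == 1], 2 / 3)
    expect_equal(km2$survival[km2$time == 3], 0)
    expect_equal(km2$n_risk[km2$time == 3], 1)

    km3 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))   # S identically 1
    expect_equal(nrow(km3), 0L)

    expect_error(kmEstimate(numeric(), numeric()), "at least one")
})

test_that("the log-rank report is symmetric and hand-checkable", {
    # identical groups: z = 0, p = 1, HR = 1
    lr <- logrankTest(c(1, 2), c(1, 1), c(1, 2), c(1, 1))
    expect_equal(lr$z, 0)
    expect_equal(lr$p, 1)
    expect_equal(lr$hazard_ratio, 1)

    # all early events in A vs all late in B: explicit hypergeometric table
    lr2 <- logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
    o <- naive_logrank(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
    expect_equal(lr2$chi2, o$chi2, tolerance = 1e-12)
    expect_equal(lr2$z, o$z, tolerance = 1e-12)

    # label swap: z negates, p unchanged, HR inverts
    lr3 <- logrankTest(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
    expect_equal(lr3$z, -lr2$z, tolerance = 1e-12)
    expect_equal(lr3$p, lr2$p, tolerance = 1e-12)
    expect_equal(lr3$hazard_ratio, 1 / lr2$hazard_ratio, tolerance = 1e-12)

    # schema invariants
    expect_equal(lr2$chi2, lr2$z^2)
    expect_true(lr2$ci_lower < lr2$hazard_ratio &&
        lr2$hazard_ratio < lr2$ci_upper)
    expect_equal(lr2$hazard_rate_a, 2 / 3)   # 2 events / 3 time units
    expect_error(logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
        "at least one event")
})

test_that("module evaluation handles empty input and absent genes", {
    out <- evaluateModules(list(), NULL, NULL, NULL, NULL)
    expect_equal(nrow(out$results), 0L)
    expect_length(out$significant, 0L)

    set.seed(6)
    d <- syntheticDesign(n_tumor = 60L, n_normal = 4L, seed = 6L)
    sc <- generateScaffold(d)
    ds <- generateDataset(d, sc)
    tum <- names(ds$sample_class)[ds$sample_class == "tumor"]
    sp <- splitTrainTest(tum, seed = 6L)
    ghost <- methods::new("GeneModule", id = 99L,
        genes = c("zz1", "zz2", "zz3"),
        edges = data.frame(gene_x = character(), gene_y = character(),
            D = numeric()))
    expect_warning(
        out2 <- evaluateModules(list(ghost),
            ds$expr[, sp$train], ds$survival[ds$survival$sample_id %in% sp$train, ],
            ds$expr[, sp$test], ds$survival[ds$survival$sample_id %in% sp$test, ]),
        "absent")
    expect_equal(nrow(out2$results), 0L)
})

test_that("a planted hazard-linked module is flagged significant", {
    d <- syntheticDesign(seed = 19L)   # hazard_coef = 1 by default
    sc <- generateScaffold(d)
    ds <- generateDataset(d, sc)
    tum <- names(ds$sample_class)[ds$sample_class == "tumor"]
    sp <- splitTrainTest(tum, seed = 19L)
    assign <- sc$truth$module_assignment
    mods <- lapply(1:5, function(m) methods::new("GeneModule",
        id = as.integer(m),
        genes = names(assign)[!is.na(assign) & assign == m],
        edges = data.frame(gene_x = character(), gene_y = character(),
            D = numeric())))
    out <- evaluateModules(mods,
        ds$expr[, sp$train], ds$survival[ds$survival$sample_id %in% sp$train, ],
        ds$expr[, sp$test], ds$survival[ds$survival$sample_id %in% sp$test, ])
    expect_true(sc$truth$survival_module_id %in% out$significant)
    expect_equal(out$results$chi2, out$results$z^2, tolerance = 1e-12)
})
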