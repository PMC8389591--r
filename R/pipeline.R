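# End-to-end orchestration: differential expression -> survival-stratified
# edge weighting -> overlapping module detection -> module survival screening
# -> hub selection. runAnalysis() works on in-memory objects; runPipeline()
# wraps it with file I/O, a config, logging and a run manifest.

#' Assemble a pipeline configuration
#'
#' @param expr,surv,edges,classes,gmt,degs,outdir input/output paths
#'   (`classes`, `gmt` and `degs` optional; without a class table every
#'   sample with a survival record is treated as tumor).
#' @param lfc,alpha_de DE thresholds (|log2FC| > lfc, adjusted p < alpha_de).
#' @param alpha_surv per-partition log-rank significance level.
#' @param min_module_size,module_criterion module size filter (count nodes or
#'   edges).
#' @param top_k centrality top-list size.
#' @param train_frac training fraction of the tumor samples.
#' @param stratify_rule longer/shorter split rule (see [stratifySurvival()]).
#' @param hub_cor_method hub correlation kind (spearman/pearson).
#' @param restrict_to_degs restrict the scaffold to DE genes before
#'   weighting (mirrors building the interaction network from DEGs).
#' @param fitness_alpha module-detection fitness exponent.
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(expr, surv, edges, outdir, classes = NULL,
                           gmt = NULL, degs = NULL, lfc = 2, alpha_de = 0.05,
                           alpha_surv = 0.05, min_module_size = 6L,
                           module_criterion = "nodes", top_k = 10L,
                           train_frac = 0.6, stratify_rule = "median_time",
                           hub_cor_method = "spearman",
                           restrict_to_degs = TRUE, fitness_alpha = 1,
                           seed = 1L) {
    cfg <- list(expr = expr, surv = surv, edges = edges, classes = classes,
        gmt = gmt, degs = degs, outdir = outdir, lfc = lfc,
        alpha_de = alpha_de,
        alpha_surv = alpha_surv, min_module_size = as.integer(min_module_size),
        module_criterion = module_criterion, top_k = as.integer(top_k),
        train_frac = train_frac, stratify_rule = stratify_rule,
        hub_cor_method = hub_cor_method,
        restrict_to_degs = isTRUE(restrict_to_degs),
        fitness_alpha = fitness_alpha, seed = as.integer(seed))
    for (thr in c("lfc", "alpha_de", "alpha_surv", "min_module_size",
        "top_k", "train_frac", "fitness_alpha"))
        if (cfg[[thr]] <= 0) stop(thr, " must be positive")
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [pipelineConfig()]; relative paths are kept
#' as given. Missing fields take the defaults.
#'
#' @param path YAML file.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

#' Run the analysis on in-memory objects
#'
#' The computational core of [runPipeline()]: differential expression,
#' train/test split of the tumor samples with survival records,
#' survival-stratified weighting of the scaffold on each partition,
#' overlapping module detection on the training network, module eigengene /
#' log-rank screening on both partitions, and hub selection from the most
#' significant module (smallest worst-partition p among modules significant
#' in both).
#'
#' @param expr genes-by-samples log2 expression matrix (duplicates allowed).
#' @param sample_class named character vector, "tumor"/"normal" per sample.
#' @param survival data.frame `sample_id`, `time`, `event` (tumor samples).
#' @param scaffold_edges data.frame `gene_x`, `gene_y`.
#' @param gene_sets optional named list of gene sets (enrichment skipped if
#'   NULL).
#' @param external_degs optional character vector: external validation DEG
#'   list (not intersected if NULL).
#' @param config a `pipelineConfig` (paths ignored); or NULL for defaults.
#' @return list with elements `de`, `degs`, `split`, `network_train`,
#'   `network_test`, `modules_all`, `modules`, `module_survival`,
#'   `selected_module`, `centrality`, `enrichment`, `pathway_genes`, `hubs`,
#'   `hub_correlations`, `counts`.
#' @export
runAnalysis <- function(expr, sample_class, survival, scaffold_edges,
                        gene_sets = NULL, external_degs = NULL,
                        config = NULL) {
    cfg <- if (is.null(config))
        pipelineConfig(expr = "", surv = "", edges = "", outdir = "")
        else config

    expr <- collapseDuplicates(expr)
    cls <- sample_class[colnames(expr)]

    # stage 1: differential expression
    de <- runDE(expr, cls, lfc_thr = cfg$lfc, alpha = cfg$alpha_de)
    deg_lists <- filterDEGs(de, lfc_thr = cfg$lfc, alpha = cfg$alpha_de)
    degs <- c(deg_lists$up, deg_lists$down)
    message("DE: ", length(deg_lists$up), " up, ",
        length(deg_lists$down), " down")

    # stage 2: split + survival-stratified weighting
    tumor_ids <- intersect(names(cls)[cls == "tumor"], survival$sample_id)
    split <- splitTrainTest(tumor_ids, train_frac = cfg$train_frac,
        seed = .stageSeed(cfg$seed, "split"))
    edges <- scaffold_edges
    in_expr <- edges$gene_x %in% rownames(expr) &
        edges$gene_y %in% rownames(expr)
    if (!all(in_expr)) {
        message(sum(!in_expr), " scaffold edge(s) dropped: gene not in ",
            "expression matrix")
        edges <- edges[in_expr, , drop = FALSE]
    }
    if (cfg$restrict_to_degs)
        edges <- edges[edges$gene_x %in% degs & edges$gene_y %in% degs, ,
            drop = FALSE]
    strata_train <- stratifySurvival(survival, split$train,
        rule = cfg$stratify_rule)
    strata_test <- stratifySurvival(survival, split$test,
        rule = cfg$stratify_rule)
    net_train <- weightNetwork(edges, expr, strata_train)
    net_test <- weightNetwork(edges, expr, strata_test)
    message("weighted network (train): ", length(nodeSet(net_train)),
        " nodes, ", nrow(edgeTable(net_train)), " edges")

    # stage 3: overlapping module detection on the training network
    modules_all <- detectModules(net_train, alpha = cfg$fitness_alpha)
    modules <- filterModules(modules_all, min_size = cfg$min_module_size,
        criterion = cfg$module_criterion)
    message("modules: ", length(modules_all), " detected, ",
        length(modules), " with >= ", cfg$min_module_size, " ",
        cfg$module_criterion)

    # stage 4: module survival screening on both partitions
    surv_train <- survival[survival$sample_id %in% split$train, ,
        drop = FALSE]
    surv_test <- survival[survival$sample_id %in% split$test, , drop = FALSE]
    ev <- evaluateModules(modules,
        expr[, split$train, drop = FALSE], surv_train,
        expr[, split$test, drop = FALSE], surv_test,
        alpha = cfg$alpha_surv)
    message("modules significant in both partitions: ",
        length(ev$significant))

    selected <- NULL
    if (length(ev$significant)) {
        worst <- vapply(ev$significant, function(id)
            max(ev$results$p[ev$results$module_id == id]), 0)
        sel_id <- ev$significant[order(worst, ev$significant)][1L]
        selected <- modules[[which(vapply(modules, moduleId, 0L) == sel_id)]]
    }

    # stage 5: hub selection from the selected module
    centrality <- enrichment <- hub_cors <- NULL
    pathway_genes <- character()
    hubs <- character()
    if (!is.null(selected)) {
        centrality <- list(
            weighted_degree = rankCentrality(selected, "weighted_degree",
                k = cfg$top_k),
            eigenvector = rankCentrality(selected, "eigenvector",
                k = cfg$top_k))
        cand <- list(centrality$weighted_degree$top_k,
            centrality$eigenvector$top_k)
        if (!is.null(gene_sets)) {
            enrichment <- hypergeometricEnrichment(moduleGenes(selected),
                gene_sets, universe = rownames(expr))
            pathway_genes <- significantPathwayGenes(enrichment, gene_sets,
                top_n = 10L, alpha = 0.05,
                restrict = moduleGenes(selected))
            cand <- c(cand, list(pathway_genes))
        }
        if (!is.null(external_degs))
            cand <- c(cand, list(external_degs))
        hubs <- do.call(intersectHubs, cand)
        message("hub set: ", length(hubs), " gene(s)")
        if (length(hubs) >= 2L)
            hub_cors <- hubCorrelations(
                expr[, names(cls)[cls == "tumor"], drop = FALSE], hubs,
                method = cfg$hub_cor_method)
    }

    list(de = de, degs = deg_lists, split = split,
        network_train = net_train, network_test = net_test,
        modules_all = modules_all, modules = modules,
        module_survival = ev, selected_module = selected,
        centrality = centrality, enrichment = enrichment,
        pathway_genes = pathway_genes, hubs = hubs,
        hub_correlations = hub_cors,
        counts = list(
            n_up = length(deg_lists$up), n_down = length(deg_lists$down),
            n_nodes = length(nodeSet(net_train)),
            n_edges = nrow(edgeTable(net_train)),
            n_modules = length(modules_all),
            n_modules_filtered = length(modules),
            n_significant_both = length(ev$significant),
            n_hubs = length(hubs)))
}

#' Validate pipeline inputs
#'
#' Checks sample-ID consistency between expression, classes and survival,
#' gene-ID consistency between expression and scaffold, class balance, and
#' threshold sanity. Reports issues; never raises.
#'
#' @param config a `pipelineConfig` with existing input paths.
#' @return data.frame with columns `issue`, `detail` (zero rows when clean).
#' @export
validateInputs <- function(config) {
    issues <- list()
    add <- function(issue, detail)
        issues[[length(issues) + 1L]] <<- data.frame(issue = issue,
            detail = detail, stringsAsFactors = FALSE)
    for (f in c("expr", "surv", "edges")) {
        if (is.null(config[[f]]) || !file.exists(config[[f]])) {
            add("missing file", paste0(f, ": ", config[[f]]))
        }
    }
    if (length(issues))
        return(do.call(rbind, issues))
    expr <- readExpression(config$expr)
    surv <- readSurvival(config$surv)
    edges <- readEdgeList(config$edges)
    cls <- NULL
    if (!is.null(config$classes) && file.exists(config$classes))
        cls <- readSampleClass(config$classes)
    unmatched <- setdiff(surv$sample_id, colnames(expr))
    if (length(unmatched))
        add("unmatched sample",
            paste("survival sample(s) not in expression:",
                paste(head(unmatched, 5L), collapse = ", ")))
    if (!is.null(cls)) {
        miss <- setdiff(names(cls), colnames(expr))
        if (length(miss))
            add("unmatched sample",
                paste("class table sample(s) not in expression:",
                    paste(head(miss, 5L), collapse = ", ")))
        if (sum(cls == "tumor") < 2L || sum(cls == "normal") < 2L)
            add("class balance", "need >= 2 samples per class for DE")
    }
    bad_genes <- setdiff(unique(c(edges$gene_x, edges$gene_y)),
        rownames(expr))
    if (length(bad_genes))
        add("unmatched gene",
            paste("edge gene(s) not in expression:",
                paste(head(bad_genes, 5L), collapse = ", ")))
    if (config$train_frac <= 0 || config$train_frac >= 1)
        add("threshold", "train_frac must be in (0, 1)")
    for (thr in c("alpha_de", "alpha_surv"))
        if (config[[thr]] <= 0 || config[[thr]] >= 1)
            add("threshold", paste(thr, "must be in (0, 1)"))
    if (length(issues)) do.call(rbind, issues) else
        data.frame(issue = character(), detail = character())
}

#' Run the full pipeline from files
#'
#' Reads the configured inputs, runs [runAnalysis()], writes every
#' intermediate table to `outdir`, and returns (and writes) a run manifest.
#' Rerunning with the same config and seed reproduces byte-identical tabular
#' outputs.
#'
#' @param config a `pipelineConfig` (see [pipelineConfig()],
#'   [readPipelineConfig()]).
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    if (!file.exists(config$expr))
        stop("expression matrix not found: ", config$expr)
    if (!file.exists(config$surv))
        stop("survival table not found: ", config$surv)
    if (!file.exists(config$edges))
        stop("edge list not found: ", config$edges)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

    expr <- readExpression(config$expr)
    surv <- readSurvival(config$surv)
    edges <- readEdgeList(config$edges)
    cls <- if (!is.null(config$classes) && file.exists(config$classes))
        readSampleClass(config$classes)
    else
        setNames(ifelse(colnames(expr) %in% surv$sample_id,
            "tumor", "normal"), colnames(expr))
    gene_sets <- if (!is.null(config$gmt)) {
        if (!file.exists(config$gmt))
            stop("gene-set collection not found: ", config$gmt)
        readGMT(config$gmt)
    }
    ext_degs <- if (!is.null(config$degs)) {
        if (!file.exists(config$degs))
            stop("external DEG list not found: ", config$degs)
        readDEGList(config$degs)
    }

    res <- runAnalysis(expr, cls, surv, edges, gene_sets = gene_sets,
        external_degs = ext_degs, config = config)

    out <- function(f) file.path(config$outdir, f)
    stages <- list()
    .writeTSV(res$de, out("de_table.tsv"))
    stages$de <- list(output = out("de_table.tsv"),
        n_genes = nrow(res$de), n_up = res$counts$n_up,
        n_down = res$counts$n_down)
    writeWeightedNetwork(res$network_train, out("weighted_train.tsv"))
    writeWeightedNetwork(res$network_test, out("weighted_test.tsv"))
    stages$weighting <- list(
        output = c(out("weighted_train.tsv"), out("weighted_test.tsv")),
        n_nodes = res$counts$n_nodes, n_edges = res$counts$n_edges,
        n_train = length(res$split$train), n_test = length(res$split$test))
    writeModules(res$modules, out("modules_membership.tsv"),
        out("modules_edges.tsv"))
    stages$modules <- list(
        output = c(out("modules_membership.tsv"), out("modules_edges.tsv")),
        n_detected = res$counts$n_modules,
        n_filtered = res$counts$n_modules_filtered)
    .writeTSV(res$module_survival$results, out("module_survival.tsv"))
    stages$survival <- list(output = out("module_survival.tsv"),
        n_significant_both = res$counts$n_significant_both,
        significant_ids = res$module_survival$significant)
    if (!is.null(res$selected_module)) {
        for (kind in names(res$centrality)) {
            r <- res$centrality[[kind]]
            .writeTSV(data.frame(gene = names(r$scores),
                score = unname(r$scores)),
                out(paste0("centrality_", kind, ".tsv")))
        }
        if (!is.null(res$enrichment))
            .writeTSV(res$enrichment, out("enrichment.tsv"))
        jsonlite::write_json(res$hubs, out("hubs.json"))
        if (!is.null(res$hub_correlations))
            .writeTSV(data.frame(gene = rownames(res$hub_correlations),
                res$hub_correlations, check.names = FALSE),
                out("hub_correlations.tsv"))
        stages$hubs <- list(
            output = out("hubs.json"),
            selected_module = moduleId(res$selected_module),
            n_hubs = res$counts$n_hubs, hubs = res$hubs)
    } else {
        stages$hubs <- list(output = character(), selected_module = NULL,
            n_hubs = 0L, hubs = character())
    }

    manifest <- list(
        config = unclass(config),
        versions = list(
            package = as.character(utils::packageVersion("SurvModNet")),
            r = paste(R.version$major, R.version$minor, sep = ".")),
        stages = stages,
        timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
    invisible(manifest)
}
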