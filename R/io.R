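# Plain-text readers and writers for the pipeline's tabular formats: TSV
# expression matrices (genes x samples), survival tables, edge lists, GMT
# gene-set collections, weighted networks and module membership tables.
# All writers emit deterministic, header-carrying TSV.

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene-by-sample expression TSV
#'
#' First column: gene identifier (column name free); remaining columns:
#' samples, named in the header. Values are log2-scale expression.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames (duplicate
#'   gene rows are kept; collapse with [collapseDuplicates()]).
#' @export
readExpression <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    m
}

#' Write a gene-by-sample expression TSV
#' @param expr numeric matrix, gene rownames, sample colnames.
#' @param path output file.
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
        stringsAsFactors = FALSE)
    .writeTSV(df, path)
}

#' Read a survival table
#'
#' Expects columns `sample_id`, `time`, `event` (0 censored / 1 death).
#' @param path TSV file.
#' @return data.frame.
#' @export
readSurvival <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "time", "event")
    if (!all(need %in% names(df)))
        stop("survival table must have columns: ",
            paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in survival")
    if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
    df[need]
}

#' Read a sample-class table
#' Expects columns `sample_id`, `class` (tumor/normal).
#' @param path TSV file.
#' @return named character vector (names = sample ids).
#' @export
readSampleClass <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "class") %in% names(df)))
        stop("class table must have columns sample_id, class")
    setNames(df$class, df$sample_id)
}

#' Read a scaffold edge list
#'
#' First two columns are the endpoints; an optional numeric column (e.g. an
#' interaction confidence score) can be used as a filter.
#'
#' @param path TSV file.
#' @param min_score optional minimum value of `score_col` (strict >).
#' @param score_col name of the filter column.
#' @return data.frame with columns `gene_x`, `gene_y`.
#' @export
readEdgeList <- function(path, min_score = NULL, score_col = "score") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("edge list needs at least two columns")
    if (!is.null(min_score)) {
        if (!score_col %in% names(df))
            stop("no column '", score_col, "' to filter on")
        df <- df[df[[score_col]] > min_score, , drop = FALSE]
    }
    out <- data.frame(gene_x = as.character(df[[1L]]),
        gene_y = as.character(df[[2L]]), stringsAsFactors = FALSE)
    out <- out[out$gene_x != out$gene_y, , drop = FALSE]
    flip <- out$gene_x > out$gene_y
    tmp <- out$gene_x[flip]
    out$gene_x[flip] <- out$gene_y[flip]
    out$gene_y[flip] <- tmp
    out <- unique(out[order(out$gene_x, out$gene_y), , drop = FALSE])
    rownames(out) <- NULL
    out
}

#' Write a weighted network as TSV
#'
#' Columns: `gene_x`, `gene_y`, `r_L`, `r_S`, `z_L`, `z_S`, `D`; the stratum
#' sizes are recorded on a leading `#` comment line so the file round-trips.
#'
#' @param net a [WeightedNetwork-class].
#' @param path output file.
#' @export
writeWeightedNetwork <- function(net, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# n_long=%d n_short=%d", net@n_long, net@n_short),
        con)
    write.table(edgeTable(net), con, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read a weighted network TSV written by [writeWeightedNetwork()]
#' @param path TSV file.
#' @return a [WeightedNetwork-class].
#' @export
readWeightedNetwork <- function(path) {
    first <- readLines(path, n = 1L)
    n_long <- n_short <- NA_integer_
    if (startsWith(first, "#")) {
        n_long <- as.integer(sub(".*n_long=(\\d+).*", "\\1", first))
        n_short <- as.integer(sub(".*n_short=(\\d+).*", "\\1", first))
    }
    if (is.na(n_long) || is.na(n_short))
        stop("weighted network file lacks the stratum-size header line")
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    new("WeightedNetwork",
        nodes = sort(unique(c(df$gene_x, df$gene_y))),
        edges = df, n_long = n_long, n_short = n_short)
}

#' Export a weighted network as GraphML
#' @param net a [WeightedNetwork-class].
#' @param path output .graphml file.
#' @export
writeGraphML <- function(net, path) {
    e <- edgeTable(net)
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
        vertices = data.frame(name = nodeSet(net)))
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Uses `fgsea::gmtPathways()` when available, otherwise a plain parser.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    if (requireNamespace("fgsea", quietly = TRUE))
        return(fgsea::gmtPathways(path))
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[[`, "", 1L)
    sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
writeGMT <- function(sets, path, description = "na") {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Write module membership and induced edges
#' @param modules list of [GeneModule-class].
#' @param membership_path TSV `module_id`, `gene`.
#' @param edges_path TSV `module_id`, `gene_x`, `gene_y`, `D`.
#' @export
writeModules <- function(modules, membership_path, edges_path) {
    mem <- do.call(rbind, lapply(modules, function(m) data.frame(
        module_id = moduleId(m), gene = moduleGenes(m),
        stringsAsFactors = FALSE)))
    edg <- do.call(rbind, lapply(modules, function(m) {
        e <- moduleEdges(m)
        if (!nrow(e)) return(NULL)
        cbind(module_id = moduleId(m), e)
    }))
    if (is.null(mem)) mem <- data.frame(module_id = integer(),
        gene = character())
    if (is.null(edg)) edg <- data.frame(module_id = integer(),
        gene_x = character(), gene_y = character(), D = numeric())
    .writeTSV(mem, membership_path)
    .writeTSV(edg, edges_path)
    invisible(c(membership_path, edges_path))
}

#' Read modules written by [writeModules()]
#' @param membership_path,edges_path the two TSV files.
#' @return list of [GeneModule-class].
#' @export
readModules <- function(membership_path, edges_path) {
    mem <- read.delim(membership_path, stringsAsFactors = FALSE)
    edg <- read.delim(edges_path, stringsAsFactors = FALSE)
    lapply(sort(unique(mem$module_id)), function(id) {
        e <- edg[edg$module_id == id,
            c("gene_x", "gene_y", "D"), drop = FALSE]
        rownames(e) <- NULL
        new("GeneModule", id = as.integer(id),
            genes = sort(mem$gene[mem$module_id == id]), edges = e)
    })
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expression.tsv`, `classes.tsv`, `survival.tsv`, `edges.tsv`,
#' `genesets.gmt`, `external_degs.tsv` (the planted DE genes, usable as the
#' external validation list) and `truth.json`.
#'
#' @param design a [SyntheticDesign-class].
#' @param outdir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
writeSyntheticData <- function(design, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    scaffold <- generateScaffold(design)
    ds <- generateDataset(design, scaffold)
    sets <- syntheticGeneSets(scaffold, seed = design@seed)
    paths <- c(
        expression = file.path(outdir, "expression.tsv"),
        classes = file.path(outdir, "classes.tsv"),
        survival = file.path(outdir, "survival.tsv"),
        edges = file.path(outdir, "edges.tsv"),
        genesets = file.path(outdir, "genesets.gmt"),
        external_degs = file.path(outdir, "external_degs.tsv"),
        truth = file.path(outdir, "truth.json"))
    writeExpression(ds$expr, paths["expression"])
    .writeTSV(data.frame(sample_id = names(ds$sample_class),
        class = unname(ds$sample_class)), paths["classes"])
    .writeTSV(ds$survival, paths["survival"])
    .writeTSV(scaffold$edges, paths["edges"])
    writeGMT(sets, paths["genesets"])
    .writeTSV(data.frame(gene = sort(ds$truth$de_genes)),
        paths["external_degs"])
    truth <- ds$truth
    truth$module_assignment <- as.list(truth$module_assignment)
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
        digits = NA, null = "null", na = "null")
    invisible(paths)
}

#' Read an external DEG list (one gene per row, column `gene`)
#' @param path TSV file.
#' @return character vector.
#' @export
readDEGList <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"gene" %in% names(df)) stop("DEG list needs a 'gene' column")
    unique(as.character(df$gene))
}
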