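## End-to-end orchestration: ingest -> align -> filter -> transform ->
## merge -> width selection -> covariance analysis -> lists -> validation,
## driven by a single configuration, with reproducible outputs.

#' Build a run configuration
#'
#' Either `width` must be given, or the width-selection parameters are used
#' to calibrate it by permutation. Inputs may be file paths (tab-separated,
#' see [readCytology()] / [readExpression()]) or in-memory objects.
#'
#' @param cytology path to a cytology TSV, or a [CytologyTable-class].
#' @param expression path to an expression TSV, or an
#'   [ExpressionMatrix-class] on the TPM scale.
#' @param outDir output directory (created if needed).
#' @param excludeSamples sample ids dropped before alignment.
#' @param tpmMin detection threshold (default 3).
#' @param mergeMap substage merge map, or NULL to skip merging (e.g. when
#'   the table is already at analysis groups); see [defaultMergeMap()].
#' @param width fixed window width, or NULL to select by permutation.
#' @param candidateWidths,alpha,jStar,nPermutations width-selection
#'   parameters (see [selectWidth()]).
#' @param depth matching depth; NULL for all usable components.
#' @param seed top-level integer seed; all randomness derives from it.
#' @return a `list` of class `pmcaRunConfig`.
#' @export
runConfig <- function(cytology, expression, outDir,
                      excludeSamples = character(0), tpmMin = 3,
                      mergeMap = NULL, width = NULL,
                      candidateWidths = defaultWidthGrid(), alpha = 0.05,
                      jStar = 3L, nPermutations = 100L, depth = NULL,
                      seed = 1L) {
    cfg <- list(cytology = cytology, expression = expression,
                outDir = outDir, excludeSamples = excludeSamples,
                tpmMin = tpmMin, mergeMap = mergeMap, width = width,
                candidateWidths = candidateWidths, alpha = alpha,
                jStar = as.integer(jStar),
                nPermutations = as.integer(nPermutations), depth = depth,
                seed = as.integer(seed))
    class(cfg) <- "pmcaRunConfig"
    cfg
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [runConfig()]; `merge_map` may be given as
#' a mapping or the string `"default"`.
#'
#' @param path YAML file path.
#' @return a `pmcaRunConfig` list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    toChar <- function(v) if (is.null(v)) character(0) else as.character(v)
    mm <- y$merge_map
    if (identical(mm, "default")) mm <- defaultMergeMap()
    else if (!is.null(mm)) mm <- unlist(mm)
    runConfig(cytology = y$cytology, expression = y$expression,
              outDir = y$out_dir,
              excludeSamples = toChar(y$exclude_samples),
              tpmMin = y$tpm_min %||% 3,
              mergeMap = mm, width = y$width,
              candidateWidths = if (is.null(y$candidate_widths))
                  defaultWidthGrid() else as.numeric(y$candidate_widths),
              alpha = y$alpha %||% 0.05, jStar = y$j_star %||% 3L,
              nPermutations = y$n_permutations %||% 100L,
              depth = y$depth, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis
#'
#' Executes ingest, sample alignment, the TPM detection filter, the
#' log2(TPM + 1) transform, optional substage merging, window-width
#' selection (when no fixed width is configured), the covariance analysis
#' with window matching, combination lists, and the PCA concordance check.
#' All declared outputs are written under `outDir` as tab-separated text
#' (floating point at 10 significant digits) plus JSON summaries, and a
#' manifest records paths, shapes, package version, seed and a config
#' digest. Matrix shapes are logged at every stage via `message()`.
#'
#' @param config a `pmcaRunConfig` from [runConfig()] /
#'   [readRunConfig()], or a path to a YAML config file.
#' @param quiet suppress stage logging.
#' @return (invisibly) a list: the manifest (`paths`, `shapes`, `version`,
#'   `seed`, `configDigest`) plus the in-memory `fit`, `assignment`,
#'   `widthReport` and `concordance` objects.
#' @export
runPmca <- function(config, quiet = FALSE) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "pmcaRunConfig"))
    note <- function(...) if (!quiet) message("[pmca] ", ...)
    stage <- function(label, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", label,
                         conditionMessage(e)), call. = FALSE))
    }
    cyto <- stage("ingest-cytology",
        if (is(config$cytology, "CytologyTable")) config$cytology
        else readCytology(config$cytology))
    expr <- stage("ingest-expression",
        if (is(config$expression, "ExpressionMatrix")) config$expression
        else readExpression(config$expression))
    note(nrow(frequencies(cyto)), " x ", ncol(frequencies(cyto)),
         " cytology; ", nrow(expr), " x ", ncol(expr), " expression")

    al <- stage("align", alignSamples(expr, cyto,
                                      exclude = config$excludeSamples))
    expr <- al$expression; cyto <- al$cytology
    note(ncol(expr), " aligned samples")

    expr <- stage("filter", filterExpressed(expr, tpmMin = config$tpmMin))
    note(nrow(expr), " genes with TPM >= ", config$tpmMin,
         " in at least one sample")
    expr <- stage("log-transform", logTransform(expr))

    if (!is.null(config$mergeMap)) {
        cyto <- stage("merge", mergeSubstages(cyto, config$mergeMap))
        note(nrow(frequencies(cyto)), " substage groups after merging")
    }

    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    out <- function(name) file.path(config$outDir, name)

    widthReport <- NULL
    width <- config$width
    if (is.null(width)) {
        widthReport <- stage("width-selection", selectWidth(
            cyto, expr, candidateWidths = config$candidateWidths,
            alpha = config$alpha, jStar = config$jStar,
            nPermutations = config$nPermutations,
            seed = config$seed))
        width <- chosenWidth(widthReport)
        note("selected width ", signif(width, 6), " (FPR at j = ",
             config$jStar, ": ",
             signif(fprGrid(widthReport)[
                 match(width, widthReport@candidateWidths),
                 config$jStar], 4), ")")
        grid <- data.frame(width = widthReport@candidateWidths,
                           fprGrid(widthReport), check.names = FALSE)
        write.table(format(grid, digits = 10, trim = TRUE),
                    out("width_selection_grid.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(chosen_width = width, alpha = config$alpha,
                 j_star = config$jStar, seed = config$seed,
                 n_permutations = config$nPermutations),
            out("width_selection.json"), auto_unbox = TRUE, digits = NA)
        paths$width_selection_grid <- out("width_selection_grid.tsv")
        paths$width_selection <- out("width_selection.json")
    }

    fit <- stage("pmca", pmcaFit(cyto, expr, width = width,
                                 depth = config$depth))
    assignment <- fit$assignment
    note(sum(rowSums(assignment@concordant) > 0), " genes concordant, ",
         sum(rowSums(assignment@negative) > 0),
         " negatively concordant with >= 1 substage")

    writeCytology(cyto, out("cytology_merged.tsv"))
    writeExpression(expr, out("expression_filtered_log.tsv"))
    writeMatrix <- function(m, name, label) {
        df <- data.frame(label = rownames(m),
                         format(m, digits = 10, trim = TRUE),
                         check.names = FALSE)
        names(df)[1L] <- label
        write.table(df, out(name), sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    writeMatrix(cytoPatterns(fit$patterns), "patterns_zx.tsv", "substage")
    writeMatrix(genePatterns(fit$patterns), "patterns_zy.tsv", "gene_id")
    write.table(assignmentTable(assignment), out("assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    comb <- combinationLists(assignment)
    combDf <- data.frame(
        substage_set = rep(names(comb), lengths(comb)),
        gene_id = unlist(comb, use.names = FALSE))
    write.table(combDf, out("combination_lists.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    conc <- stage("pca-concordance", pcaConcordance(cyto, expr))
    jsonlite::write_json(
        list(pc1_correlation = conc$pc1Correlation,
             pc1_orientation = conc$pc1Orientation),
        out("pca_concordance.json"), auto_unbox = TRUE, digits = NA)

    paths <- c(paths, list(
        cytology = out("cytology_merged.tsv"),
        expression = out("expression_filtered_log.tsv"),
        patterns_zx = out("patterns_zx.tsv"),
        patterns_zy = out("patterns_zy.tsv"),
        assignments = out("assignments.tsv"),
        combination_lists = out("combination_lists.tsv"),
        pca_concordance = out("pca_concordance.json")))

    cfgTxt <- tempfile(fileext = ".yaml")
    serializable <- config
    serializable$cytology <- if (is.character(config$cytology))
        config$cytology else "<in-memory>"
    serializable$expression <- if (is.character(config$expression))
        config$expression else "<in-memory>"
    yaml::write_yaml(serializable[order(names(serializable))], cfgTxt)
    digest <- unname(tools::md5sum(cfgTxt))
    unlink(cfgTxt)

    manifest <- list(paths = paths,
                     shapes = list(
                         cytology = dim(frequencies(cyto)),
                         expression = dim(exprValues(expr))),
                     width = width,
                     version = as.character(packageVersion("pmca")),
                     seed = config$seed,
                     configDigest = digest)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$paths$manifest <- out("manifest.json")
    invisible(c(manifest,
                list(fit = fit, assignment = assignment,
                     widthReport = widthReport, concordance = conc)))
}
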