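#' Assemble and validate a pipeline configuration
#'
#' @param globalEdgelist path to the global network edge list.
#' @param expressionSources list of lists, each with \code{path} and
#'   \code{threshold} (and optionally \code{source}); a missing threshold in
#'   any source is a configuration error, caught before any solve.
#' @param ell collective-influence distance parameter (default 1).
#' @param backend solver backend, \code{"bb"} or \code{"highs"}.
#' @param hkMin,tsMax classification breadth thresholds (defaults 14 / 3).
#' @param tsStrict strict TS-MDS reading (default TRUE).
#' @param universe enrichment universe, \code{"union"} (default) or
#'   \code{"global"}.
#' @param geneSets optional path to a GMT file for enrichment.
#' @param outputDir directory for result files.
#' @param seed integer seed recorded in the manifest.
#' @return a validated config list of class \code{cimdsConfig}.
#' @export
pipelineConfig <- function(globalEdgelist, expressionSources, ell = 1L,
                           backend = "bb", hkMin = 14L, tsMax = 3L,
                           tsStrict = TRUE, universe = c("union", "global"),
                           geneSets = NULL, outputDir = "cimds_output",
                           seed = 1L) {
    universe <- match.arg(universe)
    .checkBackend(backend)
    if (length(expressionSources) == 0L)
        stop("configuration error: no expression sources", call. = FALSE)
    for (i in seq_along(expressionSources)) {
        src <- expressionSources[[i]]
        if (is.null(src$path))
            stop("configuration error: expression source ", i,
                 " has no path", call. = FALSE)
        if (is.null(src$threshold) || !is.finite(src$threshold))
            stop("configuration error: expression source ", i,
                 " has no threshold (per-source thresholds are mandatory)",
                 call. = FALSE)
    }
    if (hkMin <= tsMax)
        stop("configuration error: need hkMin > tsMax", call. = FALSE)
    structure(list(globalEdgelist = globalEdgelist,
                   expressionSources = expressionSources,
                   ell = as.integer(ell), backend = backend,
                   hkMin = as.integer(hkMin), tsMax = as.integer(tsMax),
                   tsStrict = tsStrict, universe = universe,
                   geneSets = geneSets, outputDir = outputDir,
                   seed = as.integer(seed)),
              class = "cimdsConfig")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file mirroring the arguments of [pipelineConfig()].
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    args <- raw
    args$expressionSources <- raw$expressionSources
    do.call(pipelineConfig, args)
}

#' Run the full driver-protein pipeline
#'
#' Executes the complete analysis: read the global network, call expression
#' from the configured sources, build per-tissue networks (node removal +
#' largest component), solve the CI-corrected minimum dominating set for
#' every tissue, classify proteins by expression and MDS breadth, compute
#' breadth histograms, and (when gene sets are configured) enrichment
#' tables. Every output is written to \code{outputDir} and a manifest
#' records configuration, per-stage counts and session info. Each stage
#' fails loudly with a stage-named error; nothing is silently skipped.
#'
#' @param config a config from [pipelineConfig()] / [readPipelineConfig()].
#' @param quiet suppress stage-progress messages.
#' @return invisibly, a list with the in-memory results (networks, mdsSets,
#'   classes, histograms, enrichment, manifest).
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "cimdsConfig"))
    say <- function(...) if (!quiet) message(...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
    }
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

    global <- stage("read-network", readEdgeList(config$globalEdgelist))
    say("global network: ", igraph::gorder(global), " nodes, ",
        igraph::gsize(global), " edges")

    sources <- stage("read-expression", lapply(config$expressionSources,
        function(src) readExpressionTable(src$path, src$threshold,
                                          src$source)))
    calls <- stage("call-expression", callExpression(sources))

    tns <- stage("build-networks",
                 suppressWarnings(buildTissueNetworks(global, calls)))
    for (t in tissueNames(tns)) {
        g <- tissueNetwork(tns, t)
        say("tissue ", t, ": ", igraph::gorder(g), " nodes (",
            igraph::gorder(global) - igraph::gorder(g), " removed), ",
            igraph::gsize(g), " edges")
        writeEdgeList(g, file.path(config$outputDir,
                                   paste0("network_", t, ".tsv")))
    }

    mdsResults <- stage("solve-ci-mds", lapply(tissueNames(tns), function(t)
        solveCIMDS(tissueNetwork(tns, t), ell = config$ell,
                   backend = config$backend)))
    names(mdsResults) <- tissueNames(tns)
    mdsSets <- lapply(mdsResults, dsMembers)
    gamma <- vapply(mdsResults, dsSize, integer(1L))
    for (t in tissueNames(tns)) {
        say("tissue ", t, ": gamma = ", gamma[[t]], ", total CI = ",
            dsTotalCI(mdsResults[[t]]))
        writeLines(sort(mdsSets[[t]]),
                   file.path(config$outputDir, paste0("mds_", t, ".txt")))
    }
    summary <- tissueSummary(tns, global)
    summary$gamma <- gamma
    summary$totalCI <- vapply(mdsResults, dsTotalCI, numeric(1L))
    utils::write.table(summary,
        file.path(config$outputDir, "tissue_summary.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    classes <- stage("classify", {
        b <- countBreadths(tns, mdsSets)
        classifyProteins(b, hkMin = config$hkMin, tsMax = config$tsMax,
                         tsStrict = config$tsStrict)
    })
    utils::write.table(classes,
        file.path(config$outputDir, "protein_classes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    hists <- stage("histograms", list(
        expressed = breadthHistogram(classes, "expressed",
                                     nTissues = length(tissueNames(tns))),
        mds = breadthHistogram(classes, "mds",
                               nTissues = length(tissueNames(tns)))))

    enrichment <- NULL
    if (!is.null(config$geneSets)) {
        enrichment <- stage("enrich", {
            gs <- readGMT(config$geneSets)
            uni <- if (config$universe == "union") classes$protein
                   else igraph::V(global)$name
            enrichmentTable(gs, classes, universe = uni)
        })
        utils::write.table(enrichment,
            file.path(config$outputDir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    manifest <- list(
        config = unclass(config),
        nGlobalNodes = igraph::gorder(global),
        nGlobalEdges = igraph::gsize(global),
        tissues = tissueNames(tns),
        droppedTissues = droppedTissues(tns),
        gamma = as.list(gamma),
        classCounts = as.list(table(classes$label)),
        nUnionProteins = nrow(classes),
        bandFractions = list(expressedLow = hists$expressed$lowBand,
                             expressedHigh = hists$expressed$highBand,
                             mdsLow = hists$mds$lowBand,
                             mdsHigh = hists$mds$highBand),
        rVersion = as.character(getRversion()),
        packageVersion = as.character(utils::packageVersion("ciMDS")))
    jsonlite::write_json(manifest,
        file.path(config$outputDir, "manifest.json"),
        auto_unbox = TRUE, digits = NA)

    invisible(list(global = global, calls = calls, networks = tns,
                   mdsResults = mdsResults, mdsSets = mdsSets,
                   classes = classes, histograms = hists,
                   enrichment = enrichment, manifest = manifest))
}
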