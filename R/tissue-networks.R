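#' Read a gene-by-tissue expression table
#'
#' Tab-separated file with genes in the first column and one numeric column
#' per tissue (header row names the tissues).
#'
#' @param path file path.
#' @param threshold source-specific expression cutoff (mandatory; platforms
#'   need their own stringent threshold and no default is meaningful).
#' @param source name of the resource; defaults to the file base name.
#' @return an [ExpressionSource-class].
#' @export
readExpressionTable <- function(path, threshold, source = NULL) {
    if (is.null(source))
        source <- sub("\\.[^.]*$", "", basename(path))
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expression table needs a gene column plus >= 1 tissue column",
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    ExpressionSource(m, threshold = threshold, source = source)
}

#' Consolidate expression sources into boolean expression calls
#'
#' A gene is called expressed in a tissue when its value exceeds the
#' source-specific threshold in at least one source (logical OR across
#' sources). A gene absent from a source contributes "not expressed" for that
#' source; expression compendia routinely cover different gene universes
#' (microarray vs immunohistochemistry vs RNA-seq) and absence is never an
#' error.
#'
#' @param sources a list of [ExpressionSource-class] objects (at least one).
#' @param strict if \code{TRUE} (default) a value must strictly exceed the
#'   threshold; \code{FALSE} uses \code{>=}.
#' @return logical matrix, rows = union of genes, columns = union of tissues.
#' @examples
#' m1 <- matrix(c(1, 9), 1, 2, dimnames = list("g1", c("t1", "t2")))
#' m2 <- matrix(c(9, 1), 1, 2, dimnames = list("g1", c("t1", "t2")))
#' callExpression(list(ExpressionSource(m1, 3), ExpressionSource(m2, 3)))
#' @export
callExpression <- function(sources, strict = TRUE) {
    if (inherits(sources, "ExpressionSource")) sources <- list(sources)
    if (length(sources) == 0L)
        stop("at least one expression source is required", call. = FALSE)
    ok <- vapply(sources, function(s) inherits(s, "ExpressionSource"),
                 logical(1L))
    if (!all(ok))
        stop("all sources must be ExpressionSource objects", call. = FALSE)
    genes <- sort(unique(unlist(lapply(sources, function(s)
        rownames(s@values)))))
    tissues <- unique(unlist(lapply(sources, function(s)
        colnames(s@values))))
    calls <- matrix(FALSE, length(genes), length(tissues),
                    dimnames = list(genes, tissues))
    for (s in sources) {
        hit <- if (strict) s@values > s@threshold else s@values >= s@threshold
        hit[is.na(hit)] <- FALSE
        calls[rownames(hit), colnames(hit)] <-
            calls[rownames(hit), colnames(hit)] | hit
    }
    calls
}

#' Build one tissue-specific network by node removal
#'
#' Restricts the global network to the genes called expressed in the tissue
#' (so every retained interaction joins two proteins expressed there
#' simultaneously), then keeps only the largest connected component. The LCC
#' restriction removes isolated fragments whose trivial domination would
#' distort the identified driver set; it is applied per tissue, after
#' filtering — the global network is never pre-trimmed.
#'
#' @param global the global interactome, a simple undirected named
#'   \code{igraph}.
#' @param calls logical gene-by-tissue matrix from [callExpression()].
#' @param tissue a tissue name present in \code{calls}.
#' @return the tissue network as an \code{igraph}.
#' @export
buildTissueNetwork <- function(global, calls, tissue) {
    if (!tissue %in% colnames(calls))
        stop("unknown tissue: ", tissue, call. = FALSE)
    expressed <- rownames(calls)[calls[, tissue]]
    keep <- intersect(igraph::V(global)$name, expressed)
    if (length(keep) == 0L)
        stop("no expressed gene of tissue '", tissue,
             "' is present in the global network", call. = FALSE)
    induced <- igraph::induced_subgraph(global, keep,
                                        impl = "create_from_scratch")
    largestComponent(induced)
}

#' Build the full set of tissue-specific networks
#'
#' Applies [buildTissueNetwork()] to every tissue in the calls matrix.
#' Tissues whose induced subgraph is empty are skipped with a warning and
#' recorded in the result's \code{dropped} slot.
#'
#' @inheritParams buildTissueNetwork
#' @return a [TissueNetworkSet-class].
#' @export
buildTissueNetworks <- function(global, calls) {
    tissues <- colnames(calls)
    if (length(tissues) == 0L)
        stop("calls matrix has no tissues", call. = FALSE)
    networks <- list()
    dropped <- character(0)
    for (t in tissues) {
        g <- tryCatch(buildTissueNetwork(global, calls, t),
                      error = function(e) NULL)
        if (is.null(g)) {
            warning("tissue '", t, "' skipped: empty induced network",
                    call. = FALSE)
            dropped <- c(dropped, t)
        } else {
            networks[[t]] <- g
        }
    }
    new("TissueNetworkSet", tissues = names(networks),
        networks = networks, dropped = dropped)
}

#' Per-tissue size summary of a TissueNetworkSet
#'
#' @param tns a [TissueNetworkSet-class].
#' @param global optional global network; when given, percentage coverage of
#'   its nodes and edges is included.
#' @return data.frame with columns tissue, nNodes, nEdges (and pctNodes,
#'   pctEdges when \code{global} is supplied).
#' @export
tissueSummary <- function(tns, global = NULL) {
    df <- data.frame(
        tissue = tissueNames(tns),
        nNodes = as.integer(vapply(tns@networks, igraph::gorder, numeric(1L))),
        nEdges = as.integer(vapply(tns@networks, igraph::gsize, numeric(1L))),
        row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(global)) {
        df$pctNodes <- 100 * df$nNodes / igraph::gorder(global)
        df$pctEdges <- 100 * df$nEdges / igraph::gsize(global)
    }
    df
}

#' Union of all tissue networks
#'
#' Nodes and interactions active in at least one tissue. This union, not the
#' global network, is the natural universe for downstream classification and
#' enrichment.
#'
#' @param tns a [TissueNetworkSet-class].
#' @return an \code{igraph} over the union node and edge sets.
#' @export
unionNetwork <- function(tns) {
    if (length(tns@networks) == 0L)
        stop("empty TissueNetworkSet", call. = FALSE)
    els <- lapply(tns@networks, function(g) {
        el <- igraph::as_edgelist(g, names = TRUE)
        iso <- names(which(igraph::degree(g) == 0L))
        list(el = el, iso = iso)
    })
    from <- unlist(lapply(els, function(x) x$el[, 1L]))
    to <- unlist(lapply(els, function(x) x$el[, 2L]))
    iso <- unlist(lapply(els, function(x) x$iso))
    makeNetwork(from, to, iso)
}
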