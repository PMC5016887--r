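#' Read an undirected protein network from an edge-list file
#'
#' Parses a whitespace- or delimiter-separated edge list into a simple
#' undirected \code{igraph}. Node labels are opaque, case-sensitive strings.
#' Lines starting with \code{#} are ignored. A one-column line declares a
#' singleton (isolated) node. Three-column SIF-style lines
#' (\code{nodeA interaction nodeB}) are accepted when \code{sif = TRUE}, with
#' the middle column ignored.
#'
#' Self-loops and duplicate edges (including reversed duplicates) are
#' canonicalized away on ingest, with a message reporting how many were
#' dropped; the dominating-set constraints assume a simple graph.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; the default splits on any run of
#'   whitespace (tabs or spaces).
#' @param sif accept 3-column SIF lines, ignoring the middle column.
#' @return a simple undirected named \code{igraph}.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc"), f)
#' g <- readEdgeList(f)
#' igraph::gorder(g)  # 3
#' @export
readEdgeList <- function(path, delimiter = "[ \t]+", sif = FALSE) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0L)
        stop("empty network: no edge or node lines in ", path, call. = FALSE)
    from <- character(0); to <- character(0); singletons <- character(0)
    for (i in idx) {
        fields <- strsplit(trimws(lines[i]), delimiter)[[1L]]
        fields <- fields[nzchar(fields)]
        if (length(fields) == 1L) {
            singletons <- c(singletons, fields)
        } else if (length(fields) == 2L) {
            from <- c(from, fields[1L]); to <- c(to, fields[2L])
        } else if (length(fields) == 3L && sif) {
            from <- c(from, fields[1L]); to <- c(to, fields[3L])
        } else if (length(fields) >= 3L && !sif) {
            stop(sprintf(
                "malformed line %d in %s: %d fields (use sif = TRUE for 3-column SIF)",
                i, path, length(fields)), call. = FALSE)
        } else {
            stop(sprintf("malformed line %d in %s", i, path), call. = FALSE)
        }
    }
    makeNetwork(from, to, singletons)
}

#' Build a canonical simple undirected network from endpoint vectors
#'
#' @param from,to equal-length character vectors of edge endpoints.
#' @param singletons labels of nodes with no edges.
#' @param quiet suppress the canonicalization message.
#' @return a simple undirected named \code{igraph}.
#' @export
makeNetwork <- function(from, to, singletons = character(0), quiet = TRUE) {
    stopifnot(length(from) == length(to))
    nodes <- unique(c(from, to, singletons))
    if (any(!nzchar(nodes)))
        stop("empty node label", call. = FALSE)
    g <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to, stringsAsFactors = FALSE),
        directed = FALSE, vertices = data.frame(name = nodes))
    before <- igraph::gsize(g)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    dropped <- before - igraph::gsize(g)
    if (dropped > 0L && !quiet)
        message(dropped, " self-loop/duplicate edge(s) canonicalized away")
    g
}

#' Write a network as a canonical edge list
#'
#' One edge per line with endpoints in lexicographic order and lines sorted;
#' isolated nodes are emitted as one-column lines. The output round-trips
#' exactly through [readEdgeList()].
#'
#' @param network a simple undirected named \code{igraph}.
#' @param path output file path.
#' @param delimiter output field separator (default tab).
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(network, path, delimiter = "\t") {
    el <- igraph::as_edgelist(network, names = TRUE)
    lines <- character(0)
    if (nrow(el) > 0L) {
        swap <- el[, 1L] > el[, 2L]
        tmp <- el[swap, 1L]; el[swap, 1L] <- el[swap, 2L]; el[swap, 2L] <- tmp
        lines <- sort(paste(el[, 1L], el[, 2L], sep = delimiter))
    }
    iso <- sort(names(which(igraph::degree(network) == 0L)))
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' Largest connected component of a network
#'
#' Returns the induced subgraph on the largest connected component. Ties on
#' component size are broken deterministically in favour of the component
#' containing the lexicographically smallest node label.
#'
#' @param network a simple undirected named \code{igraph}.
#' @return the component as an \code{igraph}.
#' @examples
#' g <- makeNetwork(c("a", "d"), c("b", "e"))
#' igraph::V(largestComponent(g))$name  # "a" "b" (tie broken by label)
#' @export
largestComponent <- function(network) {
    if (igraph::gorder(network) == 0L)
        stop("empty network has no components", call. = FALSE)
    comp <- igraph::components(network)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1L) {
        # smallest member label decides among equally sized components
        firstLabel <- vapply(best, function(k)
            min(igraph::V(network)$name[comp$membership == k]), character(1L))
        best <- best[order(firstLabel)][1L]
    }
    igraph::induced_subgraph(network,
        which(comp$membership == best), impl = "create_from_scratch")
}
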