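#' Degree centrality
#'
#' Number of interaction partners of each protein; isolated nodes score 0.
#'
#' @param network a simple undirected named \code{igraph}.
#' @return named integer vector over all nodes.
#' @export
degreeCentrality <- function(network) {
    d <- igraph::degree(network, loops = FALSE)
    storage.mode(d) <- "integer"
    d
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness: for each node, the number of
#' shortest paths between all other node pairs that pass through it, with a
#' pair's unit contribution split equally among its equal-length shortest
#' paths and each unordered pair counted once. Path endpoints do not count as
#' passed-through. The raw (unnormalized) convention is used throughout;
#' downstream comparisons are rank/distribution based, so only consistency
#' matters.
#'
#' @param network a simple undirected named \code{igraph}.
#' @return named numeric vector over all nodes.
#' @export
betweennessCentrality <- function(network) {
    igraph::betweenness(network, directed = FALSE, normalized = FALSE)
}

#' Nodes at an exact shortest-path distance (frontier of a ball)
#'
#' The set of nodes exactly \code{ell} hops from \code{v}: \code{ell = 0}
#' gives \code{v} itself, \code{ell = 1} its neighbours, and distances beyond
#' the component give the empty set.
#'
#' @param network a simple undirected named \code{igraph}.
#' @param v a node label present in the network.
#' @param ell non-negative integer distance.
#' @return character vector of node labels (possibly empty).
#' @examples
#' g <- makeNetwork(c("a", "b", "c"), c("b", "c", "d"))
#' boundaryBall(g, "a", 2)  # "c"
#' @export
boundaryBall <- function(network, v, ell) {
    if (!is.numeric(ell) || length(ell) != 1L || ell < 0 || ell != floor(ell))
        stop("ell must be a single non-negative integer", call. = FALSE)
    if (!v %in% igraph::V(network)$name)
        stop("unknown node: ", v, call. = FALSE)
    if (ell == 0) return(v)
    ring <- igraph::ego(network, order = ell, nodes = v, mindist = ell)[[1L]]
    ring$name
}
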