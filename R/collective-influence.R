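#' Collective influence of every node
#'
#' Collective influence at distance \code{ell} is the product of a node's
#' reduced degree (degree minus one) and the sum of the reduced degrees of all
#' nodes exactly \code{ell} hops away:
#' \deqn{CI_\ell(v) = (d_v - 1) \sum_{u \in \partial Ball(v,\ell)} (d_u - 1).}
#' At \code{ell = 0} this is the square of the reduced degree; for \code{ell}
#' beyond a node's eccentricity the frontier is empty and the score is 0.
#' Isolated nodes are assigned 0 (their reduced degree of -1 has no meaning;
#' the model operates on connected components, and 0 extends the definition
#' safely).
#'
#' All scores are integers, so downstream equality comparisons are exact.
#'
#' @param network a simple undirected named \code{igraph}.
#' @param ell single non-negative integer distance parameter. The default 1
#'   balances topological content (richer than the degree-like \code{ell = 0})
#'   against frontier depletion at large \code{ell}, where the network
#'   boundary is reached and all scores shrink towards zero.
#' @return named numeric vector of non-negative integer-valued scores, one per
#'   node.
#' @examples
#' star <- makeNetwork(rep("c", 4), paste0("l", 1:4))
#' collectiveInfluence(star, ell = 0)[["c"]]  # (4-1)^2 = 9
#' @export
collectiveInfluence <- function(network, ell = 1L) {
    if (!is.numeric(ell) || length(ell) != 1L || is.na(ell) ||
        ell < 0 || ell != floor(ell))
        stop("ell must be a single non-negative integer", call. = FALSE)
    deg <- igraph::degree(network, loops = FALSE)
    red <- deg - 1
    n <- length(deg)
    scores <- numeric(n)
    names(scores) <- igraph::V(network)$name
    if (n == 0L) return(scores)
    if (ell == 0) {
        scores <- red * red
    } else {
        rings <- igraph::ego(network, order = ell, mindist = ell)
        ringSum <- vapply(rings, function(ring)
            sum(red[as.integer(ring)]), numeric(1L))
        scores <- red * ringSum
    }
    scores[deg == 0L] <- 0
    scores
}
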