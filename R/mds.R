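#' Check the domination property of a candidate node set
#'
#' A set dominates the network when every node either belongs to the set or
#' is adjacent to a member, i.e. the cover constraint
#' \eqn{x_v + \sum_{u \in N(v)} x_u \ge 1} holds for all \eqn{v}.
#'
#' @param network a simple undirected named \code{igraph}.
#' @param candidate character vector of node labels, all present in the
#'   network.
#' @return \code{TRUE} iff \code{candidate} is a dominating set.
#' @examples
#' g <- makeNetwork(c("a", "b"), c("b", "c"))
#' verifyDominatingSet(g, "b")  # TRUE
#' @export
verifyDominatingSet <- function(network, candidate) {
    labels <- igraph::V(network)$name
    unknown <- setdiff(candidate, labels)
    if (length(unknown))
        stop("unknown node(s) in candidate: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    nbrs <- .closedNbrs(network)
    inSet <- labels %in% candidate
    all(vapply(nbrs, function(nb) any(inSet[nb]), logical(1L)))
}

.makeDS <- function(labels, idx, totalCI = 0, ell = NA_integer_, backend) {
    new("DominatingSet",
        members = labels[idx],
        size    = length(idx),
        totalCI = as.numeric(totalCI),
        ell     = as.integer(ell),
        backend = backend,
        status  = "optimal")
}

#' Solve the standard minimum dominating set program
#'
#' Finds a dominating set of provably minimum cardinality by solving the
#' binary integer program
#' \deqn{\min \sum_v x_v \quad \mathrm{s.t.}\quad
#'       x_v + \sum_{u \in N(v)} x_u \ge 1 \ \forall v,\ x_v \in \{0,1\}.}
#' Isolated nodes have a degenerate constraint \eqn{x_v \ge 1} and are forced
#' into every solution. When several minimum dominating sets exist, which one
#' is returned is backend-dependent; only the size is part of the contract
#' (use [solveCIMDS()] to resolve the ambiguity by collective influence).
#'
#' @param network a non-empty simple undirected named \code{igraph}.
#' @param backend \code{"bb"} (branch-and-bound over neighbourhood covers,
#'   pure R, default) or \code{"highs"} (HiGHS MILP via SciPy). Both are
#'   exact.
#' @return a [DominatingSet-class] with \code{status = "optimal"}.
#' @examples
#' g <- makeNetwork(c("a", "b"), c("b", "c"))
#' dsMembers(solveStandardMDS(g))  # "b"
#' @export
solveStandardMDS <- function(network, backend = "bb") {
    .checkBackend(backend)
    n <- igraph::gorder(network)
    if (n == 0L) stop("empty network", call. = FALSE)
    nbrs <- .closedNbrs(network)
    sol <- switch(backend,
        bb    = .bbMinDS(nbrs, n),
        highs = .highsMinDS(nbrs, n))
    .makeDS(igraph::V(network)$name, sol$members, backend = backend)
}

#' Domination number of a network
#'
#' The cardinality \eqn{\gamma(G)} of a minimum dominating set. The value is a
#' property of the graph, independent of which optimal set the backend
#' happens to return.
#'
#' @inheritParams solveStandardMDS
#' @return a single integer.
#' @export
dominationNumber <- function(network, backend = "bb") {
    dsSize(solveStandardMDS(network, backend = backend))
}

#' Solve the collective-influence-corrected minimum dominating set program
#'
#' Two-stage exact solve. Stage 1 computes the domination number
#' \eqn{\gamma(G)} via the standard program; stage 2 maximizes the summed
#' collective influence of the members over all dominating sets of size
#' exactly \eqn{\gamma(G)}:
#' \deqn{\max \sum_v CI_\ell(v)\, x_v \quad \mathrm{s.t.}\quad
#'       x_v + \sum_{u \in N(v)} x_u \ge 1 \ \forall v,\
#'       \sum_v x_v = \gamma(G).}
#' The cardinality is imposed as a hard equality, so the result is always a
#' true minimum dominating set; the returned \code{totalCI} is the proven
#' maximum over all such sets. When several sets tie on the maximum total
#' collective influence, which one is returned is backend-dependent; size and
#' \code{totalCI} are the invariant contract (see [enumerateAllMDS()] for a
#' deterministic canonical enumeration on small graphs).
#'
#' @inheritParams solveStandardMDS
#' @param ell non-negative integer distance parameter of the collective
#'   influence weights (default 1, see [collectiveInfluence()]).
#' @return a [DominatingSet-class] with \code{totalCI} the exact maximum.
#' @examples
#' # hub h and a secondary centre m: {h, m} beats the tied alternatives
#' g <- makeNetwork(c("h", "h", "h", "h", "m", "m", "p"),
#'                  c("l1", "l2", "l3", "m", "p", "q", "q"))
#' solveCIMDS(g, ell = 1)
#' @export
solveCIMDS <- function(network, ell = 1L, backend = "bb") {
    .checkBackend(backend)
    n <- igraph::gorder(network)
    if (n == 0L) stop("empty network", call. = FALSE)
    ci <- collectiveInfluence(network, ell = ell)
    gamma <- dominationNumber(network, backend = backend)
    nbrs <- .closedNbrs(network)
    w <- unname(ci)
    sol <- switch(backend,
        bb    = .bbMaxWeightDS(nbrs, n, w, gamma),
        highs = .highsMaxWeightDS(nbrs, n, w, gamma))
    stopifnot(length(sol$members) == gamma)
    .makeDS(igraph::V(network)$name, sol$members,
            totalCI = sol$weight, ell = ell, backend = backend)
}

#' Enumerate every minimum dominating set of a small network
#'
#' Exhaustively lists all dominating sets whose size equals the domination
#' number, in lexicographic order of their sorted member labels. Intended as
#' a ground-truth oracle for small graphs; networks above \code{cap} nodes
#' are refused.
#'
#' @inheritParams solveStandardMDS
#' @param cap maximum allowed node count (default 16).
#' @return list of character vectors, each a minimum dominating set; the
#'   first element is the canonical (lexicographically smallest) choice.
#' @examples
#' cyc <- makeNetwork(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
#' length(enumerateAllMDS(cyc))  # 6 dominating pairs on the 4-cycle
#' @export
enumerateAllMDS <- function(network, cap = 16L) {
    n <- igraph::gorder(network)
    if (n == 0L) stop("empty network", call. = FALSE)
    if (n > cap)
        stop("network has ", n, " nodes, above the enumeration cap of ", cap,
             call. = FALSE)
    labels <- igraph::V(network)$name
    nbrs <- .closedNbrs(network)
    gamma <- dominationNumber(network)
    dominates <- function(idx) {
        inSet <- logical(n); inSet[idx] <- TRUE
        all(vapply(nbrs, function(nb) any(inSet[nb]), logical(1L)))
    }
    combos <- utils::combn(n, gamma, simplify = FALSE)
    sets <- Filter(dominates, combos)
    out <- lapply(sets, function(idx) labels[idx])
    keys <- vapply(out, function(s) paste(sort(s), collapse = "\r"),
                   character(1L))
    out[order(keys)]
}

#' Overlap between two node sets
#'
#' Jaccard index \eqn{|A \cap B| / |A \cup B|}, used to compare dominating
#' sets across solver backends or across distance parameters.
#'
#' @param setA,setB character vectors; at least one must be non-empty.
#' @return a number in \[0, 1\].
#' @examples
#' mdsOverlap(c("1", "2", "3"), c("2", "3", "4"))  # 0.5
#' @export
mdsOverlap <- function(setA, setB) {
    a <- unique(setA); b <- unique(setB)
    u <- union(a, b)
    if (length(u) == 0L)
        stop("overlap of two empty sets is undefined", call. = FALSE)
    length(intersect(a, b)) / length(u)
}
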