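# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where feasible, the libraries) they check:
# everything here works from a plain adjacency matrix with base R.

# 0/1 adjacency matrix of an igraph, ordered by vertex name
adjacencyOracle <- function(g) {
    m <- as.matrix(igraph::as_adjacency_matrix(g))
    m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

# all-pairs shortest-path distances by plain BFS (Inf when unreachable)
bfsDistancesOracle <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n, dimnames = dimnames(adj))
    for (s in seq_len(n)) {
        d[s, s] <- 0
        frontier <- s
        lev <- 0
        while (length(frontier)) {
            lev <- lev + 1
            nxt <- unique(unlist(lapply(frontier, function(v)
                which(adj[v, ] == 1))))
            nxt <- nxt[!is.finite(d[s, nxt])]
            d[s, nxt] <- lev
            frontier <- nxt
        }
    }
    d
}

# naive collective influence: double loop over the BFS level sets
ciOracle <- function(adj, ell) {
    deg <- rowSums(adj)
    d <- bfsDistancesOracle(adj)
    out <- numeric(nrow(adj))
    names(out) <- rownames(adj)
    for (v in seq_len(nrow(adj))) {
        if (deg[v] == 0) next
        ring <- which(d[v, ] == ell)
        out[v] <- (deg[v] - 1) * sum(deg[ring] - 1)
    }
    out
}

# unnormalized betweenness by explicit shortest-path counting
betweennessOracle <- function(adj) {
    n <- nrow(adj)
    d <- bfsDistancesOracle(adj)
    # sigma[s, v]: number of shortest s->v paths, by dynamic programming in
    # order of distance from s
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        sigma[s, s] <- 1
        reach <- which(is.finite(d[s, ]))
        for (v in reach[order(d[s, reach])]) {
            if (v == s) next
            preds <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
            sigma[s, v] <- sum(sigma[s, preds])
        }
    }
    bc <- numeric(n)
    names(bc) <- rownames(adj)
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
        if (!is.finite(d[s, t])) next
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
                d[s, v] + d[v, t] == d[s, t])
                bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
    }
    bc
}

dominatesOracle <- function(adj, idx) {
    closed <- adj
    diag(closed) <- 1
    all(rowSums(closed[, idx, drop = FALSE]) >= 1)
}

# exhaustive minimum dominating sets: minimum size and every optimal subset
bruteForceMDS <- function(adj) {
    n <- nrow(adj)
    for (k in seq_len(n)) {
        combos <- utils::combn(n, k, simplify = FALSE)
        hits <- Filter(function(idx) dominatesOracle(adj, idx), combos)
        if (length(hits))
            return(list(gamma = k,
                        sets = lapply(hits, function(i) rownames(adj)[i])))
    }
    stop("unreachable")
}

# hypergeometric upper tail from log-factorials (independent of phyper)
hyperTailOracle <- function(k, m, n, drawn) {
    lchooseLF <- function(a, b) {
        if (b < 0 || b > a) return(-Inf)
        lfactorial(a) - lfactorial(b) - lfactorial(a - b)
    }
    hi <- min(m, drawn)
    if (k > hi) return(0)
    terms <- vapply(k:hi, function(i)
        lchooseLF(m, i) + lchooseLF(n, drawn - i) - lchooseLF(m + n, drawn),
        numeric(1))
    sum(exp(terms))
}

# empirical-CDF sweep for the two-sample KS statistic
ksStatOracle <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
    Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
    max(abs(Fa - Fb))
}

# small seeded ER graph for parameterised cases
testGraph <- function(seed, n = NULL, p = NULL) {
    set.seed(seed)
    if (is.null(n)) n <- sample(5:12, 1)
    if (is.null(p)) p <- runif(1, 0.15, 0.5)
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g
}
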