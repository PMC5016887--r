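# Exact 0/1 solvers behind solveStandardMDS()/solveCIMDS().
#
# Two interchangeable backends are wired so optimality can be cross-checked:
#   "bb"    a depth-first branch-and-bound over closed-neighbourhood covers,
#           implemented here (pure R)
#   "highs" the HiGHS branch-and-cut MILP solver, driven through SciPy's
#           optimize.milp via the python interpreter on PATH
# Both prove optimality; a solve that cannot be proven optimal raises an
# error rather than returning a heuristic set.

# closed neighbourhoods N[v] = {v} + N(v), as integer indices
.closedNbrs <- function(network) {
    adj <- igraph::as_adj_list(network, mode = "all")
    lapply(seq_along(adj), function(i)
        sort(unique(c(i, as.integer(adj[[i]])))))
}

# greedy cover: fast incumbent for the minimization branch-and-bound
.greedyCover <- function(nbrs, n) {
    covered <- logical(n)
    chosen <- integer(0)
    covDeg <- lengths(nbrs)
    while (!all(covered)) {
        gain <- vapply(seq_len(n), function(u)
            sum(!covered[nbrs[[u]]]), integer(1L))
        u <- which.max(gain)
        chosen <- c(chosen, u)
        covered[nbrs[[u]]] <- TRUE
    }
    chosen
}

# exact minimum dominating set, branch-and-bound backend
.bbMinDS <- function(nbrs, n) {
    env <- new.env(parent = emptyenv())
    env$bestSet <- .greedyCover(nbrs, n)
    env$best <- length(env$bestSet)

    rec <- function(chosen, inSet, excluded, coverCount) {
        uncov <- which(coverCount == 0L)
        if (length(uncov) == 0L) {
            if (length(chosen) < env$best) {
                env$best <- length(chosen)
                env$bestSet <- chosen
            }
            return(invisible(NULL))
        }
        # candidates per uncovered node; any node with none makes the
        # branch infeasible
        candList <- lapply(uncov, function(v) {
            nb <- nbrs[[v]]
            nb[!excluded[nb] & !inSet[nb]]
        })
        nCand <- lengths(candList)
        if (any(nCand == 0L)) return(invisible(NULL))
        # lower bound: each pick covers at most maxGain uncovered nodes
        avail <- unique(unlist(candList))
        maxGain <- max(vapply(avail, function(u)
            sum(coverCount[nbrs[[u]]] == 0L), integer(1L)))
        if (length(chosen) + ceiling(length(uncov) / maxGain) >= env$best)
            return(invisible(NULL))
        # branch on the most constrained uncovered node
        v <- uncov[which.min(nCand)]
        cands <- candList[[which.min(nCand)]]
        gain <- vapply(cands, function(u)
            sum(coverCount[nbrs[[u]]] == 0L), integer(1L))
        cands <- cands[order(-gain)]
        for (u in cands) {
            inSet2 <- inSet; inSet2[u] <- TRUE
            cc2 <- coverCount
            cc2[nbrs[[u]]] <- cc2[nbrs[[u]]] + 1L
            rec(c(chosen, u), inSet2, excluded, cc2)
            excluded[u] <- TRUE   # later branches must cover v differently
        }
        invisible(NULL)
    }
    rec(integer(0), logical(n), logical(n), integer(n))
    list(members = sort(env$bestSet), size = env$best)
}

# exact maximum-weight dominating set of fixed cardinality (stage 2)
.bbMaxWeightDS <- function(nbrs, n, w, gamma) {
    env <- new.env(parent = emptyenv())
    env$best <- -Inf
    env$bestSet <- NULL
    wSorted <- sort(w, decreasing = TRUE)

    rec <- function(chosen, inSet, excluded, coverCount) {
        k <- length(chosen)
        uncov <- which(coverCount == 0L)
        if (length(uncov) == 0L) {
            # any completion stays dominating; take the heaviest pad
            slots <- gamma - k
            pad <- integer(0)
            if (slots > 0L) {
                avail <- which(!excluded & !inSet)
                if (length(avail) < slots) return(invisible(NULL))
                pad <- avail[order(-w[avail])][seq_len(slots)]
            }
            total <- sum(w[chosen]) + sum(w[pad])
            if (total > env$best) {
                env$best <- total
                env$bestSet <- sort(c(chosen, pad))
            }
            return(invisible(NULL))
        }
        if (k >= gamma) return(invisible(NULL))
        candList <- lapply(uncov, function(v) {
            nb <- nbrs[[v]]
            nb[!excluded[nb] & !inSet[nb]]
        })
        nCand <- lengths(candList)
        if (any(nCand == 0L)) return(invisible(NULL))
        avail <- which(!excluded & !inSet)
        maxGain <- max(vapply(unique(unlist(candList)), function(u)
            sum(coverCount[nbrs[[u]]] == 0L), integer(1L)))
        if (k + ceiling(length(uncov) / maxGain) > gamma)
            return(invisible(NULL))
        # optimistic weight bound: current + heaviest remaining picks
        slots <- gamma - k
        ub <- sum(w[chosen]) +
            sum(utils::head(sort(w[avail], decreasing = TRUE), slots))
        if (ub <= env$best) return(invisible(NULL))
        v <- uncov[which.min(nCand)]
        cands <- candList[[which.min(nCand)]]
        cands <- cands[order(-w[cands])]
        for (u in cands) {
            inSet2 <- inSet; inSet2[u] <- TRUE
            cc2 <- coverCount
            cc2[nbrs[[u]]] <- cc2[nbrs[[u]]] + 1L
            rec(c(chosen, u), inSet2, excluded, cc2)
            excluded[u] <- TRUE
        }
        invisible(NULL)
    }
    rec(integer(0), logical(n), logical(n), integer(n))
    if (is.null(env$bestSet))
        stop("no dominating set of size ", gamma, " exists", call. = FALSE)
    list(members = env$bestSet, weight = env$best)
}

# ---- HiGHS (SciPy MILP) backend -------------------------------------------

.pythonBin <- function() {
    for (cand in c("python", "python3")) {
        p <- Sys.which(cand)
        if (nzchar(p)) return(p)
    }
    stop("backend 'highs' needs a python interpreter with scipy on PATH; ",
         "none found (configuration error)", call. = FALSE)
}

# solve min obj'x s.t. closed-neighbourhood cover rows >= 1,
# optionally sum(x) == card, x binary; returns 0/1 vector
.highsSolve <- function(nbrs, n, obj, card = NULL) {
    script <- system.file("python", "milp_solve.py", package = "ciMDS")
    if (!nzchar(script))
        stop("bundled MILP driver script not found (configuration error)",
             call. = FALSE)
    infile <- tempfile(fileext = ".json")
    outfile <- tempfile(fileext = ".json")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    spec <- list(n = n, obj = obj,
                 cover_rows = lapply(nbrs, function(v) v - 1L))
    if (!is.null(card)) spec$card <- card
    jsonlite::write_json(spec, infile, auto_unbox = TRUE, digits = NA)
    status <- system2(.pythonBin(), c(script, infile, outfile),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(outfile))
        stop("MILP backend process failed (exit ", status, ")", call. = FALSE)
    res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
    if (!isTRUE(res$success) || res$status != 0L)
        stop("MILP backend did not prove optimality (status ", res$status,
             ")", call. = FALSE)
    as.integer(res$x)
}

.highsMinDS <- function(nbrs, n) {
    x <- .highsSolve(nbrs, n, obj = rep(1, n))
    members <- which(x == 1L)
    list(members = members, size = length(members))
}

.highsMaxWeightDS <- function(nbrs, n, w, gamma) {
    x <- .highsSolve(nbrs, n, obj = -w, card = gamma)
    members <- which(x == 1L)
    list(members = members, weight = sum(w[members]))
}

.checkBackend <- function(backend) {
    if (!backend %in% c("bb", "highs"))
        stop("unknown solver backend '", backend,
             "' (available: 'bb', 'highs')", call. = FALSE)
    backend
}
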