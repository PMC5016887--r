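# Seeded generators that let every stage of the pipeline run and be tested
# without any external data. Each generator returns its own ground truth so
# downstream checks never have to re-derive it. All randomness is local:
# seeds are taken as arguments and the generators restore nothing globally
# beyond set.seed().

#' Seeded random network
#'
#' Erdos-Renyi (\code{model = "er"}) or preferential-attachment
#' (\code{model = "pa"}) graph with deterministic labels, canonicalized to a
#' simple undirected network. The same seed always yields the identical
#' graph. Preferential attachment gives the heavy-tailed degree profile of
#' an interactome; ER is the neutral default for solver stress tests.
#'
#' @param nNodes number of nodes (>= 2).
#' @param p ER edge probability in \[0, 1\] (model "er").
#' @param m edges attached per step (model "pa", default 2).
#' @param model \code{"er"} or \code{"pa"}.
#' @param seed integer seed.
#' @return a simple undirected named \code{igraph}.
#' @export
randomNetwork <- function(nNodes, p = 0.1, m = 2L, model = c("er", "pa"),
                          seed = 1L) {
    model <- match.arg(model)
    if (nNodes < 2L) stop("need nNodes >= 2", call. = FALSE)
    if (model == "er" && (p < 0 || p > 1))
        stop("infeasible edge density: p must be in [0, 1]", call. = FALSE)
    set.seed(seed)
    g <- if (model == "er")
        igraph::sample_gnp(nNodes, p, directed = FALSE)
    else
        igraph::as_undirected(igraph::sample_pa(nNodes, power = 1, m = m,
                                                directed = TRUE))
    igraph::V(g)$name <- sprintf("g%04d", seq_len(nNodes))
    igraph::simplify(g)
}

#' Planted network with multiple minimum dominating sets
#'
#' Deterministically constructs a small graph on which the minimum-
#' dominating-set ambiguity is real and the collective-influence correction
#' resolves it: a hub \code{h} with \code{k} leaves forces itself into every
#' minimum dominating set, a secondary centre \code{m} (adjacent to the hub
#' and to a mutually linked pair \code{p}, \code{q}) completes it, and
#' \code{\{h, m\}}, \code{\{h, p\}}, \code{\{h, q\}} are the three minimum
#' dominating sets with distinct total collective influence, uniquely
#' maximized by \code{\{h, m\}}. The seed varies the leaf count
#' (\code{k = 3 + seed mod 3}) and permutes the labels. The returned ground
#' truth (all MDS configurations and exact \eqn{CI_1} scores, computed in
#' closed form from the construction) is verified internally against the
#' enumeration oracle.
#'
#' @param seed integer seed.
#' @return list with elements \code{network} (igraph), \code{mdsList} (all
#'   minimum dominating sets, lexicographic), \code{ci} (named \eqn{CI_1}
#'   vector) and \code{best} (the unique maximum-CI configuration).
#' @export
plantedMultiMDSNetwork <- function(seed = 1L) {
    k <- 3L + (abs(as.integer(seed)) %% 3L)
    roles <- c("h", "m", "p", "q", paste0("l", seq_len(k)))
    set.seed(seed)
    labels <- sprintf("n%02d", sample(length(roles)))
    names(labels) <- roles
    from <- c(rep("h", k), "h", "m", "m", "p")
    to <- c(paste0("l", seq_len(k)), "m", "p", "q", "q")
    g <- makeNetwork(labels[from], labels[to])
    # closed-form CI_1 of the construction: deg(h)=k+1, deg(m)=3,
    # deg(p)=deg(q)=2, leaves 1
    ci <- stats::setNames(numeric(length(roles)), labels[roles])
    ci[labels["h"]] <- k * 2
    ci[labels["m"]] <- 2 * (k + 2)
    ci[labels[c("p", "q")]] <- 3
    ci <- ci[igraph::V(g)$name]
    mdsList <- lapply(c("m", "p", "q"), function(r)
        sort(c(labels["h"], labels[r]), method = "radix"))
    keys <- vapply(mdsList, paste, character(1L), collapse = "\r")
    mdsList <- mdsList[order(keys)]
    best <- sort(unname(labels[c("h", "m")]), method = "radix")
    # construction guarantees, checked against the independent oracle
    stopifnot(
        identical(lapply(enumerateAllMDS(g), sort, method = "radix"),
                  lapply(mdsList, unname)),
        all(collectiveInfluence(g, 1L) == ci),
        sum(ci[best]) > max(vapply(
            Filter(function(s) !setequal(s, best), mdsList),
            function(s) sum(ci[s]), numeric(1L))))
    list(network = g, mdsList = lapply(mdsList, unname),
         ci = ci, best = best)
}

#' Synthetic multi-source expression tables with a bimodal breadth profile
#'
#' Emulates a trio of expression compendia (microarray / antibody-based /
#' RNA-seq style) over a shared tissue panel. Each gene draws a true
#' expression breadth from a three-band mixture — housekeeping genes
#' expressed in nearly all tissues, tissue-specific genes in few, the rest
#' in between; the default band weights (0.659 housekeeping, 0.107
#' tissue-specific over 16 tissues) reproduce the bimodal profile observed
#' in human tissue panels. Expressed (gene, tissue) pairs are carried by a
#' random non-empty subset of the sources (values above that source's
#' threshold), so the OR-consolidation rule is exercised; unexpressed pairs
#' sit below threshold everywhere. Each source also drops a fraction of
#' genes entirely, emulating the differing gene universes of real
#' platforms.
#'
#' @param genes character vector of gene labels, or a named \code{igraph}
#'   whose nodes are used.
#' @param nTissues number of tissues (default 16).
#' @param mixture numeric length-2: fractions of housekeeping and
#'   tissue-specific genes; the remainder is mid-breadth.
#' @param sourceCount number of expression sources (default 3).
#' @param thresholds per-source cutoffs (recycled; default 5).
#' @param dropout per-source probability that a gene is absent (default 0.1).
#' @param carryProb probability that a given present source carries an
#'   expressed call (at least one always does; default 0.6).
#' @param seed integer seed.
#' @return list with \code{sources} (list of [ExpressionSource-class]),
#'   \code{breadth} (named integer ground-truth breadths) and \code{calls}
#'   (ground-truth logical gene-by-tissue matrix).
#' @export
syntheticExpression <- function(genes, nTissues = 16L,
                                mixture = c(hk = 0.659, ts = 0.107),
                                sourceCount = 3L,
                                thresholds = 5,
                                dropout = 0.1, carryProb = 0.6,
                                seed = 1L) {
    if (igraph::is_igraph(genes)) genes <- igraph::V(genes)$name
    stopifnot(nTissues >= 1L, sourceCount >= 1L,
              all(mixture >= 0), sum(mixture) <= 1)
    thresholds <- rep_len(thresholds, sourceCount)
    nG <- length(genes)
    set.seed(seed)
    tsBand <- 1L:min(3L, nTissues)
    hkBand <- max(1L, nTissues - 2L):nTissues
    midBand <- setdiff(seq_len(nTissues), c(tsBand, hkBand))
    if (length(midBand) == 0L) midBand <- tsBand
    band <- sample(c("hk", "ts", "mid"), nG, replace = TRUE,
                   prob = c(mixture[1L], mixture[2L],
                            max(0, 1 - sum(mixture))))
    breadth <- vapply(band, function(b) switch(b,
        hk = sample(hkBand, 1L),
        ts = sample(tsBand, 1L),
        mid = sample(midBand, 1L)), integer(1L))
    names(breadth) <- genes
    tissues <- sprintf("tissue%02d", seq_len(nTissues))
    calls <- matrix(FALSE, nG, nTissues, dimnames = list(genes, tissues))
    for (i in seq_len(nG))
        calls[i, sample(nTissues, breadth[i])] <- TRUE
    # which sources cover which genes at all
    present <- matrix(stats::runif(nG * sourceCount) > dropout,
                      nG, sourceCount)
    present[rowSums(present) == 0L, 1L] <- TRUE
    sources <- vector("list", sourceCount)
    for (s in seq_len(sourceCount)) {
        thr <- thresholds[s]
        vals <- matrix(stats::runif(nG * nTissues, 0, thr * 0.9),
                       nG, nTissues, dimnames = list(genes, tissues))
        sources[[s]] <- vals
    }
    expressedIdx <- which(calls, arr.ind = TRUE)
    for (r in seq_len(nrow(expressedIdx))) {
        i <- expressedIdx[r, 1L]; j <- expressedIdx[r, 2L]
        avail <- which(present[i, ])
        carry <- avail[stats::runif(length(avail)) < carryProb]
        if (length(carry) == 0L) carry <- sample(avail, 1L)
        for (s in carry)
            sources[[s]][i, j] <- thresholds[s] * (1.1 + stats::rexp(1L))
    }
    out <- vector("list", sourceCount)
    for (s in seq_len(sourceCount)) {
        m <- sources[[s]][present[, s], , drop = FALSE]
        out[[s]] <- ExpressionSource(m, threshold = thresholds[s],
                                     source = sprintf("source%d", s))
    }
    list(sources = out, breadth = breadth, calls = calls)
}

#' Planted per-protein attribute values with a class location shift
#'
#' Draws one attribute value per protein from a standard normal base
#' distribution, shifted upward by \code{attributeShift} for proteins whose
#' class label is in \code{shiftedLabels}. With shift 0 all classes share
#' the null distribution (calibration checks); with a shift of several
#' spreads the designated classes dominate stochastically (power checks).
#'
#' @param classes data.frame from [classifyProteins()].
#' @param attributeShift location shift, in units of the base standard
#'   deviation.
#' @param seed integer seed.
#' @param shiftedLabels labels receiving the shift (default: the three MDS
#'   classes, so MDS proteins are stochastically larger than NMDS).
#' @return named numeric vector, protein -> attribute value.
#' @export
plantedClassAttributes <- function(classes, attributeShift = 1, seed = 1L,
                                   shiftedLabels = c("HK-MDS", "TS-MDS",
                                                     "Remaining-MDS")) {
    if (nrow(classes) == 0L) stop("no classes supplied", call. = FALSE)
    set.seed(seed)
    x <- stats::rnorm(nrow(classes))
    x[classes$label %in% shiftedLabels] <-
        x[classes$label %in% shiftedLabels] + attributeShift
    stats::setNames(x, classes$protein)
}

#' Write a fixture bundle to disk
#'
#' Emits a self-contained synthetic input set for the pipeline: a global
#' edge list, one expression TSV per source, a small GMT gene-set file and
#' a ground-truth JSON (true breadths plus generator parameters).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param nNodes global network size (default 120).
#' @param nTissues tissue count (default 6).
#' @return invisibly, a named list of the written paths.
#' @export
writeFixtures <- function(dir, seed = 1L, nNodes = 120L, nTissues = 6L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- randomNetwork(nNodes, m = 2L, model = "pa", seed = seed)
    paths <- list(edgelist = file.path(dir, "global_network.tsv"))
    writeEdgeList(g, paths$edgelist)
    expr <- syntheticExpression(g, nTissues = nTissues, seed = seed + 1L)
    for (s in seq_along(expr$sources)) {
        src <- expr$sources[[s]]
        p <- file.path(dir, sprintf("expression_source%d.tsv", s))
        df <- data.frame(gene = rownames(src@values), src@values,
                         check.names = FALSE)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[[sprintf("expression%d", s)]] <- p
    }
    set.seed(seed + 2L)
    sets <- list(
        setA = sample(igraph::V(g)$name, min(25L, nNodes)),
        setB = sample(igraph::V(g)$name, min(40L, nNodes)))
    gmt <- file.path(dir, "gene_sets.gmt")
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t"),
        character(1L)), gmt)
    paths$gmt <- gmt
    truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
        list(seed = seed, nNodes = nNodes, nTissues = nTissues,
             breadth = as.list(expr$breadth),
             thresholds = vapply(expr$sources, function(s) s@threshold,
                                 numeric(1L))),
        truth, auto_unbox = TRUE, digits = NA)
    paths$truth <- truth
    invisible(paths)
}
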