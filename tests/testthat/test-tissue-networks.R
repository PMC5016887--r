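mk <- function(vals, genes, tissues, thr = 3, src = "s1")
    ExpressionSource(matrix(vals, length(genes), length(tissues),
                            dimnames = list(genes, tissues)),
                     threshold = thr, source = src)

test_that("expression calls follow the threshold-OR rule across sources", {
    one <- mk(5, "g1", "t1")
    expect_true(callExpression(list(one))["g1", "t1"])
    expect_false(callExpression(list(mk(3, "g1", "t1")))["g1", "t1"])  # strict >
    expect_true(callExpression(list(mk(3, "g1", "t1")),
                               strict = FALSE)["g1", "t1"])

    # OR: below in one source, above in the other
    two <- list(mk(1, "g1", "t1", src = "a"), mk(9, "g1", "t1", src = "b"))
    expect_true(callExpression(two)["g1", "t1"])

    # gene missing from a source contributes FALSE, never an error
    uneven <- list(mk(9, "g1", "t1", src = "a"),
                   mk(c(1, 1), c("g1", "g2"), "t1", src = "b"))
    calls <- callExpression(uneven)
    expect_true(calls["g1", "t1"])
    expect_false(calls["g2", "t1"])

    expect_error(callExpression(list()), "at least one")
    expect_error(ExpressionSource(matrix(1, 1, 1,
        dimnames = list("g", "t"))), "threshold")
})

test_that("node removal keeps co-expressed interactions then takes the LCC", {
    global <- makeNetwork(c("a", "b"), c("b", "c"))
    calls <- matrix(c(TRUE, TRUE, FALSE), 3, 1,
                    dimnames = list(c("a", "b", "c"), "t1"))
    t1 <- buildTissueNetwork(global, calls, "t1")
    expect_setequal(igraph::V(t1)$name, c("a", "b"))

    # square with one unexpressed corner leaves a connected path
    sq <- makeNetwork(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
    calls2 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 4, 1,
                     dimnames = list(c("a", "b", "c", "d"), "t1"))
    t2 <- buildTissueNetwork(sq, calls2, "t1")
    expect_setequal(igraph::V(t2)$name, c("a", "b", "d"))
    expect_equal(igraph::gsize(t2), 2)

    expect_error(buildTissueNetwork(global, calls, "nope"), "unknown tissue")
    none <- matrix(FALSE, 3, 1, dimnames = list(c("a", "b", "c"), "t1"))
    expect_error(buildTissueNetwork(global, none, "t1"), "no expressed")
})

test_that("tissue networks are subgraph-closed within the global network", {
    g <- randomNetwork(60, p = 0.08, seed = 4)
    expr <- syntheticExpression(g, nTissues = 4, seed = 5)
    calls <- callExpression(expr$sources)
    tns <- suppressWarnings(buildTissueNetworks(g, calls))
    globalEdges <- apply(igraph::as_edgelist(g), 1, function(e)
        paste(sort(e), collapse = "|"))
    for (t in tissueNames(tns)) {
        tg <- tissueNetwork(tns, t)
        nodes <- igraph::V(tg)$name
        expect_true(all(nodes %in% igraph::V(g)$name))
        expect_true(all(calls[nodes, t]))  # every node expressed there
        tEdges <- apply(igraph::as_edgelist(tg), 1, function(e)
            paste(sort(e), collapse = "|"))
        expect_true(all(tEdges %in% globalEdges))
        expect_true(igraph::is_connected(tg))
        # induced-subgraph oracle: same nodes by plain set algebra + LCC
        expressed <- intersect(rownames(calls)[calls[, t]],
                               igraph::V(g)$name)
        oracle <- largestComponent(igraph::induced_subgraph(g, expressed))
        expect_setequal(nodes, igraph::V(oracle)$name)
    }
    expect_lte(length(unique(unlist(lapply(tissueNames(tns), function(t)
        igraph::V(tissueNetwork(tns, t))$name)))), igraph::gorder(g))
})

test_that("all-expressed calls reproduce the global LCC in every tissue", {
    g <- randomNetwork(40, p = 0.1, seed = 2)
    calls <- matrix(TRUE, igraph::gorder(g), 3,
                    dimnames = list(igraph::V(g)$name, paste0("t", 1:3)))
    tns <- buildTissueNetworks(g, calls)
    lcc <- largestComponent(g)
    for (t in tissueNames(tns))
        expect_setequal(igraph::V(tissueNetwork(tns, t))$name,
                        igraph::V(lcc)$name)
    expect_length(droppedTissues(tns), 0)
})

test_that("filtering is monotone in the expressed set (pre-LCC)", {
    g <- randomNetwork(50, p = 0.1, seed = 8)
    genes <- igraph::V(g)$name
    set.seed(9)
    small <- sample(genes, 20)
    large <- union(small, sample(genes, 20))
    inducedSize <- function(keep)
        igraph::gorder(igraph::induced_subgraph(g, intersect(genes, keep)))
    expect_lte(inducedSize(small), inducedSize(large))
})

test_that("summary and union cover the tissue set", {
    g <- randomNetwork(60, p = 0.08, seed = 4)
    expr <- syntheticExpression(g, nTissues = 4, seed = 5)
    tns <- suppressWarnings(buildTissueNetworks(g, callExpression(expr$sources)))
    sm <- tissueSummary(tns, g)
    expect_identical(sm$tissue, tissueNames(tns))
    expect_true(all(sm$pctNodes <= 100))
    u <- unionNetwork(tns)
    allNodes <- unique(unlist(lapply(tissueNames(tns), function(t)
        igraph::V(tissueNetwork(tns, t))$name)))
    expect_setequal(igraph::V(u)$name, allNodes)
})
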