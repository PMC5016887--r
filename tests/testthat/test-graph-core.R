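test_that("edge-list ingest canonicalizes and validates", {
    f <- withr::local_tempfile()
    writeLines(c("# comment", "a\tb", "b\tc"), f)
    g <- readEdgeList(f)
    expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
    expect_equal(igraph::gsize(g), 2)

    # reversed duplicates merge, self-loops drop
    writeLines(c("a b", "b a", "a a"), f)
    g2 <- readEdgeList(f)
    expect_equal(igraph::gorder(g2), 2)
    expect_equal(igraph::gsize(g2), 1)

    # singleton declaration, SIF acceptance, malformed rejection
    writeLines(c("a\tb", "lonely"), f)
    expect_true("lonely" %in% igraph::V(readEdgeList(f))$name)
    writeLines("a\tpp\tb", f)
    expect_error(readEdgeList(f), "sif")
    expect_equal(igraph::gsize(readEdgeList(f, sif = TRUE)), 1)
    writeLines(character(0), f)
    expect_error(readEdgeList(f), "empty network")
})

test_that("canonical write is sorted and round-trips identically", {
    f <- withr::local_tempfile()
    tri <- makeNetwork(c("b", "a", "c"), c("a", "c", "b"))
    writeEdgeList(tri, f)
    expect_identical(readLines(f), c("a\tb", "a\tc", "b\tc"))

    empty1 <- makeNetwork(character(0), character(0), singletons = "x")
    writeEdgeList(empty1, f)
    expect_identical(readLines(f), "x")

    for (seed in 1:5) {
        g <- randomNetwork(20, p = 0.15, seed = seed)
        writeEdgeList(g, f)
        g2 <- readEdgeList(f)
        expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
        f2 <- withr::local_tempfile()
        writeEdgeList(g2, f2)
        expect_identical(readLines(f2), readLines(f))
    }
})

test_that("largest component follows BFS labelling with deterministic ties", {
    g <- makeNetwork(c("a", "b", "d"), c("b", "c", "e"))
    expect_setequal(igraph::V(largestComponent(g))$name, c("a", "b", "c"))

    tie <- makeNetwork(c("c", "a"), c("d", "b"))
    expect_setequal(igraph::V(largestComponent(tie))$name, c("a", "b"))

    expect_error(largestComponent(makeNetwork(character(0), character(0))),
                 "empty")

    # planted components agree with an exhaustive BFS reachability check
    for (seed in 1:5) {
        g <- testGraph(seed, n = 12, p = 0.15)
        adj <- adjacencyOracle(g)
        d <- bfsDistancesOracle(adj)
        comps <- unique(lapply(seq_len(nrow(adj)), function(v)
            rownames(adj)[is.finite(d[v, ])]))
        biggest <- comps[[which.max(lengths(comps))]]
        if (sum(lengths(comps) == length(biggest)) == 1)
            expect_setequal(igraph::V(largestComponent(g))$name, biggest)
    }
})

test_that("degree satisfies the handshake identity; star/empty cases exact", {
    star <- makeNetwork(rep("c", 4), paste0("l", 1:4))
    d <- degreeCentrality(star)
    expect_equal(d[["c"]], 4L)
    expect_true(all(d[paste0("l", 1:4)] == 1L))

    iso <- makeNetwork(character(0), character(0), singletons = c("a", "b"))
    expect_true(all(degreeCentrality(iso) == 0L))

    for (seed in 1:6) {
        g <- testGraph(seed)
        expect_identical(sum(degreeCentrality(g)),
                         as.integer(2 * igraph::gsize(g)))
    }
})

test_that("betweenness matches brute-force path enumeration", {
    path <- makeNetwork(c("a", "b"), c("b", "c"))
    expect_equal(betweennessCentrality(path),
                 c(a = 0, b = 1, c = 0))

    k4 <- makeNetwork(c("a", "a", "a", "b", "b", "c"),
                      c("b", "c", "d", "c", "d", "d"))
    expect_true(all(betweennessCentrality(k4) == 0))

    for (seed in 1:8) {
        g <- testGraph(seed, n = 12)
        adj <- adjacencyOracle(g)
        got <- betweennessCentrality(g)[rownames(adj)]
        expect_equal(got, betweennessOracle(adj), tolerance = 1e-10)
    }
})

test_that("boundary balls are exact BFS level sets partitioning components", {
    p4 <- makeNetwork(c("a", "b", "c"), c("b", "c", "d"))
    expect_identical(boundaryBall(p4, "a", 2), "c")
    expect_identical(boundaryBall(p4, "b", 0), "b")
    expect_length(boundaryBall(p4, "a", 9), 0)
    expect_error(boundaryBall(p4, "zz", 1), "unknown node")
    expect_error(boundaryBall(p4, "a", -1), "non-negative")

    for (seed in 1:5) {
        g <- testGraph(seed)
        adj <- adjacencyOracle(g)
        d <- bfsDistancesOracle(adj)
        for (v in rownames(adj)) {
            comp <- rownames(adj)[is.finite(d[v, ])]
            levels <- lapply(0:max(d[v, is.finite(d[v, ])]), function(l)
                sort(boundaryBall(g, v, l)))
            for (l in seq_along(levels))
                expect_setequal(levels[[l]],
                                rownames(adj)[d[v, ] == l - 1])
            expect_setequal(unlist(levels), comp)  # levels partition comp
        }
    }
})
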