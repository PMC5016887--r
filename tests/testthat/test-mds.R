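test_that("domination verification agrees with direct constraint checks", {
    p3 <- makeNetwork(c("a", "b"), c("b", "c"))
    expect_true(verifyDominatingSet(p3, "b"))
    p4 <- makeNetwork(c("a", "b", "c"), c("b", "c", "d"))
    expect_false(verifyDominatingSet(p4, "b"))
    expect_error(verifyDominatingSet(p4, c("b", "zz")), "unknown")

    g <- testGraph(11, n = 8, p = 0.3)
    adj <- adjacencyOracle(g)
    for (k in 1:3) for (idx in utils::combn(8, k, simplify = FALSE))
        expect_identical(verifyDominatingSet(g, rownames(adj)[idx]),
                         dominatesOracle(adj, idx))
})

test_that("standard solve returns proven minimum sets on canonical graphs", {
    p3 <- makeNetwork(c("a", "b"), c("b", "c"))
    expect_identical(dsMembers(solveStandardMDS(p3)), "b")

    c4 <- makeNetwork(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
    s <- solveStandardMDS(c4)
    expect_equal(dsSize(s), 2)
    expect_true(verifyDominatingSet(c4, dsMembers(s)))

    star <- makeNetwork(rep("c", 5), paste0("l", 1:5))
    expect_identical(dsMembers(solveStandardMDS(star)), "c")

    # isolated node forced by its degenerate constraint
    g <- makeNetwork(c("a", "a", "b"), c("b", "c", "c"), singletons = "v")
    s2 <- solveStandardMDS(g)
    expect_equal(dsSize(s2), 2)
    expect_true("v" %in% dsMembers(s2))

    kn <- makeNetwork(rep("a", 4), paste0("b", 1:4))
    expect_equal(dominationNumber(kn), 1)
    expect_error(solveStandardMDS(makeNetwork(character(0), character(0))),
                 "empty")
    expect_error(solveStandardMDS(p3, backend = "nope"), "unknown solver")
})

test_that("enumeration lists exactly the optimal dominating sets", {
    p3 <- makeNetwork(c("a", "b"), c("b", "c"))
    expect_identical(enumerateAllMDS(p3), list("b"))

    c4 <- makeNetwork(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
    all4 <- enumerateAllMDS(c4)
    expect_length(all4, 6)  # 4 adjacent + 2 opposite pairs all dominate
    for (s in all4) expect_true(verifyDominatingSet(c4, s))

    big <- randomNetwork(20, p = 0.2, seed = 1)
    expect_error(enumerateAllMDS(big), "cap")

    for (seed in 1:6) {
        g <- testGraph(seed, n = 9)
        bf <- bruteForceMDS(adjacencyOracle(g))
        got <- enumerateAllMDS(g)
        expect_equal(dominationNumber(g), bf$gamma)
        expect_setequal(vapply(got, function(s) paste(sort(s), collapse = ","),
                               character(1)),
                        vapply(bf$sets, function(s) paste(sort(s), collapse = ","),
                               character(1)))
    }
})

test_that("CI-corrected solve attains the enumeration maximum", {
    pm <- plantedMultiMDSNetwork(1)
    got <- solveCIMDS(pm$network, ell = 1)
    expect_setequal(dsMembers(got), pm$best)
    expect_equal(dsTotalCI(got), sum(pm$ci[pm$best]))

    # vertex-transitive 5-cycle: all optima tie on total CI
    c5 <- makeNetwork(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"))
    s <- solveCIMDS(c5, ell = 1)
    expect_equal(dsSize(s), 2)
    cis <- vapply(enumerateAllMDS(c5), function(m)
        sum(collectiveInfluence(c5, 1)[m]), numeric(1))
    expect_true(all(cis == dsTotalCI(s)))

    for (seed in 1:6) for (l in 0:2) {
        g <- testGraph(seed, n = 9)
        ci <- collectiveInfluence(g, l)
        best <- max(vapply(enumerateAllMDS(g), function(m) sum(ci[m]),
                           numeric(1)))
        got <- solveCIMDS(g, ell = l)
        expect_equal(dsTotalCI(got), best)
        expect_equal(dsSize(got), dominationNumber(g))
        expect_true(verifyDominatingSet(g, dsMembers(got)))
    }
})

test_that("the two exact backends agree on size and total CI", {
    for (seed in c(2, 9, 17)) {
        g <- testGraph(seed, n = 14, p = 0.25)
        expect_equal(dsSize(solveStandardMDS(g, "highs")),
                     dsSize(solveStandardMDS(g, "bb")))
        a <- solveCIMDS(g, 1, "bb"); b <- solveCIMDS(g, 1, "highs")
        expect_equal(dsTotalCI(a), dsTotalCI(b))
        expect_true(verifyDominatingSet(g, dsMembers(b)))
    }
})

test_that("adding an edge never increases the domination number", {
    for (seed in 1:5) {
        g <- testGraph(seed, n = 10, p = 0.2)
        gamma0 <- dominationNumber(g)
        labels <- igraph::V(g)$name
        set.seed(seed + 100)
        pair <- sample(labels, 2)
        g2 <- igraph::add_edges(g, pair)
        g2 <- igraph::simplify(g2)
        expect_lte(dominationNumber(g2), gamma0)
    }
})

test_that("set overlap is the Jaccard index with defined edge cases", {
    expect_equal(mdsOverlap(c("a", "b"), c("a", "b")), 1)
    expect_equal(mdsOverlap(c("a"), c("b")), 0)
    expect_equal(mdsOverlap(c("1", "2", "3"), c("2", "3", "4")), 0.5)
    expect_error(mdsOverlap(character(0), character(0)), "undefined")
})
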