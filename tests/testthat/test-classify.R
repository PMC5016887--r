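smallSet <- function(seed = 1) {
    g <- randomNetwork(50, p = 0.12, seed = seed)
    expr <- syntheticExpression(g, nTissues = 5, seed = seed + 1)
    tns <- suppressWarnings(buildTissueNetworks(g, callExpression(expr$sources)))
    mds <- lapply(tissueNames(tns), function(t)
        dsMembers(solveCIMDS(tissueNetwork(tns, t))))
    names(mds) <- tissueNames(tns)
    list(tns = tns, mds = mds)
}

test_that("breadth counting matches planted memberships", {
    s <- smallSet(1)
    b <- countBreadths(s$tns, s$mds)
    nodeSets <- lapply(tissueNames(s$tns), function(t)
        igraph::V(tissueNetwork(s$tns, t))$name)
    for (i in sample(nrow(b), 10)) {
        p <- b$protein[i]
        expect_equal(b$nExpressed[i],
                     sum(vapply(nodeSets, function(ns) p %in% ns, logical(1))))
        expect_equal(b$nMDS[i],
                     sum(vapply(s$mds, function(m) p %in% m, logical(1))))
    }
    expect_true(all(b$nMDS <= b$nExpressed))
    expect_true(all(b$nExpressed >= 1))

    bad <- s$mds
    bad[[1]] <- c(bad[[1]], "not-a-node")
    expect_error(countBreadths(s$tns, bad), "outside")
})

test_that("six-class assignment follows the breadth rules exactly", {
    b <- data.frame(
        protein = paste0("p", 1:8),
        nExpressed = c(16L, 2L, 2L, 10L, 16L, 2L, 8L, 14L),
        nMDS       = c(15L, 2L, 1L,  0L,  0L, 0L, 3L, 14L))
    cl <- classifyProteins(b)  # defaults hkMin = 14, tsMax = 3, strict
    expect_identical(as.character(cl$label),
        c("HK-MDS", "TS-MDS", "Remaining-MDS", "Remaining-NMDS",
          "HK-NMDS", "TS-NMDS", "Remaining-MDS", "HK-MDS"))

    # relaxed reading admits partial-breadth TS-MDS
    relaxed <- classifyProteins(b, tsStrict = FALSE)
    expect_identical(as.character(relaxed$label[3]), "TS-MDS")

    expect_error(classifyProteins(b, hkMin = 3, tsMax = 3), "hkMin > tsMax")
    b$nMDS[1] <- 17L
    expect_error(classifyProteins(b), "invalid breadths")
})

test_that("labels partition the union set and reconcile with marginals", {
    for (seed in c(1, 7)) {
        s <- smallSet(seed)
        cl <- classifyProteins(countBreadths(s$tns, s$mds),
                               hkMin = 4, tsMax = 2)
        expect_false(any(is.na(cl$label)))
        expect_equal(nrow(cl),
                     length(unique(unlist(lapply(tissueNames(s$tns),
                         function(t) igraph::V(tissueNetwork(s$tns, t))$name)))))
        counts <- table(cl$label)
        expect_equal(sum(counts), nrow(cl))
        mdsCount <- sum(counts[c("HK-MDS", "TS-MDS", "Remaining-MDS")])
        expect_equal(mdsCount, sum(cl$nMDS >= 1))
        # invariance to tissue order
        perm <- rev(tissueNames(s$tns))
        tns2 <- new("TissueNetworkSet",
                    tissues = perm, networks = s$tns@networks[perm],
                    dropped = character(0))
        cl2 <- classifyProteins(countBreadths(tns2, s$mds),
                                hkMin = 4, tsMax = 2)
        expect_identical(cl2[order(cl2$protein), ],
                         cl[order(cl$protein), ])
    }
})

test_that("breadth histogram reports per-bin and band fractions", {
    b <- data.frame(protein = c("a", "b"), nExpressed = c(2L, 15L),
                    nMDS = c(0L, 0L))
    h <- breadthHistogram(b, "expressed", nTissues = 16)
    expect_equal(sum(h$fractions), 1)
    expect_equal(h$lowBand, 0.5)
    expect_equal(h$highBand, 0.5)

    all1 <- data.frame(protein = letters[1:4], nExpressed = rep(1L, 4),
                       nMDS = rep(0L, 4))
    expect_equal(breadthHistogram(all1, "expressed")$fractions[["1"]], 1)

    expect_error(breadthHistogram(all1, "mds"), "no proteins")
})

test_that("bimodal generator recovers the target band fractions", {
    genes <- sprintf("g%04d", 1:5000)
    expr <- syntheticExpression(genes, nTissues = 16,
                                mixture = c(hk = 0.659, ts = 0.107),
                                seed = 42)
    b <- data.frame(protein = genes,
                    nExpressed = as.integer(expr$breadth[genes]),
                    nMDS = 0L)
    h <- breadthHistogram(b, "expressed", nTissues = 16)
    expect_equal(h$highBand, 0.659, tolerance = 0.03 / 0.659)
    expect_equal(h$lowBand, 0.107, tolerance = 0.03 / 0.107)
})
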