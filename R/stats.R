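#' One-sided Fisher (hypergeometric) enrichment of an annotation in a class
#'
#' Tests whether an annotation gene set is over-represented in a protein
#' class relative to a universe, via the exact one-sided (greater) test on
#' the 2x2 table. The p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)} for observed overlap \eqn{k}, identical to
#' \code{fisher.test(..., alternative = "greater")}. One-sided testing
#' matches the directional question asked of such tables (is the class
#' enriched?); near-1 p-values for depleted classes are expected output, not
#' errors. Members of either set that fall outside the universe are dropped
#' with a warning. No multiple-testing correction is applied here; apply
#' [stats::p.adjust()] across a battery of tests if desired.
#'
#' @param classSet character vector, the protein class.
#' @param annotationSet character vector, the annotation gene set.
#' @param universe character vector, the background (non-empty).
#' @return one-row data.frame: inClassInSet, inClassTotal,
#'   setTotalInUniverse, universeSize, fraction, pValue.
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' fisherEnrichment(u[1:10], u[1:10], u)$pValue  # 1 / choose(20, 10)
#' @export
fisherEnrichment <- function(classSet, annotationSet, universe) {
    universe <- unique(universe)
    if (length(universe) == 0L)
        stop("empty universe", call. = FALSE)
    cs <- unique(classSet); as <- unique(annotationSet)
    outC <- setdiff(cs, universe); outA <- setdiff(as, universe)
    if (length(outC) || length(outA))
        warning(length(outC) + length(outA),
                " set member(s) outside the universe dropped", call. = FALSE)
    cs <- intersect(cs, universe); as <- intersect(as, universe)
    if (length(cs) == 0L)
        stop("empty class after restriction to the universe", call. = FALSE)
    k <- length(intersect(cs, as))
    m <- length(as)                      # annotated in universe
    n <- length(universe) - m            # not annotated
    drawn <- length(cs)
    p <- stats::phyper(k - 1L, m, n, drawn, lower.tail = FALSE)
    data.frame(inClassInSet = k,
               inClassTotal = drawn,
               setTotalInUniverse = m,
               universeSize = length(universe),
               fraction = k / drawn,
               pValue = p)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS test on two numeric samples: statistic
#' \eqn{D = \sup_x |F_a(x) - F_b(x)|} with the asymptotic p-value (sample
#' sizes in this context are hundreds to thousands, where the asymptotic
#' distribution is accurate; exact small-sample p-values are deliberately
#' not used so that the convention is constant).
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @param groupA,groupB display names for the two samples.
#' @return one-row data.frame: groupA, groupB, nA, nB, statistic, pValue.
#' @export
ksCompare <- function(valuesA, valuesB, groupA = "A", groupB = "B") {
    if (length(valuesA) == 0L || length(valuesB) == 0L)
        stop("both samples must be non-empty", call. = FALSE)
    kt <- suppressWarnings(
        stats::ks.test(valuesA, valuesB, alternative = "two.sided",
                       exact = FALSE))
    data.frame(groupA = groupA, groupB = groupB,
               nA = length(valuesA), nB = length(valuesB),
               statistic = unname(kt$statistic),
               pValue = unname(kt$p.value),
               stringsAsFactors = FALSE)
}

#' Compare a per-protein attribute between protein classes
#'
#' Runs one KS comparison per requested pair of class labels over the
#' attribute values of each class. Besides the six class labels, the
#' aggregate labels \code{"MDS"} (selected in at least one tissue) and
#' \code{"NMDS"} (never selected) are understood. Proteins without an
#' attribute value are ignored; a requested label with no covered protein is
#' reported as skipped.
#'
#' @param attribute named numeric vector, protein -> value (e.g. degree,
#'   collective influence, betweenness, dN/dS, PTM-site or GO-term counts).
#' @param classes data.frame from [classifyProteins()].
#' @param pairs list of length-2 character vectors of labels; default
#'   compares MDS vs NMDS and HK-MDS vs TS-MDS.
#' @return data.frame with one row per pair: labelA, labelB, nA, nB,
#'   statistic, pValue, skipped.
#' @export
compareClasses <- function(attribute, classes,
                           pairs = list(c("MDS", "NMDS"),
                                        c("HK-MDS", "TS-MDS"))) {
    known <- c(.CLASS_LABELS, "MDS", "NMDS")
    groupValues <- function(lab) {
        prot <- switch(lab,
            MDS = classes$protein[classes$nMDS >= 1L],
            NMDS = classes$protein[classes$nMDS == 0L],
            classes$protein[classes$label == lab])
        attribute[intersect(prot, names(attribute))]
    }
    out <- lapply(pairs, function(pr) {
        if (length(pr) != 2L || !all(pr %in% known))
            stop("unknown label in pair: ", paste(pr, collapse = " vs "),
                 call. = FALSE)
        a <- groupValues(pr[1L]); b <- groupValues(pr[2L])
        if (length(a) == 0L || length(b) == 0L)
            return(data.frame(labelA = pr[1L], labelB = pr[2L],
                              nA = length(a), nB = length(b),
                              statistic = NA_real_, pValue = NA_real_,
                              skipped = TRUE, stringsAsFactors = FALSE))
        ks <- ksCompare(a, b, pr[1L], pr[2L])
        data.frame(labelA = pr[1L], labelB = pr[2L],
                   nA = ks$nA, nB = ks$nB,
                   statistic = ks$statistic, pValue = ks$pValue,
                   skipped = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: set name, description, then members.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("empty GMT file: ", path, call. = FALSE)
    sets <- lapply(lines, function(l) {
        fields <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop("malformed GMT line (need name, description, >= 1 member)",
                 call. = FALSE)
        unique(fields[-(1:2)])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L),
        USE.NAMES = FALSE)
    sets
}

#' Enrichment of several gene sets across protein classes
#'
#' Convenience wrapper producing a long-format table of one-sided Fisher
#' enrichment results, one row per (gene set, class) combination.
#'
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @param classes data.frame from [classifyProteins()].
#' @param universe background protein set; defaults to all classified
#'   proteins (the union-network set).
#' @param labels class labels to test; defaults to MDS, TS-MDS, HK-MDS.
#' @return data.frame: geneSet, class, count, classSize, pct, pValue.
#' @export
enrichmentTable <- function(geneSets, classes, universe = NULL,
                            labels = c("MDS", "TS-MDS", "HK-MDS")) {
    if (is.null(universe)) universe <- classes$protein
    rows <- list()
    for (gs in names(geneSets)) {
        for (lab in labels) {
            prot <- switch(lab,
                MDS = classes$protein[classes$nMDS >= 1L],
                NMDS = classes$protein[classes$nMDS == 0L],
                classes$protein[classes$label == lab])
            if (length(prot) == 0L) next
            er <- suppressWarnings(
                fisherEnrichment(prot, geneSets[[gs]], universe))
            rows[[length(rows) + 1L]] <- data.frame(
                geneSet = gs, class = lab,
                count = er$inClassInSet, classSize = er$inClassTotal,
                pct = 100 * er$fraction, pValue = er$pValue,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
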