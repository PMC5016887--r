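.CLASS_LABELS <- c("HK-MDS", "TS-MDS", "Remaining-MDS",
                   "HK-NMDS", "TS-NMDS", "Remaining-NMDS")

#' Count expression breadth and MDS breadth per protein
#'
#' For every protein in the union of the tissue networks, counts the number
#' of tissue networks containing it (\code{nExpressed}; membership in the
#' post-LCC network is what "expressed in that tissue" means here, since all
#' dominating-set calls operate on those networks) and the number of tissues
#' in whose minimum dominating set it appears (\code{nMDS}).
#'
#' @param tns a [TissueNetworkSet-class].
#' @param mdsSets named list (one element per tissue of \code{tns}) of
#'   character vectors: each tissue's MDS members, e.g.
#'   \code{dsMembers(solveCIMDS(...))} per tissue.
#' @return data.frame with columns protein, nExpressed, nMDS.
#' @export
countBreadths <- function(tns, mdsSets) {
    tissues <- tissueNames(tns)
    if (!all(tissues %in% names(mdsSets)))
        stop("mdsSets must contain every tissue of the network set",
             call. = FALSE)
    nodeSets <- lapply(tns@networks, function(g) igraph::V(g)$name)
    for (t in tissues) {
        bad <- setdiff(mdsSets[[t]], nodeSets[[t]])
        if (length(bad))
            stop("MDS member(s) outside the '", t, "' network: ",
                 paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    proteins <- sort(unique(unlist(nodeSets)))
    nExpressed <- rowSums(vapply(tissues, function(t)
        proteins %in% nodeSets[[t]], logical(length(proteins))))
    nMDS <- rowSums(vapply(tissues, function(t)
        proteins %in% mdsSets[[t]], logical(length(proteins))))
    data.frame(protein = proteins,
               nExpressed = as.integer(nExpressed),
               nMDS = as.integer(nMDS),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign the six housekeeping/tissue-specific protein classes
#'
#' A protein is an MDS protein when it sits in at least one tissue's minimum
#' dominating set, and a non-MDS (NMDS) protein otherwise. Each group is
#' split by breadth: housekeeping (HK) proteins are expressed in at least
#' \code{hkMin} tissues, tissue-specific (TS) proteins in at most
#' \code{tsMax}, and the rest are "Remaining". The defaults 14 and 3 (of 16
#' tissues) follow the established housekeeping/tissue-specific convention;
#' they are plain inputs and are not rescaled automatically for other tissue
#' counts.
#'
#' The six labels partition the proteins:
#' \itemize{
#'   \item HK-MDS: \code{nExpressed >= hkMin} and \code{nMDS >= hkMin}
#'   \item TS-MDS: \code{nExpressed <= tsMax} and (strict reading, default)
#'     MDS in \emph{every} tissue where expressed (\code{nMDS == nExpressed
#'     >= 1}); with \code{tsStrict = FALSE}, MDS in at least one
#'     (\code{nMDS >= 1})
#'   \item Remaining-MDS: any other protein with \code{nMDS >= 1}
#'   \item HK-NMDS / TS-NMDS / Remaining-NMDS: the same breadth split for
#'     proteins with \code{nMDS == 0}
#' }
#'
#' @param breadths data.frame from [countBreadths()].
#' @param hkMin minimum breadth of a housekeeping protein (default 14).
#' @param tsMax maximum breadth of a tissue-specific protein (default 3).
#' @param tsStrict use the strict TS-MDS reading (default \code{TRUE}).
#' @return the input data.frame with a \code{label} factor column added.
#' @examples
#' b <- data.frame(protein = c("p1", "p2", "p3"),
#'                 nExpressed = c(16L, 2L, 2L), nMDS = c(15L, 2L, 1L))
#' classifyProteins(b)$label  # HK-MDS, TS-MDS, Remaining-MDS
#' @export
classifyProteins <- function(breadths, hkMin = 14L, tsMax = 3L,
                             tsStrict = TRUE) {
    if (!all(c("protein", "nExpressed", "nMDS") %in% names(breadths)))
        stop("breadths needs columns protein, nExpressed, nMDS",
             call. = FALSE)
    if (hkMin <= tsMax || tsMax < 1L)
        stop("thresholds must satisfy hkMin > tsMax >= 1", call. = FALSE)
    if (any(breadths$nMDS > breadths$nExpressed) ||
        any(breadths$nExpressed < 1L))
        stop("invalid breadths: need 0 <= nMDS <= nExpressed, nExpressed >= 1",
             call. = FALSE)
    ne <- breadths$nExpressed
    nm <- breadths$nMDS
    isMDS <- nm >= 1L
    tsCond <- if (tsStrict) isMDS & nm == ne else isMDS
    label <- ifelse(!isMDS,
        ifelse(ne >= hkMin, "HK-NMDS",
               ifelse(ne <= tsMax, "TS-NMDS", "Remaining-NMDS")),
        ifelse(ne >= hkMin & nm >= hkMin, "HK-MDS",
               ifelse(ne <= tsMax & tsCond, "TS-MDS", "Remaining-MDS")))
    breadths$label <- factor(label, levels = .CLASS_LABELS)
    breadths
}

#' Breadth histogram with housekeeping/tissue-specific bands
#'
#' Distribution of proteins over the number of tissues in which they are
#' expressed (or selected as MDS members). Along with the per-bin fractions,
#' the aggregate fractions of the tissue-specific band (1 to \code{tsMax}
#' tissues) and the housekeeping band (\code{nTissues - bandWidth + 1} to
#' \code{nTissues}) are reported; a bimodal profile concentrates mass in
#' these two bands. For the MDS field only proteins selected at least once
#' contribute.
#'
#' @param breadths data.frame from [countBreadths()].
#' @param field \code{"expressed"} or \code{"mds"}.
#' @param nTissues total number of tissues (defaults to the maximum observed
#'   breadth).
#' @param lowBand,highBand integer vectors of bins aggregated into the
#'   tissue-specific and housekeeping bands; defaults 1:3 and
#'   (nTissues-2):nTissues.
#' @return list with \code{fractions} (named numeric over bins 1..nTissues,
#'   summing to 1), \code{lowBand} and \code{highBand} aggregate fractions,
#'   and \code{n}, the number of proteins counted.
#' @export
breadthHistogram <- function(breadths, field = c("expressed", "mds"),
                             nTissues = NULL, lowBand = NULL,
                             highBand = NULL) {
    field <- match.arg(field)
    x <- if (field == "expressed") breadths$nExpressed else
        breadths$nMDS[breadths$nMDS >= 1L]
    if (length(x) == 0L)
        stop("no proteins to histogram", call. = FALSE)
    if (is.null(nTissues)) nTissues <- max(x)
    if (is.null(lowBand)) lowBand <- 1:min(3L, nTissues)
    if (is.null(highBand)) highBand <- max(1L, nTissues - 2L):nTissues
    counts <- tabulate(x, nbins = nTissues)
    fr <- counts / length(x)
    names(fr) <- as.character(seq_len(nTissues))
    list(fractions = fr,
         lowBand = sum(fr[lowBand]),
         highBand = sum(fr[highBand]),
         n = length(x))
}
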