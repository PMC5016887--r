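#' @import methods
#' @importFrom igraph V E vcount ecount gorder gsize is_igraph
NULL

#' DominatingSet: an exact (CI-)MDS solution
#'
#' Container for the result of an exact minimum-dominating-set solve. For the
#' collective-influence-corrected model the set is additionally the one of
#' maximum total collective influence among all minimum dominating sets; for a
#' standard solve \code{totalCI} is 0 and \code{ell} is \code{NA}.
#'
#' @slot members character vector of member node labels.
#' @slot size integer, \code{length(members)}; for a CI-corrected solve this is
#'   the domination number of the network.
#' @slot totalCI numeric, the summed collective influence of the members under
#'   the model's distance parameter (0 for a standard solve).
#' @slot ell integer distance parameter of the collective-influence weights, or
#'   \code{NA_integer_} for a standard solve.
#' @slot backend character, identifier of the solver that produced the set.
#' @slot status character, always \code{"optimal"}: sub-optimal or unproven
#'   solutions are never returned, they raise an error instead.
#'
#' @seealso [solveStandardMDS()], [solveCIMDS()]
#' @export
setClass("DominatingSet",
    representation(
        members = "character",
        size    = "integer",
        totalCI = "numeric",
        ell     = "integer",
        backend = "character",
        status  = "character"
    )
)

setValidity("DominatingSet", function(object) {
    msg <- character()
    if (length(object@size) != 1L || object@size != length(object@members))
        msg <- c(msg, "size must equal length(members)")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(object@totalCI) != 1L || is.na(object@totalCI) || object@totalCI < 0)
        msg <- c(msg, "totalCI must be a single non-negative number")
    if (!identical(object@status, "optimal"))
        msg <- c(msg, "status must be 'optimal'")
    if (length(msg)) msg else TRUE
})

#' @describeIn DominatingSet-class compact display
#' @param object a \code{DominatingSet}
#' @export
setMethod("show", "DominatingSet", function(object) {
    kind <- if (is.na(object@ell)) "standard MDS" else
        sprintf("CI-MDS (ell = %d)", object@ell)
    cat(sprintf("%s solution of size %d [backend: %s, %s]\n",
                kind, object@size, object@backend, object@status))
    if (!is.na(object@ell))
        cat(sprintf("  total collective influence: %g\n", object@totalCI))
    preview <- utils::head(sort(object@members), 8L)
    cat(sprintf("  members: %s%s\n", paste(preview, collapse = ", "),
                if (object@size > 8L) ", ..." else ""))
    invisible(NULL)
})

#' ExpressionSource: one gene-by-tissue expression table with its threshold
#'
#' A single expression resource (e.g. a microarray, immunohistochemistry or
#' RNA-seq compendium) as a numeric gene-by-tissue matrix together with the
#' source-specific cutoff above which a gene counts as expressed. Thresholds
#' are deliberately mandatory: each profiling platform needs its own stringent
#' cutoff and no cross-platform default is meaningful.
#'
#' @slot source character, name of the resource.
#' @slot values numeric matrix, rows = genes, columns = tissues, with dimnames.
#' @slot threshold single finite numeric cutoff for this source.
#'
#' @seealso [callExpression()]
#' @export
setClass("ExpressionSource",
    representation(
        source    = "character",
        values    = "matrix",
        threshold = "numeric"
    )
)

setValidity("ExpressionSource", function(object) {
    msg <- character()
    if (length(object@source) != 1L || !nzchar(object@source))
        msg <- c(msg, "source must be a single non-empty string")
    if (!is.numeric(object@values))
        msg <- c(msg, "values must be a numeric matrix")
    dn <- dimnames(object@values)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        msg <- c(msg, "values must have gene rownames and tissue colnames")
    else {
        if (anyDuplicated(dn[[1L]])) msg <- c(msg, "duplicate gene rownames")
        if (anyDuplicated(dn[[2L]])) msg <- c(msg, "duplicate tissue colnames")
    }
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        msg <- c(msg, "threshold must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionSource
#'
#' @param values numeric gene-by-tissue matrix with dimnames.
#' @param threshold single finite numeric expression cutoff for this source.
#' @param source name of the resource.
#' @return an [ExpressionSource-class] object.
#' @examples
#' m <- matrix(c(5, 1, 0, 8), 2, 2,
#'             dimnames = list(c("TP53", "GATA1"), c("liver", "brain")))
#' ExpressionSource(m, threshold = 3, source = "rnaseq")
#' @export
ExpressionSource <- function(values, threshold, source = "source1") {
    if (missing(threshold) || is.null(threshold))
        stop("an expression threshold is required for every source ",
             "(no cross-platform default exists)", call. = FALSE)
    new("ExpressionSource", source = as.character(source),
        values = values, threshold = as.numeric(threshold))
}

#' @describeIn ExpressionSource-class compact display
#' @param object an \code{ExpressionSource}
#' @export
setMethod("show", "ExpressionSource", function(object) {
    cat(sprintf("ExpressionSource '%s': %d genes x %d tissues, threshold > %g\n",
                object@source, nrow(object@values), ncol(object@values),
                object@threshold))
    invisible(NULL)
})

#' TissueNetworkSet: per-tissue networks carved from a global interactome
#'
#' The ordered collection of tissue-specific networks produced by node-removal
#' filtering of a global network followed by restriction to the largest
#' connected component. Tissues whose induced subgraph was empty are recorded
#' in \code{dropped} rather than stored.
#'
#' @slot tissues character vector of tissue names, in construction order.
#' @slot networks named list of \code{igraph} objects, one per tissue.
#' @slot dropped character vector of tissues skipped because no expressed
#'   gene intersected the global network.
#'
#' @seealso [buildTissueNetworks()]
#' @export
setClass("TissueNetworkSet",
    representation(
        tissues  = "character",
        networks = "list",
        dropped  = "character"
    )
)

setValidity("TissueNetworkSet", function(object) {
    msg <- character()
    if (!identical(object@tissues, names(object@networks)))
        msg <- c(msg, "tissues must equal names(networks), in order")
    if (!all(vapply(object@networks, igraph::is_igraph, logical(1L))))
        msg <- c(msg, "all networks must be igraph objects")
    if (any(object@dropped %in% object@tissues))
        msg <- c(msg, "a tissue cannot be both stored and dropped")
    if (length(msg)) msg else TRUE
})

#' @describeIn TissueNetworkSet-class summary display with per-tissue sizes
#' @param object a \code{TissueNetworkSet}
#' @export
setMethod("show", "TissueNetworkSet", function(object) {
    cat(sprintf("TissueNetworkSet with %d tissue network(s)\n",
                length(object@tissues)))
    for (t in utils::head(object@tissues, 10L)) {
        g <- object@networks[[t]]
        cat(sprintf("  %-20s %6d proteins, %7d interactions\n",
                    t, igraph::gorder(g), igraph::gsize(g)))
    }
    if (length(object@tissues) > 10L)
        cat(sprintf("  ... and %d more\n", length(object@tissues) - 10L))
    if (length(object@dropped))
        cat(sprintf("  dropped (empty after filtering): %s\n",
                    paste(object@dropped, collapse = ", ")))
    invisible(NULL)
})

# ---- accessors -------------------------------------------------------------

#' @rdname DominatingSet-class
#' @param x a \code{DominatingSet}
#' @export
dsMembers <- function(x) x@members

#' @rdname DominatingSet-class
#' @export
dsSize <- function(x) x@size

#' @rdname DominatingSet-class
#' @export
dsTotalCI <- function(x) x@totalCI

#' @rdname DominatingSet-class
#' @export
dsBackend <- function(x) x@backend

#' @rdname TissueNetworkSet-class
#' @param x a \code{TissueNetworkSet}
#' @export
tissueNames <- function(x) x@tissues

#' @rdname TissueNetworkSet-class
#' @param tissue tissue name
#' @export
tissueNetwork <- function(x, tissue) {
    if (!tissue %in% x@tissues)
        stop("unknown tissue: ", tissue, call. = FALSE)
    x@networks[[tissue]]
}

#' @rdname TissueNetworkSet-class
#' @export
droppedTissues <- function(x) x@dropped
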