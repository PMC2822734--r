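#' @import methods
NULL

#' GeneSet: a labeled set of unique gene symbols
#'
#' A \code{GeneSet} holds the genes attached to one disease term (human,
#' MeSH) or one phenotype term (mouse, Mammalian Phenotype ontology).
#' Members are deduplicated character symbols; the label is the term name.
#'
#' @slot label single non-empty character, the disease/phenotype term.
#' @slot members character vector of unique, non-empty gene symbols.
#'
#' @seealso [geneSet()], [GeneSetCollection-class]
#' @export
setClass("GeneSet",
         representation(label = "character", members = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L || is.na(object@label) ||
        !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    if (anyDuplicated(object@members))
        msg <- c(msg, "'members' must be unique")
    if (length(object@members) && (any(is.na(object@members)) ||
                                   !all(nzchar(object@members))))
        msg <- c(msg, "'members' must be non-empty symbols")
    if (length(msg)) msg else TRUE
})

#' GeneSetCollection: an ordered collection of uniquely labeled gene sets
#'
#' The container for the gene sets entering distance, tree and clustering
#' analyses.  Labels are unique; the gene universe is the union of all
#' members and is derived, never stored stale.
#'
#' @slot sets list of [GeneSet-class] objects with unique labels.
#'
#' @seealso [geneSetCollection()], [geneUniverse()]
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets)) {
        if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
            msg <- c(msg, "'sets' must contain only GeneSet objects")
        else {
            labs <- vapply(object@sets, function(s) s@label, character(1))
            if (anyDuplicated(labs))
                msg <- c(msg, paste0("duplicate set labels: ",
                                     paste(unique(labs[duplicated(labs)]),
                                           collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
})

#' SetDistanceMatrix: symmetric pairwise distances between labeled sets
#'
#' A labeled, symmetric, zero-diagonal matrix of pairwise distances, as
#' produced by [setDistanceMatrix()] from the overlap-coefficient distance.
#' Values from the overlap coefficient lie in [0, 1]; the class only
#' enforces symmetry, the zero diagonal and non-negativity so that matrices
#' read from external PHYLIP files remain representable.
#'
#' @slot values square numeric matrix with dimnames equal to labels.
#'
#' @seealso [setDistanceMatrix()], [njTree()], [readPhylipMatrix()]
#' @export
setClass("SetDistanceMatrix", representation(values = "matrix"))

setValidity("SetDistanceMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v) || nrow(v) != ncol(v))
        return("'values' must be a square numeric matrix")
    if (anyNA(v)) msg <- c(msg, "'values' must not contain NA/NaN")
    labs <- rownames(v)
    if (is.null(labs) || anyDuplicated(labs) || !all(nzchar(labs)))
        msg <- c(msg, "rows must carry unique non-empty labels")
    if (!identical(rownames(v), colnames(v)))
        msg <- c(msg, "row and column labels must agree")
    if (!anyNA(v)) {
        if (max(abs(v - t(v))) > 1e-12)
            msg <- c(msg, "matrix must be symmetric within 1e-12")
        if (any(abs(diag(v)) > 0))
            msg <- c(msg, "diagonal must be exactly zero")
        if (any(v < 0))
            msg <- c(msg, "distances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})
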