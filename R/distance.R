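#' Overlap-coefficient distance between two gene sets
#'
#' The distance between two sets is one minus the overlap coefficient: the
#' number of shared genes divided by the size of the smaller set, subtracted
#' from one.  Identical (or nested) sets are at distance 0; disjoint sets at
#' distance 1.  The measure is deliberately normalized by the smaller set so
#' that a small disease set fully contained in a large one counts as a
#' perfect match; it is not a metric (the triangle inequality can fail on
#' subset chains), which the downstream tree methods do not require.
#'
#' @param a,b [GeneSet-class] objects; both must be non-empty.
#'
#' @return a single numeric in [0, 1].
#'
#' @examples
#' hyp <- geneSet("Hypertension",
#'   c("ACE", "AGT", "NOS3", "CYP11B2", "GNB3", "ADD1", "AGTR1", "ADRB2"))
#' mi <- geneSet("Myocardial Infarction",
#'   c("NOS3", "ACE", "SERPINE1", "ITGA2", "LPL", "APOE", "GP1BA", "F7"))
#' overlapDistance(hyp, mi)   # 1 - 2/8 = 0.75
#' @seealso [setDistanceMatrix()]
#' @export
overlapDistance <- function(a, b) {
    stopifnot(is(a, "GeneSet"), is(b, "GeneSet"))
    if (length(a) == 0L || length(b) == 0L)
        stop("overlap distance is undefined for empty gene sets")
    shared <- length(intersect(members(a), members(b)))
    1 - shared / min(length(a), length(b))
}

#' Pairwise overlap-distance matrix for a gene-set collection
#'
#' Computes all pairwise [overlapDistance()] values.  Intersections are
#' obtained through the binary membership matrix (set-by-gene cross
#' products), which is algebraically identical to pairwise set
#' intersection.
#'
#' @param collection a [GeneSetCollection-class] with at least 2 non-empty
#'   sets (at least 3 are needed for downstream tree building).
#' @param method dissimilarity used; the default (and the measure every
#'   downstream default assumes) is the min-normalized overlap
#'   coefficient distance.  \code{"jaccard"} (1 - |A∩B|/|A∪B|) and
#'   \code{"dice"} (1 - 2|A∩B|/(|A|+|B|)) are available as explicit
#'   alternatives only.
#'
#' @return a [SetDistanceMatrix-class] whose label order equals the
#'   collection order.
#'
#' @export
setDistanceMatrix <- function(collection,
                              method = c("overlap", "jaccard", "dice")) {
    method <- match.arg(method)
    stopifnot(is(collection, "GeneSetCollection"))
    labs <- setLabels(collection)
    if (length(labs) < 2L)
        stop("need at least 2 gene sets")
    sizes <- vapply(collection@sets, length, integer(1))
    if (any(sizes == 0L))
        stop("all gene sets must be non-empty")
    M <- membershipMatrix(collection)
    inter <- tcrossprod(M)
    v <- switch(method,
        overlap = 1 - inter / outer(sizes, sizes, pmin),
        jaccard = 1 - inter / (outer(sizes, sizes, `+`) - inter),
        dice = 1 - 2 * inter / outer(sizes, sizes, `+`))
    diag(v) <- 0
    v <- (v + t(v)) / 2  # remove last-bit asymmetry from float division
    dimnames(v) <- list(labs, labs)
    new("SetDistanceMatrix", values = v)
}

#' Build a SetDistanceMatrix from a plain labeled matrix
#'
#' @param values square numeric matrix; symmetric, zero diagonal, labeled
#'   dimnames.
#' @param x a \code{SetDistanceMatrix}.
#' @param ... unused.
#'
#' @return \code{distanceMatrix()} wraps and validates the matrix;
#'   \code{as.matrix()} unwraps it; \code{labels()} returns the label order.
#' @export
distanceMatrix <- function(values) {
    new("SetDistanceMatrix", values = values)
}

#' @rdname distanceMatrix
#' @export
setMethod("dim", "SetDistanceMatrix", function(x) dim(x@values))

#' @rdname distanceMatrix
#' @export
as.matrix.SetDistanceMatrix <- function(x, ...) x@values

#' @rdname distanceMatrix
#' @export
labels.SetDistanceMatrix <- function(object, ...) rownames(object@values)

setMethod("show", "SetDistanceMatrix", function(object) {
    n <- nrow(object@values)
    cat("SetDistanceMatrix over ", n, " sets\n", sep = "")
    k <- min(n, 5L)
    print(round(object@values[seq_len(k), seq_len(k), drop = FALSE], 4))
    if (n > k) cat("  ... (", n, " x ", n, " total)\n", sep = "")
})
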