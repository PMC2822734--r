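#' Binary membership matrix of a gene-set collection
#'
#' Vectorizes gene sets for clustering: entry (i, g) is 1 iff gene g
#' belongs to set i.  Columns follow the sorted gene universe, rows the
#' collection order; row sums equal set sizes.
#'
#' @param collection a non-empty [GeneSetCollection-class].
#' @return a 0/1 numeric matrix, sets x universe genes, with dimnames.
#' @export
membershipMatrix <- function(collection) {
    stopifnot(is(collection, "GeneSetCollection"))
    if (length(collection) == 0L)
        stop("collection is empty")
    univ <- geneUniverse(collection)
    M <- t(vapply(collection@sets,
                  function(s) as.numeric(univ %in% members(s)),
                  numeric(length(univ))))
    dimnames(M) <- list(setLabels(collection), univ)
    M
}

## Ward inter-cluster distance between clusters K and L:
##   D_KL = ||xbar_K - xbar_L||^2 / (1/N_K + 1/N_L)
## which equals the increase in within-cluster sum of squares caused by
## merging K and L.  For singletons this is ||x - y||^2 / 2, so the
## Lance-Williams recurrence (linear in the distances) reproduces D_KL
## throughout when seeded with half the squared Euclidean distances.

#' Ward minimum-variance clustering of binary membership vectors
#'
#' Agglomerative clustering of gene sets represented as rows of a binary
#' membership matrix.  At each step the pair of clusters whose merge
#' minimally increases the within-cluster sum of squares is joined; the
#' merge height recorded is that increase,
#' \eqn{D_{KL} = \|\bar x_K - \bar x_L\|^2 / (1/N_K + 1/N_L)} — the ANOVA
#' between-cluster sum of squares added up over all variables.  Heights
#' are non-decreasing along the merge sequence.  Implemented with the
#' Lance-Williams recurrence (O(n^2) memory), which is exactly equivalent
#' to recomputing centroid distances at every step.
#'
#' Ties in the minimal merge distance (values within 1e-12 of the
#' minimum) are broken deterministically: the pair with the smallest
#' (min cluster id, max cluster id) merges, where a cluster's id is the
#' smallest original row index it contains.
#'
#' @param matrix binary (0/1) numeric matrix, observations in rows; at
#'   least 2 rows.  Row names become leaf labels.  By contract this
#'   module clusters membership vectors, so non-binary entries are an
#'   error; use \code{binary = FALSE} to lift that check for
#'   count-weighted variants.
#' @param binary enforce 0/1 entries (default TRUE).
#'
#' @return an object of class \code{c("wardDendrogram", "hclust")} with
#'   the standard \code{merge}, \code{height}, \code{order},
#'   \code{labels} components, so that \code{stats::cutree} and
#'   \code{plot} apply.
#'
#' @seealso [cutDendrogram()], [membershipMatrix()]
#' @export
wardCluster <- function(matrix, binary = TRUE) {
    X <- as.matrix(matrix)
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 rows to cluster")
    if (binary && !all(X %in% c(0, 1)))
        stop("membership matrix must be binary (0/1); ",
             "pass binary = FALSE to cluster weighted vectors")
    labs <- rownames(X)
    if (is.null(labs)) labs <- as.character(seq_len(n))

    ## D_KL seeded at half the squared Euclidean distance
    D <- as.matrix(stats::dist(X))^2 / 2
    diag(D) <- Inf
    active <- rep(TRUE, n)
    id <- seq_len(n)            # smallest original row index per cluster
    node <- -seq_len(n)         # hclust merge coding: -leaf, +merge step
    size <- rep(1L, n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)

    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        sub <- D[idx, idx, drop = FALSE]
        dmin <- min(sub)
        hit <- which(sub - dmin <= 1e-12 * max(1, dmin), arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        pi <- idx[hit[, 1]]; pj <- idx[hit[, 2]]
        lo <- pmin(id[pi], id[pj]); hi <- pmax(id[pi], id[pj])
        best <- order(lo, hi)[1]
        i <- pi[best]; j <- pj[best]

        merge[step, ] <- sort(c(node[i], node[j]))
        height[step] <- D[i, j]

        ## Lance-Williams update for Ward's method
        others <- idx[idx != i & idx != j]
        if (length(others)) {
            ni <- size[i]; nj <- size[j]; nk <- size[others]
            D[i, others] <- ((ni + nk) * D[i, others] +
                             (nj + nk) * D[j, others] -
                             nk * D[i, j]) / (ni + nj + nk)
            D[others, i] <- D[i, others]
        }
        size[i] <- size[i] + size[j]
        id[i] <- min(id[i], id[j])
        node[i] <- step
        active[j] <- FALSE
        D[j, ] <- Inf; D[, j] <- Inf
    }

    ord <- .leafOrder(merge, n)
    structure(list(merge = merge, height = height, order = ord,
                   labels = labs, method = "ward.DKL",
                   call = match.call(),
                   dist.method = "half squared Euclidean"),
              class = c("wardDendrogram", "hclust"))
}

## Display order: left-to-right leaves of the merge tree.
.leafOrder <- function(merge, n) {
    expand <- function(k) {
        if (k < 0) return(-k)
        c(expand(merge[k, 1]), expand(merge[k, 2]))
    }
    if (n == 1L) return(1L)
    expand(nrow(merge))
}

#' Cut a Ward dendrogram into k clusters
#'
#' Undoes the last k-1 merges, assigning every leaf to exactly one of k
#' clusters.
#'
#' @param dendrogram an \code{hclust}-like object from [wardCluster()].
#' @param k number of clusters, between 1 and the number of leaves.
#'
#' @return a named integer vector of cluster assignments (names = leaf
#'   labels, values in 1..k).
#' @export
cutDendrogram <- function(dendrogram, k) {
    stopifnot(inherits(dendrogram, "hclust"))
    n <- length(dendrogram$labels)
    if (k < 1L || k > n)
        stop("k must be between 1 and ", n)
    stats::cutree(dendrogram, k = k)
}
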