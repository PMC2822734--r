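#' Configuration for the Fitch-Margoliash criterion
#'
#' The weighted least-squares tree criterion is
#' \deqn{\sum_{i<j} n_{ij} (D_{ij} - d_{ij})^2 / D_{ij}^P}
#' where \eqn{D} is the observed distance, \eqn{d} the tree path distance
#' (the sum of branch lengths connecting the two leaves), \eqn{n} the
#' replicate count of each observed distance (1 in simple cases), and the
#' power \eqn{P} distinguishes the methods: 2.0 for Fitch-Margoliash,
#' 0.0 for the Neighbor-Joining-style unweighted fit.
#'
#' Gene-set distance matrices legitimately contain zero off-diagonal
#' distances (duplicate or nested sets); with \eqn{P = 2} the denominator
#' is floored at \code{denomEpsilon} to keep the criterion finite.
#'
#' @param powerP weighting power; 2 (Fitch-Margoliash) and 0 (NJ-style)
#'   are the standard choices, other values are accepted with a warning.
#' @param replicatesN per-pair replicate count n, a single value or a
#'   vector recycled over pairs; default 1.
#' @param denomEpsilon floor for the \eqn{D^P} denominator, default 1e-6.
#'
#' @return a list of class \code{"fmConfig"}.
#' @export
fmConfig <- function(powerP = 2, replicatesN = 1, denomEpsilon = 1e-6) {
    stopifnot(all(replicatesN >= 1), denomEpsilon > 0)
    if (!powerP %in% c(0, 2))
        warning("power P = ", powerP,
                " is non-standard (2 = Fitch-Margoliash, 0 = NJ)")
    structure(list(powerP = powerP, replicatesN = replicatesN,
                   denomEpsilon = denomEpsilon), class = "fmConfig")
}

.checkSquare <- function(matrix) {
    stopifnot(is(matrix, "SetDistanceMatrix"))
    v <- as.matrix(matrix)
    if (anyNA(v)) stop("distance matrix contains NA/NaN")
    v
}

#' Neighbor-Joining tree from a set distance matrix
#'
#' Standard Saitou-Nei Neighbor-Joining: repeatedly joins the pair
#' minimizing the Q criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} with the classic branch-length
#' and distance updates, finishing with a central trifurcation.  On an
#' additive matrix the returned tree's leaf-to-leaf path distances
#' reproduce the input exactly.  Ties in the Q minimum are broken by
#' joining the lexicographically smallest label pair, making the result a
#' deterministic function of the matrix (this is what makes randomized
#' input order an informative replicate: ties resolve differently under
#' relabeling, identically under rerunning).
#'
#' Negative branch lengths are standard NJ output on non-additive input
#' and are kept; pass \code{clampNegative = TRUE} to clamp them to zero
#' (this alters path distances).
#'
#' @param matrix a [SetDistanceMatrix-class] with >= 3 labels.
#' @param clampNegative clamp negative branch lengths to 0, default FALSE.
#'
#' @return an unrooted \code{ape::phylo} tree over the matrix labels.
#'
#' @examples
#' m <- distanceMatrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'                     dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' njTree(m)   # pendant lengths 1, 2, 3
#' @export
njTree <- function(matrix, clampNegative = FALSE) {
    v <- .checkSquare(matrix)
    n <- nrow(v)
    if (n < 3L) stop("Neighbor-Joining needs at least 3 labels")
    labs <- rownames(v)
    ## each active cluster carries its Newick subtree string; tips are
    ## written as positional placeholders so labels with Newick
    ## metacharacters (spaces, commas, parentheses) survive parsing
    subs <- sprintf("L%d", seq_len(n))
    D <- v
    repeat {
        m <- nrow(D)
        if (m == 3L) break
        r <- rowSums(D)
        Q <- (m - 2) * D - outer(r, r, `+`)
        diag(Q) <- Inf
        qmin <- min(Q)
        hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        ## lexicographically smallest (sorted) label pair among ties
        lab1 <- pmin(rownames(D)[hit[, 1]], rownames(D)[hit[, 2]])
        lab2 <- pmax(rownames(D)[hit[, 1]], rownames(D)[hit[, 2]])
        best <- order(lab1, lab2)[1]
        i <- hit[best, 1]; j <- hit[best, 2]
        vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
        vj <- D[i, j] - vi
        if (clampNegative) { vi <- max(vi, 0); vj <- max(vj, 0) }
        newsub <- sprintf("(%s:%.15g,%s:%.15g)", subs[i], vi, subs[j], vj)
        dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                    c(dnew[keep], 0))
        newlab <- paste0("\r", rownames(D)[i])  # internal, never printed
        rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newlab)
        subs <- c(subs[keep], newsub)
        D <- D2
    }
    ## terminal trifurcation: closed-form pendant lengths
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    if (clampNegative) { a <- max(a, 0); b <- max(b, 0); c3 <- max(c3, 0) }
    nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                   subs[1], a, subs[2], b, subs[3], c3)
    tree <- ape::read.tree(text = nwk)
    tree$tip.label <- labs[as.integer(substring(tree$tip.label, 2L))]
    tree
}

#' Leaf-to-leaf path distances of a tree
#'
#' The expected distance under a tree: for each leaf pair, the sum of the
#' branch lengths on the unique connecting path.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return a [SetDistanceMatrix-class] over the tip labels (tip order).
#' @export
treePathDistances <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    d <- ape::cophenetic.phylo(tree)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    new("SetDistanceMatrix", values = d)
}

## pairs x edges incidence: row (i,j) marks the edges on the i-j path.
.pathIncidence <- function(tree) {
    ntip <- length(tree$tip.label)
    nedge <- nrow(tree$edge)
    ## adjacency with edge ids
    nn <- max(tree$edge)
    adj <- vector("list", nn)
    for (e in seq_len(nedge)) {
        a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
        adj[[a]] <- rbind(adj[[a]], c(b, e))
        adj[[b]] <- rbind(adj[[b]], c(a, e))
    }
    ## BFS from each tip recording the edge used to reach every node
    pairs <- utils::combn(ntip, 2)
    A <- matrix(0, ncol(pairs), nedge)
    for (tip in seq_len(ntip)) {
        par_edge <- rep(NA_integer_, nn)
        parent <- rep(NA_integer_, nn)
        queue <- tip; seen <- rep(FALSE, nn); seen[tip] <- TRUE
        while (length(queue)) {
            u <- queue[1]; queue <- queue[-1]
            for (r in seq_len(NROW(adj[[u]]))) {
                w <- adj[[u]][r, 1]
                if (!seen[w]) {
                    seen[w] <- TRUE
                    parent[w] <- u
                    par_edge[w] <- adj[[u]][r, 2]
                    queue <- c(queue, w)
                }
            }
        }
        for (p in which(pairs[1, ] == tip)) {
            node <- pairs[2, p]
            while (!is.na(parent[node])) {
                A[p, par_edge[node]] <- 1
                node <- parent[node]
            }
        }
    }
    list(A = A, pairs = pairs)
}

#' Weighted least-squares branch lengths on a fixed topology
#'
#' Keeps the topology and refits every branch length to minimize the
#' Fitch-Margoliash criterion
#' \eqn{\sum n (D - d)^2 / \max(D, \epsilon)^P}, which for fixed topology
#' is a weighted linear least-squares problem on the path-incidence
#' system (each leaf pair's path distance is a sum of branch lengths).
#' With \eqn{P = 0} this is the unweighted least-squares fit; with
#' \eqn{P = 2} short observed distances carry more weight.  Negative
#' fitted lengths are permitted.
#'
#' @param topology an \code{ape::phylo} whose tips are exactly the matrix
#'   labels.
#' @param matrix a [SetDistanceMatrix-class].
#' @param config an [fmConfig()] object.
#'
#' @return the topology with refitted \code{edge.length}.
#' @export
fitBranchLengthsLS <- function(topology, matrix, config = fmConfig()) {
    v <- .checkSquare(matrix)
    stopifnot(inherits(topology, "phylo"))
    if (!setequal(topology$tip.label, rownames(v)))
        stop("topology leaves and matrix labels differ")
    inc <- .pathIncidence(topology)
    Dobs <- v[topology$tip.label, topology$tip.label]
    D <- vapply(seq_len(ncol(inc$pairs)), function(p)
        Dobs[inc$pairs[1, p], inc$pairs[2, p]], numeric(1))
    w <- rep_len(config$replicatesN, length(D)) /
        pmax(D, config$denomEpsilon)^config$powerP
    fit <- stats::lm.wfit(inc$A, D, w)
    if (fit$rank < ncol(inc$A))
        stop("degenerate topology: least-squares system is singular")
    out <- topology
    out$edge.length <- unname(fit$coefficients)
    out
}

#' Evaluate the Fitch-Margoliash criterion of a tree against a matrix
#'
#' Computes \eqn{\sum_{i<j} n (D_{ij} - d_{ij})^2 / \max(D_{ij},
#' \epsilon)^P} where \eqn{d} is the tree's leaf-to-leaf path distance.
#' Zero iff the tree reproduces every observed distance.
#'
#' @inheritParams fitBranchLengthsLS
#' @param tree an \code{ape::phylo} with branch lengths whose tips are
#'   exactly the matrix labels.
#'
#' @return a single non-negative number.
#' @export
fmCriterion <- function(tree, matrix, config = fmConfig()) {
    v <- .checkSquare(matrix)
    stopifnot(inherits(tree, "phylo"))
    if (!setequal(tree$tip.label, rownames(v)))
        stop("tree leaves and matrix labels differ")
    d <- as.matrix(treePathDistances(tree))[rownames(v), colnames(v)]
    ut <- upper.tri(v)
    D <- v[ut]; dd <- d[ut]
    n <- rep_len(config$replicatesN, length(D))
    sum(n * (D - dd)^2 / pmax(D, config$denomEpsilon)^config$powerP)
}

#' Randomized-input-order Neighbor-Joining replicates
#'
#' Reruns [njTree()] after permuting the order of the gene sets (and
#' hence the matrix rows) with a seeded generator.  Because NJ tie-breaks
#' depend on label order only through genuine ties, agreement across
#' replicates is evidence that the recovered topology is not an artifact
#' of input order.  The same seed always yields the same trees.
#'
#' @param collection a [GeneSetCollection-class] with >= 3 sets.
#' @param nReps number of replicates (>= 1).
#' @param seed integer seed fixing all permutations.
#' @param clampNegative passed to [njTree()].
#'
#' @return a list of \code{ape::phylo} trees carrying the original
#'   labels; attribute \code{"permutations"} records the orders used.
#'   The first replicate uses the identity permutation, so it equals
#'   \code{njTree(setDistanceMatrix(collection))}.
#' @export
randomizedReplicates <- function(collection, nReps, seed,
                                 clampNegative = FALSE) {
    stopifnot(nReps >= 1)
    labs <- setLabels(collection)
    full <- as.matrix(setDistanceMatrix(collection))
    perms <- vector("list", nReps)
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
    trees <- vector("list", nReps)
    for (k in seq_len(nReps)) {
        p <- if (k == 1L) seq_along(labs) else sample(length(labs))
        perms[[k]] <- p
        m <- new("SetDistanceMatrix", values = full[p, p])
        trees[[k]] <- njTree(m, clampNegative = clampNegative)
    }
    attr(trees, "permutations") <- perms
    trees
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two trees (symmetric-difference size); 0 iff the unrooted topologies
#' agree.  Always even for two fully resolved trees on the same leaves.
#'
#' @param t1,t2 \code{ape::phylo} trees over the same leaf label set.
#' @return a non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
    stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
    if (!setequal(t1$tip.label, t2$tip.label))
        stop("trees have different leaf label sets")
    as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Does a leaf group form a split of the tree?
#'
#' TRUE iff some edge of the unrooted tree separates exactly the given
#' leaves from the rest — the unrooted notion of monophyly.  Groups of
#' size 1 or n-1 are trivially splits.
#'
#' @param tree an \code{ape::phylo}.
#' @param tips character vector of leaf labels (a proper non-empty subset).
#' @return logical.
#' @export
groupIsSplit <- function(tree, tips) {
    labs <- tree$tip.label
    stopifnot(all(tips %in% labs))
    k <- length(tips)
    if (k == 0L || k == length(labs))
        stop("tips must be a proper non-empty subset of the leaves")
    if (k == 1L || k == length(labs) - 1L) return(TRUE)
    target <- sort(match(tips, labs))
    parts <- ape::prop.part(tree)   # tip sets below each internal node
    for (p in parts) {
        if (length(p) == length(labs)) next
        if (length(p) == length(target) && all(sort(p) == target))
            return(TRUE)
        comp <- setdiff(seq_along(labs), p)
        if (length(comp) == length(target) && all(sort(comp) == target))
            return(TRUE)
    }
    FALSE
}
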