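## Shared fixture builders and independent oracles.  Everything is
## generated in code under explicit seeds; no binary fixtures.

randomCollection <- function(nSets = 5, seed = 1, nGenes = 30,
                             minSize = 2, maxSize = 10) {
    set.seed(seed)
    genes <- sprintf("G%03d", seq_len(nGenes))
    sets <- lapply(seq_len(nSets), function(i)
        geneSet(sprintf("Set %02d", i),
                sample(genes, sample(minSize:maxSize, 1))))
    geneSetCollection(sets)
}

## association table with random flags/terms; includes unfiltered rows
randomRecordTable <- function(seed, nRec = 20, nGenes = 6, nTerms = 4) {
    set.seed(seed)
    term <- sample(c(sprintf("Term %d", seq_len(nTerms)), ""), nRec,
                   replace = TRUE)
    data.frame(
        gene_symbol = sample(sprintf("g%02d", seq_len(nGenes)), nRec,
                             replace = TRUE),
        gene_id = NA_integer_,
        term = term,
        disease_class = "CLASS",
        association = factor(sample(c("Y", "N", "UNKNOWN"), nRec,
                                    replace = TRUE, prob = c(.6, .2, .2)),
                             levels = c("Y", "N", "UNKNOWN")),
        publication_id = sprintf("P%03d", sample(10, nRec, TRUE)),
        stringsAsFactors = FALSE)
}

randomBinaryMatrix <- function(seed, n = NULL, p = NULL) {
    set.seed(seed)
    if (is.null(n)) n <- sample(2:7, 1)
    if (is.null(p)) p <- sample(3:8, 1)
    m <- matrix(rbinom(n * p, 1, 0.5), n, p)
    rownames(m) <- sprintf("row%d", seq_len(n))
    m
}

## unrooted random binary tree with branch lengths U(0.1, 2)
randomBranchTree <- function(nLeaves, seed) {
    set.seed(seed)
    tr <- ape::unroot(ape::rtree(nLeaves,
                                 tip.label = sprintf("t%02d",
                                                     seq_len(nLeaves))))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
    tr
}

## ---- Ward brute-force oracle: recompute within-cluster SS increases
## from the definition at every step, no Lance-Williams shortcut.

withinSS <- function(X) {
    if (nrow(X) < 2) return(0)
    sum(sweep(X, 2, colMeans(X))^2)
}

bruteWard <- function(X) {
    n <- nrow(X)
    clusters <- lapply(seq_len(n), identity)
    merges <- list()
    while (length(clusters) > 1) {
        best <- NULL
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            u <- c(clusters[[a]], clusters[[b]])
            delta <- withinSS(X[u, , drop = FALSE]) -
                withinSS(X[clusters[[a]], , drop = FALSE]) -
                withinSS(X[clusters[[b]], , drop = FALSE])
            key <- c(min(clusters[[a]][1], clusters[[b]][1]),
                     max(clusters[[a]][1], clusters[[b]][1]))
            if (is.null(best) || delta < best$delta - 1e-10 ||
                (abs(delta - best$delta) <= 1e-10 &&
                 (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
                best <- list(a = a, b = b, delta = delta, key = key)
            }
        }
        merges[[length(merges) + 1L]] <- list(
            a = sort(clusters[[best$a]]), b = sort(clusters[[best$b]]),
            height = best$delta)
        clusters[[best$a]] <- sort(c(clusters[[best$a]],
                                     clusters[[best$b]]))
        clusters[[best$b]] <- NULL
    }
    merges
}

## expand an hclust merge row into the two member-index sets
mergeSets <- function(hc) {
    expand <- function(k) {
        if (k < 0) return(-k)
        sort(c(expand(hc$merge[k, 1]), expand(hc$merge[k, 2])))
    }
    lapply(seq_len(nrow(hc$merge)), function(s)
        list(a = expand(hc$merge[s, 1]), b = expand(hc$merge[s, 2]),
             height = hc$height[s]))
}

sameMergeStep <- function(x, y, tol = 1e-8) {
    setsEqual <- (identical(x$a, y$a) && identical(x$b, y$b)) ||
        (identical(x$a, y$b) && identical(x$b, y$a))
    setsEqual && abs(x$height - y$height) <= tol
}

## ---- Independent weighted least-squares branch-length oracle:
## explicit path enumeration (ape::nodepath) + normal equations.

lsOracle <- function(tree, mat, powerP = 2, eps = 1e-6) {
    v <- as.matrix(mat)
    tips <- tree$tip.label
    pairs <- utils::combn(length(tips), 2)
    A <- matrix(0, ncol(pairs), nrow(tree$edge))
    D <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        path <- ape::nodepath(tree, i, j)
        for (s in seq_len(length(path) - 1)) {
            e <- which((tree$edge[, 1] == path[s] &
                        tree$edge[, 2] == path[s + 1]) |
                       (tree$edge[, 2] == path[s] &
                        tree$edge[, 1] == path[s + 1]))
            A[p, e] <- 1
        }
        D[p] <- v[tips[i], tips[j]]
    }
    w <- 1 / pmax(D, eps)^powerP
    solve(t(A) %*% (A * w), t(A) %*% (D * w))[, 1]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## the full planted-structure pipeline: records -> ward cut at k
plantedPipeline <- function(seed, minSize = 3) {
    cfg <- syntheticConfig(seed = seed)
    sim <- simulateGadRecords(cfg)
    summ <- countCooccurrences(filterRecords(sim$records), "by_term")
    gsc <- buildGeneSets(summ, minSize = minSize)
    list(cfg = cfg, sim = sim, gsc = gsc,
         truth = sim$truth$termGroup[setLabels(gsc)])
}
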