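threeTaxon <- distanceMatrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

test_that("three-taxon closed form: pendant lengths 1, 2, 3", {
    tr <- njTree(threeTaxon)
    d <- as.matrix(treePathDistances(tr))
    expect_equal(d["A", "B"], 3)
    expect_equal(d["A", "C"], 4)
    expect_equal(d["B", "C"], 5)
    lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
    expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("four-taxon additive matrix recovers the generating bipartition", {
    ## tree ((A,B),(C,D)) with all branches 1; path distances are additive
    gen <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
    D <- distanceMatrix(as.matrix(treePathDistances(gen)))
    rec <- njTree(D)
    expect_equal(rfDistance(rec, gen), 0)
    drec <- as.matrix(treePathDistances(rec))
    expect_lt(max(abs(drec[labels(D), labels(D)] - as.matrix(D))), 1e-12)
    ## least-squares fit on each of the 3 topologies: only the true one
    ## reaches zero residual
    topos <- c("((A:1,B:1):1,C:1,D:1);",
               "((A:1,C:1):1,B:1,D:1);",
               "((A:1,D:1):1,B:1,C:1);")
    resid <- vapply(topos, function(t) {
        fit <- fitBranchLengthsLS(ape::read.tree(text = t), D,
                                  fmConfig(powerP = 0))
        fmCriterion(fit, D, fmConfig(powerP = 0))
    }, numeric(1))
    expect_lt(resid[1], 1e-18)
    expect_true(all(resid[2:3] > 0.1))
})

test_that("NJ consistency on random additive matrices", {
    for (seed in 1:30) {
        n <- sample(5:12, 1)
        tr <- randomBranchTree(n, seed)
        D <- distanceMatrix(as.matrix(treePathDistances(tr)))
        rec <- njTree(D)
        expect_equal(rfDistance(rec, tr), 0)
        drec <- as.matrix(treePathDistances(rec))
        expect_lt(max(abs(drec[labels(D), labels(D)] - as.matrix(D))),
                  1e-9)
        expect_lt(fmCriterion(rec, D), 1e-16)
    }
})

test_that("NJ agrees with an independent implementation off ties", {
    for (seed in 1:10) {
        tr <- randomBranchTree(8, seed + 100)
        v <- as.matrix(treePathDistances(tr))
        set.seed(seed)
        noise <- matrix(runif(64, 0, 0.05), 8); noise <- noise + t(noise)
        diag(noise) <- 0
        D <- distanceMatrix(v + noise)
        expect_equal(rfDistance(njTree(D), ape::nj(as.matrix(D))), 0)
    }
})

test_that("NJ tie-breaking joins the lexicographically smallest pair", {
    ## 4 taxa, fully symmetric distances: every Q entry ties
    v <- matrix(1, 4, 4); diag(v) <- 0
    dimnames(v) <- list(c("D", "C", "B", "A"), c("D", "C", "B", "A"))
    tr <- njTree(distanceMatrix(v))
    ## A and B must be joined first regardless of matrix order
    expect_true(groupIsSplit(tr, c("A", "B")))
})

test_that("matrix validation rejects asymmetry and NaN", {
    v <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"),
                                                  c("a", "b")))
    expect_error(distanceMatrix(v), "symmetric")
    v2 <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
    expect_error(distanceMatrix(v2), "NA")
})

test_that("FM criterion: direct formula values and config powers", {
    ## perfect fit
    tr <- njTree(threeTaxon)
    expect_equal(fmCriterion(tr, threeTaxon), 0)
    ## single pair D=2, d=1: (2-1)^2/2^2 = 0.25 under P=2; 1 under P=0
    pair <- ape::read.tree(text = "(X:0.5,Y:0.5);")
    D <- distanceMatrix(matrix(c(0, 2, 2, 0), 2,
        dimnames = list(c("X", "Y"), c("X", "Y"))))
    expect_equal(fmCriterion(pair, D, fmConfig(powerP = 2)), 0.25)
    expect_equal(fmCriterion(pair, D, fmConfig(powerP = 0)), 1)
    ## replicate weight n scales linearly
    expect_equal(fmCriterion(pair, D, fmConfig(powerP = 2,
                                               replicatesN = 3)), 0.75)
    expect_error(fmCriterion(pair, threeTaxon), "labels differ")
    expect_warning(fmConfig(powerP = 1), "non-standard")
})

test_that("LS branch fitting matches the normal-equations oracle", {
    ## 3-taxon: closed form reproduced exactly
    tr <- njTree(threeTaxon)
    fit <- fitBranchLengthsLS(tr, threeTaxon)
    expect_equal(sort(fit$edge.length), c(1, 2, 3))
    ## additive 5-taxon matrix on the true topology: zero residual,
    ## generating lengths recovered
    gen <- randomBranchTree(5, 999)
    D <- distanceMatrix(as.matrix(treePathDistances(gen)))
    fit5 <- fitBranchLengthsLS(gen, D)
    expect_equal(fit5$edge.length, gen$edge.length, tolerance = 1e-9)
    expect_lt(fmCriterion(fit5, D), 1e-16)
    ## random noisy instances vs independent oracle, both powers
    for (seed in 1:12) {
        n <- sample(4:8, 1)
        tr <- randomBranchTree(n, seed + 500)
        v <- as.matrix(treePathDistances(tr))
        set.seed(seed)
        noise <- matrix(runif(n * n, 0, 0.3), n); noise <- noise + t(noise)
        diag(noise) <- 0
        D <- distanceMatrix(v + noise)
        for (P in c(0, 2)) {
            fit <- fitBranchLengthsLS(tr, D, fmConfig(powerP = P))
            expect_equal(fit$edge.length,
                         lsOracle(tr, D, powerP = P),
                         tolerance = 1e-8)
        }
        ## P=0 and P=2 genuinely differ on noisy input
        f0 <- fitBranchLengthsLS(tr, D, fmConfig(powerP = 0))
        f2 <- fitBranchLengthsLS(tr, D, fmConfig(powerP = 2))
        expect_gt(max(abs(f0$edge.length - f2$edge.length)), 1e-6)
    }
})

test_that("randomized replicates are seeded, label-preserving and stable", {
    gsc <- randomCollection(7, seed = 21, nGenes = 40)
    reps <- randomizedReplicates(gsc, nReps = 5, seed = 17)
    expect_length(reps, 5)
    ## identity permutation first: equals plain NJ
    expect_equal(rfDistance(reps[[1]], njTree(setDistanceMatrix(gsc))), 0)
    for (t in reps) expect_setequal(t$tip.label, setLabels(gsc))
    ## same seed twice: byte-identical Newick
    reps2 <- randomizedReplicates(gsc, nReps = 5, seed = 17)
    ## (negative NJ branch lengths are expected on non-additive input,
    ## hence the writer warnings are silenced here)
    suppressWarnings(
        expect_identical(vapply(reps, writeNewick, character(1)),
                         vapply(reps2, writeNewick, character(1))))
    ## additive input: all replicates one topology
    tr <- randomBranchTree(7, 4)
    v <- as.matrix(treePathDistances(tr))
    fake <- geneSetCollection(list())  # replicate directly over matrix
    perms <- replicate(6, sample(7), simplify = FALSE)
    trees <- lapply(perms, function(p)
        njTree(distanceMatrix(v[p, p])))
    for (t in trees) expect_equal(rfDistance(t, trees[[1]]), 0)
})

test_that("Robinson-Foulds distances on enumerated 4-leaf cases", {
    t1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
    t2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
    star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
    expect_equal(rfDistance(t1, t1), 0)
    expect_equal(rfDistance(t1, t2), 2)
    expect_equal(rfDistance(t1, star), 1)
    expect_error(rfDistance(t1, njTree(threeTaxon)), "leaf label sets")
})

test_that("group-split detection reads unrooted bipartitions", {
    t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
    expect_true(groupIsSplit(t1, c("A", "B")))
    expect_true(groupIsSplit(t1, c("C", "D")))
    expect_false(groupIsSplit(t1, c("A", "C")))
    expect_true(groupIsSplit(t1, "A"))
    expect_error(groupIsSplit(t1, c("A", "B", "C", "D")), "proper")
})
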