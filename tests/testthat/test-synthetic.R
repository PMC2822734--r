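test_that("degenerate parameters recover planted cores exactly", {
    cfg <- syntheticConfig(seed = 3, nGenes = 60, nTerms = 6, nGroups = 2,
                           coreSize = 10, pIn = 1, pBg = 0, rMax = 1,
                           fracFlagY = 1, fracMeshMissing = 0)
    sim <- simulateGadRecords(cfg)
    rec <- filterRecords(sim$records)
    expect_equal(nrow(rec), nrow(sim$records))   # no noise at all
    summ <- countCooccurrences(rec, "by_term")
    gsc <- buildGeneSets(summ)
    for (lab in setLabels(gsc)) {
        g <- sim$truth$termGroup[[lab]]
        expect_setequal(members(gsc[[lab]]), sim$truth$coreGenes[[g]])
    }
})

test_that("flag and annotation noise behave as configured", {
    ## no positive flags -> filtering leaves nothing
    cfg0 <- syntheticConfig(seed = 5, nGenes = 60, nTerms = 6,
                            nGroups = 2, coreSize = 10, fracFlagY = 0)
    sim0 <- simulateGadRecords(cfg0)
    expect_equal(nrow(filterRecords(sim0$records)), 0)
    ## default composition approximates the configured fractions
    cfg <- syntheticConfig(seed = 7)
    sim <- simulateGadRecords(cfg)
    tab <- table(sim$records$association)
    total <- nrow(sim$records)
    expect_equal(unname(tab["Y"]) / total, cfg$fracFlagY,
                 tolerance = 0.02)
    expect_equal(sum(!nzchar(sim$records$term)) / total,
                 cfg$fracMeshMissing, tolerance = 0.02)
    ## the Y stratum is exactly the planted, annotated records
    rec <- filterRecords(sim$records)
    expect_equal(nrow(rec), sum(sim$records$association == "Y"))
})

test_that("the generator is deterministic under its seed", {
    a <- simulateGadRecords(syntheticConfig(seed = 11))
    b <- simulateGadRecords(syntheticConfig(seed = 11))
    expect_identical(a, b)
    c <- simulateGadRecords(syntheticConfig(seed = 12))
    expect_false(identical(a$records, c$records))
    ## generation does not disturb the caller's RNG stream
    set.seed(99); before <- runif(3)
    set.seed(99); invisible(simulateGadRecords(syntheticConfig(seed = 1)))
    expect_identical(runif(3), before)
})

test_that("infeasible core pools are rejected", {
    expect_error(syntheticConfig(nGenes = 50, nGroups = 5, coreSize = 20),
                 "infeasible")
})

test_that("MGI-style outputs parse and carry the planted structure", {
    cfg <- syntheticConfig(seed = 13, nGenes = 60, nTerms = 10,
                           nGroups = 2, coreSize = 10, pIn = 1, pBg = 0)
    mgi <- simulateMgiFiles(cfg)
    obo <- withr::local_tempfile(fileext = ".obo")
    rpt <- withr::local_tempfile(fileext = ".tsv")
    writeLines(mgi$oboText, obo)
    utils::write.table(mgi$report, rpt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mp <- readMousePhenotypes(obo, rpt)
    ## 10 leaf terms + 2 class parents + root
    expect_equal(length(mp$ontology), 13)
    expect_equal(nrow(mp$unresolved), 0)
    ## leaf terms point at their class, classes at the root
    leaf <- mp$ontology[[names(mgi$truth$termGroup)[1]]]
    expect_length(leaf$parent_codes, 1)
    ## degenerate parameters: per-term gene sets equal the cores
    s <- annotateMousePhenotypes(mp$annotations, mp$ontology)
    byTerm <- split(s$key, s$counterpart)
    for (code in names(mgi$truth$termGroup)) {
        nm <- mgi$truth$termName[[code]]
        g <- mgi$truth$termGroup[[code]]
        expect_setequal(byTerm[[nm]], mgi$truth$coreGenes[[g]])
    }
})

test_that("ortholog map coverage scales the shared-gene table", {
    cfg <- syntheticConfig(seed = 17, nGenes = 80, nTerms = 8,
                           nGroups = 2, coreSize = 15, pIn = 1, pBg = 0,
                           rMax = 1, fracFlagY = 1, fracMeshMissing = 0)
    expect_equal(nrow(simulateOrthologMap(cfg, coverage = 0)), 0)
    full <- simulateOrthologMap(cfg, coverage = 1)
    expect_equal(nrow(full), cfg$nGenes)

    sim <- simulateGadRecords(cfg)
    mgi <- simulateMgiFiles(cfg)
    h <- countCooccurrences(filterRecords(sim$records), "by_gene")
    obo <- withr::local_tempfile(); writeLines(mgi$oboText, obo)
    ont <- readOBO(obo)
    ann <- data.frame(mouse_gene_symbol = mgi$report$gene_symbol,
                      mp_code = mgi$report$mp_code,
                      stringsAsFactors = FALSE)
    m <- annotateMousePhenotypes(ann, ont)
    half <- simulateOrthologMap(cfg, coverage = 0.5)
    tab <- sharedGeneTable(h, m, half)
    ## expected rows: mapped mouse genes annotated on both sides;
    ## with pIn=1, pBg=0 both species cover exactly the core genes
    idx <- attr(half, "mappedIdx")
    coreIdx <- seq_len(cfg$nGroups * cfg$coreSize)
    expect_equal(nrow(tab), length(intersect(idx, coreIdx)))
})

test_that("writeSimulation emits a parseable input bundle", {
    dir <- withr::local_tempdir()
    out <- writeSimulation(syntheticConfig(seed = 19, nGenes = 60,
                                           nTerms = 6, nGroups = 2,
                                           coreSize = 10),
                           dir, coverage = 0.8)
    expect_true(all(file.exists(file.path(dir,
        c("records.tsv", "mouse.obo", "phenogeno.tsv",
          "orthologs.tsv")))))
    rec <- readAssociationTable(file.path(dir, "records.tsv"))
    expect_equal(nrow(rec), nrow(out$gad$records))
    mp <- readMousePhenotypes(file.path(dir, "mouse.obo"),
                              file.path(dir, "phenogeno.tsv"))
    expect_equal(nrow(mp$unresolved), 0)
    orth <- readOrthologTable(file.path(dir, "orthologs.tsv"))
    expect_equal(nrow(orth), 48)
})
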