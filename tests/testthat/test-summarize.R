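mkRecords <- function(gene, term, flag, pub = NULL) {
    if (is.null(pub)) pub <- sprintf("p%02d", seq_along(gene))
    data.frame(gene_symbol = gene, gene_id = NA_integer_, term = term,
               disease_class = "C", association = flag,
               publication_id = pub, stringsAsFactors = FALSE)
}

test_that("filtering keeps exactly positive, annotated records in order", {
    rec <- mkRecords(c("g1", "g1", "g2", "g3"),
                     c("t1", "t1", "", "t2"),
                     c("Y", "N", "Y", "UNKNOWN"))
    out <- filterRecords(rec)
    expect_equal(nrow(out), 1)
    expect_equal(out$gene_symbol, "g1")
    expect_equal(filterRecords(rec[0, ]), rec[0, ], ignore_attr = TRUE)
    allY <- mkRecords(c("a", "b"), c("t", "t"), c("Y", "Y"))
    expect_equal(filterRecords(allY), allY)
    ## idempotence
    expect_equal(filterRecords(filterRecords(rec)), filterRecords(rec))
})

test_that("co-occurrence counting by gene, by term, and tie ordering", {
    rec <- mkRecords(c("APOE", "APOE", "APOE"),
                     c("AD", "AD", "CHD"), rep("Y", 3))
    byGene <- countCooccurrences(rec, "by_gene")
    expect_equal(byGene$key, rep("APOE", 2))
    expect_equal(byGene$counterpart, c("AD", "CHD"))
    expect_equal(byGene$count, c(2L, 1L))
    byTerm <- countCooccurrences(rec, "by_term")
    expect_equal(byTerm$key, c("AD", "CHD"))
    expect_equal(byTerm$count, c(2L, 1L))
    ## ties broken alphabetically by counterpart
    tie <- countCooccurrences(
        mkRecords(c("g1", "g1"), c("tB", "tA"), c("Y", "Y")), "by_gene")
    expect_equal(tie$counterpart, c("tA", "tB"))
    ## lowercase human symbols are normalized to uppercase
    up <- countCooccurrences(mkRecords("apoe", "AD", "Y"), "by_gene")
    expect_equal(up$key, "APOE")
})

test_that("unfiltered records are rejected by the counter", {
    expect_error(countCooccurrences(mkRecords("g", "t", "N"), "by_gene"),
                 "filtered")
    expect_error(countCooccurrences(mkRecords("g", "", "Y"), "by_gene"),
                 "filtered")
})

test_that("publication-level deduplication is optional and off by default", {
    rec <- mkRecords(c("g1", "g1", "g1"), rep("t1", 3),
                     rep("Y", 3), pub = c("p1", "p1", "p2"))
    expect_equal(countCooccurrences(rec, "by_gene")$count, 3L)
    expect_equal(countCooccurrences(rec, "by_gene",
                                    dedupByPublication = TRUE)$count, 2L)
})

test_that("duality and conservation hold on random record tables", {
    for (seed in 1:25) {
        rec <- filterRecords(randomRecordTable(seed))
        g <- countCooccurrences(rec, "by_gene")
        t <- countCooccurrences(rec, "by_term")
        trip_g <- g[order(g$key, g$counterpart), ]
        trip_t <- t[order(t$counterpart, t$key), ]
        expect_equal(trip_g$key, trip_t$counterpart)
        expect_equal(trip_g$counterpart, trip_t$key)
        expect_equal(trip_g$count, trip_t$count)
        expect_equal(sum(g$count), nrow(rec))
        expect_equal(sum(t$count), nrow(rec))
    }
})

test_that("mouse annotations map codes to term names with multiplicities", {
    ont <- list(
        "MP:0001392" = list(mp_code = "MP:0001392", name = "tremors",
                            parent_codes = character()),
        "MP:0001262" = list(mp_code = "MP:0001262",
                            name = "decreased body weight",
                            parent_codes = character()))
    ann <- data.frame(mouse_gene_symbol = c("Abca2", "Abca2", "Apoe",
                                            "Apoe"),
                      mp_code = c("MP:0001392", "MP:0001262",
                                  "MP:0001392", "MP:0001392"),
                      allele_id = NA, publication_id = NA,
                      stringsAsFactors = FALSE)
    s <- annotateMousePhenotypes(ann, ont)
    expect_equal(summaryAxis(s), "by_gene")
    abca2 <- s[s$key == "Abca2", ]
    expect_setequal(abca2$counterpart, c("tremors", "decreased body weight"))
    expect_equal(abca2$count, c(1L, 1L))
    expect_equal(s[s$key == "Apoe", "count"], 2L)   # same code twice
    expect_equal(nrow(annotateMousePhenotypes(ann[0, ], ont)), 0)
    expect_error(annotateMousePhenotypes(
        data.frame(mouse_gene_symbol = "X", mp_code = "MP:9999999"),
        ont), "unresolved")
})

test_that("summary tables round-trip through write/read", {
    rec <- filterRecords(randomRecordTable(3))
    s <- countCooccurrences(rec, "by_term")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSummaryTable(s, path)
    expect_equal(readSummaryTable(path, axis = "by_term"), s)
})
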