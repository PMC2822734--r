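#' Map mouse gene symbols to human orthologs
#'
#' Resolves a set of mouse symbols through an ortholog pair table.
#' Many-to-many mappings are preserved: one mouse symbol may map to
#' several human symbols and vice versa.
#'
#' @param mouseGenes character vector of mouse symbols.
#' @param pairs ortholog pair data.frame (see [readOrthologTable()]).
#'
#' @return a list with \code{map} (named list: mouse symbol -> character
#'   vector of human symbols; only mapped genes appear) and
#'   \code{unmapped} (character vector of mouse genes absent from the
#'   table).
#' @export
mapOrthologs <- function(mouseGenes, pairs) {
    mouseGenes <- unique(as.character(mouseGenes))
    hit <- pairs[pairs$mouse_symbol %in% mouseGenes, , drop = FALSE]
    map <- lapply(split(hit$human_symbol, hit$mouse_symbol), unique)
    list(map = map,
         unmapped = setdiff(mouseGenes, names(map)))
}

#' Human-mouse shared-gene phenotype table
#'
#' Joins a by-gene human disease summary and a by-gene mouse phenotype
#' summary through an ortholog map, producing one row per (mouse gene,
#' human ortholog) pair for which *both* species carry at least one
#' summary entry.  Each row lists the human disease terms with their
#' co-occurrence counts (descending) and the mouse phenotype term names,
#' enabling side-by-side reading of human association evidence and mouse
#' mutant phenotypes for the same gene.
#'
#' @param humanSummaries by-gene summary of human association records
#'   (see [countCooccurrences()]); keys are uppercase human symbols.
#' @param mouseSummaries by-gene summary of mouse annotations
#'   (see [annotateMousePhenotypes()]).
#' @param pairs ortholog pair data.frame.
#' @param caseFallback also match a mouse gene to the human gene whose
#'   symbol is its uppercase form when the pair table does not cover it;
#'   off by default because symbol coincidence is error-prone.
#'
#' @return a data.frame with columns \code{mouse_symbol},
#'   \code{human_symbol}, \code{human_term_entries} (semicolon-joined
#'   \code{"term(count)"}, count-descending) and
#'   \code{mouse_phenotype_terms} (semicolon-joined names); one row per
#'   shared (mouse, human) pair.
#' @export
sharedGeneTable <- function(humanSummaries, mouseSummaries, pairs,
                            caseFallback = FALSE) {
    for (s in list(humanSummaries, mouseSummaries))
        if (!is.null(summaryAxis(s)) && summaryAxis(s) != "by_gene")
            stop("sharedGeneTable needs by_gene summaries")
    humanGenes <- unique(humanSummaries$key)
    mouseGenes <- unique(mouseSummaries$key)
    use <- pairs
    if (caseFallback) {
        extra <- data.frame(mouse_symbol = mouseGenes,
                            human_symbol = toupper(mouseGenes),
                            stringsAsFactors = FALSE)
        extra <- extra[!extra$mouse_symbol %in% pairs$mouse_symbol, ,
                       drop = FALSE]
        use <- unique(rbind(pairs[c("mouse_symbol", "human_symbol")],
                            extra))
    }
    orth <- mapOrthologs(mouseGenes, use)$map
    rows <- list()
    for (mg in names(orth)) {
        for (hg in intersect(orth[[mg]], humanGenes)) {
            h <- humanSummaries[humanSummaries$key == hg, , drop = FALSE]
            m <- mouseSummaries[mouseSummaries$key == mg, , drop = FALSE]
            rows[[length(rows) + 1L]] <- data.frame(
                mouse_symbol = mg,
                human_symbol = hg,
                human_term_entries = paste0(h$counterpart, "(", h$count,
                                            ")", collapse = ";"),
                mouse_phenotype_terms = paste(m$counterpart,
                                              collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(mouse_symbol = character(),
                          human_symbol = character(),
                          human_term_entries = character(),
                          mouse_phenotype_terms = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$mouse_symbol, out$human_symbol), , drop = FALSE]
    rownames(out) <- NULL
    out
}
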