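## Co-occurrence summaries: for each gene, how many records pair it with
## each disease term (and the transpose, per term).  A summary is a long
## data.frame (key, counterpart, count) sorted by count descending within
## key, alphabetical among ties; the axis travels as an attribute.

.newSummary <- function(key, counterpart, count, axis) {
    df <- data.frame(key = as.character(key),
                     counterpart = as.character(counterpart),
                     count = as.integer(count),
                     stringsAsFactors = FALSE)
    df <- df[order(df$key, -df$count, df$counterpart), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "axis") <- axis
    df
}

#' Axis of a co-occurrence summary
#'
#' @param summary a summary data.frame from [countCooccurrences()] or
#'   [annotateMousePhenotypes()].
#' @return \code{"by_gene"} or \code{"by_term"}.
#' @export
summaryAxis <- function(summary) attr(summary, "axis")

#' Keep only positively associated, MeSH-annotated records
#'
#' The working subset of an association table: records whose flag is
#' \code{Y} and whose disease term is non-empty.  Input order is preserved
#' and the operation is idempotent.
#'
#' @param records association data.frame (see [readAssociationTable()]).
#' @return the retained rows, original order.
#' @export
filterRecords <- function(records) {
    keep <- as.character(records$association) == "Y" & nzchar(records$term)
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Count gene-term co-occurrences in filtered association records
#'
#' Counts how many records pair each gene with each disease term.  Each
#' record contributes 1 to its (gene, term) count even when the same
#' publication reports the pair repeatedly; set \code{dedupByPublication}
#' to count each (publication, gene, term) triple once.  The two axes are
#' exact transposes of one another: they contain identical
#' (gene, term, count) triples.
#'
#' @param records a *filtered* association data.frame
#'   (see [filterRecords()]); any record with a non-Y flag or an empty term
#'   is an error.
#' @param axis \code{"by_gene"} (keys are gene symbols, counterparts are
#'   terms, sorted by count within gene) or \code{"by_term"} (the
#'   transpose).
#' @param dedupByPublication collapse repeated (publication, gene, term)
#'   records to one before counting; default off.
#'
#' @return a data.frame \code{(key, counterpart, count)}, sorted by
#'   descending count within key, ties alphabetical; axis retrievable with
#'   [summaryAxis()].  Human gene symbols are uppercased.
#'
#' @examples
#' rec <- data.frame(gene_symbol = c("APOE", "APOE", "APOE"),
#'                   gene_id = NA_integer_,
#'                   term = c("Alzheimer Disease", "Alzheimer Disease",
#'                            "Coronary Heart Disease"),
#'                   disease_class = "x", association = "Y",
#'                   publication_id = c("p1", "p2", "p3"))
#' countCooccurrences(rec, "by_gene")
#' @export
countCooccurrences <- function(records, axis = c("by_gene", "by_term"),
                               dedupByPublication = FALSE) {
    axis <- match.arg(axis)
    if (nrow(records)) {
        if (any(as.character(records$association) != "Y" |
                !nzchar(records$term)))
            stop("records must be filtered to positive + annotated first",
                 " (see filterRecords)")
    }
    if (!nrow(records))
        return(.newSummary(character(), character(), integer(), axis))
    gene <- toupper(records$gene_symbol)
    term <- records$term
    if (dedupByPublication) {
        keep <- !duplicated(paste(records$publication_id, gene, term,
                                  sep = "\r"))
        gene <- gene[keep]; term <- term[keep]
    }
    agg <- stats::aggregate(list(count = rep(1L, length(gene))),
                            by = list(gene = gene, term = term), FUN = sum)
    if (axis == "by_gene")
        .newSummary(agg$gene, agg$term, agg$count, axis)
    else
        .newSummary(agg$term, agg$gene, agg$count, axis)
}

#' Summarize mouse phenotype annotations per gene
#'
#' Maps each gene's MP codes to phenotype term names through the ontology
#' and counts annotation multiplicity.  Unlike the human association
#' counts, mouse multiplicities carry no publication-replication meaning
#' and are structural only.
#'
#' @param annotations annotation data.frame from [readMousePhenotypes()];
#'   every code must resolve in \code{ontology}.
#' @param ontology named code-to-term list from [readOBO()].
#'
#' @return a by-gene summary data.frame \code{(key, counterpart, count)}
#'   whose counterparts are phenotype term *names*; mouse symbols keep
#'   their original case.
#'
#' @export
annotateMousePhenotypes <- function(annotations, ontology) {
    if (!nrow(annotations))
        return(.newSummary(character(), character(), integer(), "by_gene"))
    unresolved <- setdiff(annotations$mp_code, names(ontology))
    if (length(unresolved))
        stop("unresolved MP code(s): ",
             paste(utils::head(unresolved, 5), collapse = ", "))
    name <- vapply(ontology[annotations$mp_code], `[[`, character(1), "name")
    agg <- stats::aggregate(
        list(count = rep(1L, nrow(annotations))),
        by = list(gene = annotations$mouse_gene_symbol, term = name),
        FUN = sum)
    .newSummary(agg$gene, agg$term, agg$count, "by_gene")
}

#' Write a co-occurrence summary table
#'
#' @param summary summary data.frame.
#' @param path output path.
#' @param delim delimiter, default tab.
#' @return invisibly, \code{path}.
#' @export
writeSummaryTable <- function(summary, path, delim = "\t") {
    utils::write.table(summary, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a co-occurrence summary table written by [writeSummaryTable()]
#'
#' @param path input path.
#' @param axis the axis the table was computed under.
#' @param delim delimiter, default tab.
#' @return summary data.frame with the axis attribute restored.
#' @export
readSummaryTable <- function(path, axis = c("by_gene", "by_term"),
                             delim = "\t") {
    axis <- match.arg(axis)
    df <- utils::read.delim(path, sep = delim, header = TRUE,
                            colClasses = c("character", "character",
                                           "integer"),
                            check.names = FALSE, quote = "",
                            na.strings = NULL)
    .newSummary(df$key, df$counterpart, df$count, axis)
}
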