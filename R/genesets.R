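#' Build disease/phenotype gene sets from a by-term summary
#'
#' One candidate set per term: the genes whose co-occurrence count with the
#' term reaches \code{minCount}.  Candidates with fewer than \code{minSize}
#' genes are dropped.  The default \code{minCount = 1} admits any positive
#' association, including single-report genes; replication-weighted sets
#' are obtained by raising it.
#'
#' @param summaries a \code{by_term} summary data.frame
#'   (see [countCooccurrences()]).
#' @param minSize minimum number of genes a set must reach to be kept
#'   (>= 1); 3 and 10 are the conventional working thresholds for
#'   dendrogram-scale and clustering-scale analyses.
#' @param minCount minimum per-gene co-occurrence count for membership
#'   (>= 1).
#'
#' @return a [GeneSetCollection-class], one set per retained term, in the
#'   summary's key order.
#'
#' @export
buildGeneSets <- function(summaries, minSize = 1L, minCount = 1L) {
    stopifnot(minSize >= 1L, minCount >= 1L)
    if (!is.null(summaryAxis(summaries)) &&
        summaryAxis(summaries) != "by_term")
        stop("buildGeneSets needs a by_term summary")
    keep <- summaries$count >= minCount
    df <- summaries[keep, , drop = FALSE]
    sets <- lapply(split(df$counterpart, df$key), unique)
    sets <- sets[order(match(names(sets), summaries$key))]
    sets <- sets[lengths(sets) >= minSize]
    geneSetCollection(mapply(geneSet, names(sets), sets,
                             SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

#' Venn region counts for two or three gene sets
#'
#' Partitions the union of 2 or 3 sets into its disjoint Venn regions
#' (3 regions for a pair, 7 for a triple) and counts the genes in each.
#' Region names join the labels of the containing sets with \code{"&"}.
#'
#' @param sets a list of 2 or 3 [GeneSet-class] objects, or a
#'   [GeneSetCollection-class] of that length.
#'
#' @return a named integer vector over all disjoint regions; the counts
#'   sum to the size of the union.
#'
#' @examples
#' vennRegions(list(geneSet("A", c("1", "2", "3")),
#'                  geneSet("B", c("2", "3", "4"))))
#' @export
vennRegions <- function(sets) {
    if (is(sets, "GeneSetCollection")) sets <- sets@sets
    if (length(sets) < 2L || length(sets) > 3L)
        stop("Venn region counting supports 2 or 3 sets, got ",
             length(sets))
    labs <- vapply(sets, setLabel, character(1))
    univ <- unique(unlist(lapply(sets, members), use.names = FALSE))
    inset <- vapply(sets, function(s) univ %in% members(s),
                    logical(length(univ)))
    inset <- matrix(inset, nrow = length(univ))
    k <- length(sets)
    masks <- lapply(seq_len(2^k - 1L), function(m)
        as.logical(bitwAnd(m, 2^(seq_len(k) - 1L))))
    counts <- vapply(masks, function(sig)
        sum(apply(inset, 1L, function(row) all(row == sig))),
        integer(1))
    names(counts) <- vapply(masks, function(sig)
        paste(labs[sig], collapse = "&"), character(1))
    counts
}

#' Project a gene set onto an annotation collection
#'
#' Lifts a gene set to the annotation (e.g. pathway) level: the result's
#' "members" are the labels of annotation sets sharing at least
#' \code{minShared} genes with the input.  Projected sets can then be
#' compared with [vennRegions()] to ask whether disorders that share few
#' genes still share pathways.  The shared-gene threshold is an explicit
#' stand-in for an enrichment cutoff; no enrichment statistic is computed.
#'
#' @param set a [GeneSet-class].
#' @param annotations a non-empty [GeneSetCollection-class] mapping labels
#'   (pathways) to gene memberships, e.g. read with [readGMT()].
#' @param minShared minimum number of shared genes for an annotation label
#'   to be included (default 1).
#'
#' @return a [GeneSet-class] with the same label whose members are
#'   annotation labels.
#'
#' @export
projectToAnnotations <- function(set, annotations, minShared = 1L) {
    stopifnot(is(set, "GeneSet"), is(annotations, "GeneSetCollection"))
    if (length(annotations) == 0L)
        stop("annotation collection is empty")
    hit <- vapply(annotations@sets, function(a)
        length(intersect(members(set), members(a))) >= minShared,
        logical(1))
    geneSet(setLabel(set), setLabels(annotations)[hit])
}
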