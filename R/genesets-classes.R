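#' Construct a GeneSet
#'
#' @param label single non-empty string naming the set (a disease or
#'   phenotype term).
#' @param members character vector of gene symbols; duplicates are removed,
#'   first occurrence kept.
#' @param x a \code{GeneSet}.
#'
#' @return \code{geneSet()} returns a [GeneSet-class]; \code{setLabel()} its
#'   label; \code{members()} its (unique) member symbols; \code{length()}
#'   the set size.
#'
#' @examples
#' gs <- geneSet("Hypertension", c("ACE", "AGT", "NOS3"))
#' setLabel(gs)
#' length(gs)
#' @export
geneSet <- function(label, members) {
    new("GeneSet", label = as.character(label),
        members = unique(as.character(members)))
}

#' @rdname geneSet
#' @export
setMethod("setLabel", "GeneSet", function(x) x@label)

#' @rdname geneSet
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname geneSet
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet \"", object@label, "\" (", length(object@members),
        " genes)\n", sep = "")
    n <- length(object@members)
    shown <- utils::head(object@members, 6L)
    cat("  ", paste(shown, collapse = ", "),
        if (n > 6L) ", ..." else "", "\n", sep = "")
})

#' Construct a GeneSetCollection
#'
#' @param sets a list of [GeneSet-class] objects with unique labels.
#' @param x a \code{GeneSetCollection}.
#' @param i index or label.
#'
#' @return \code{geneSetCollection()} returns a [GeneSetCollection-class];
#'   \code{setLabels()} the ordered labels; \code{geneUniverse()} the sorted
#'   union of all members; \code{length()} the number of sets; \code{[[}
#'   extracts one [GeneSet-class] by position or label.
#'
#' @examples
#' gsc <- geneSetCollection(list(
#'   geneSet("A", c("g1", "g2")),
#'   geneSet("B", c("g2", "g3"))
#' ))
#' setLabels(gsc)
#' geneUniverse(gsc)
#' @export
geneSetCollection <- function(sets = list()) {
    new("GeneSetCollection", sets = sets)
}

#' @rdname geneSetCollection
#' @export
setMethod("setLabels", "GeneSetCollection", function(x)
    vapply(x@sets, setLabel, character(1)))

#' @rdname geneSetCollection
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x)
    sort(unique(unlist(lapply(x@sets, members), use.names = FALSE))))

#' @rdname geneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname geneSetCollection
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) {
        j <- match(i, setLabels(x))
        if (is.na(j)) stop("no gene set labeled '", i, "'")
        i <- j
    }
    x@sets[[i]]
})

setMethod("show", "GeneSetCollection", function(object) {
    n <- length(object@sets)
    cat("GeneSetCollection with ", n, " set",
        if (n == 1L) "" else "s", ", ",
        length(geneUniverse(object)), " genes in universe\n", sep = "")
    if (n) {
        sizes <- vapply(object@sets, length, integer(1))
        shown <- utils::head(seq_len(n), 5L)
        for (i in shown)
            cat("  ", setLabels(object)[i], " (", sizes[i], ")\n", sep = "")
        if (n > 5L) cat("  ...\n")
    }
})
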