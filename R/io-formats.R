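## Readers/writers for every external format the pipeline touches.
## All tables are delimiter-separated text with a header row; columns are
## addressed by name, never by position, so column order is free.

.ASSOC_COLUMNS <- c("gene_symbol", "gene_id", "term", "disease_class",
                    "association", "publication_id")

#' Read a GAD-style association record table
#'
#' Each row is one published gene-disease association record: a gene symbol,
#' an optional numeric gene id, a MeSH disease term (possibly empty = no
#' annotation), a broad disease class, a Y/N association flag (empty =
#' unknown) and a publication identifier.  MeSH terms routinely contain
#' commas and parentheses, hence the tab-delimited default.
#'
#' @param path path to a delimited text file with a header row naming the
#'   six columns \code{gene_symbol}, \code{gene_id}, \code{term},
#'   \code{disease_class}, \code{association}, \code{publication_id}
#'   (any order).
#' @param delim field delimiter, default tab.
#'
#' @return a data.frame with one row per record; \code{association} is a
#'   factor with levels \code{Y}, \code{N}, \code{UNKNOWN} (parsed
#'   case-insensitively; empty cell means unknown); an empty \code{term}
#'   means no MeSH annotation; \code{gene_id} is integer (NA when absent).
#'
#' @seealso [filterRecords()], [writeAssociationTable()]
#' @export
readAssociationTable <- function(path, delim = "\t") {
    stopifnot(file.exists(path))
    df <- utils::read.delim(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "", comment.char = "",
                            na.strings = NULL)
    missing <- setdiff(.ASSOC_COLUMNS, names(df))
    if (length(missing))
        stop("association table is missing mandatory column(s): ",
             paste(missing, collapse = ", "))
    df <- df[.ASSOC_COLUMNS]
    flag <- toupper(trimws(df$association))
    bad <- which(!flag %in% c("Y", "N", ""))
    if (length(bad))
        stop("unparseable association flag ", sQuote(df$association[bad[1]]),
             " at line ", bad[1] + 1L)  # +1 for the header row
    flag[flag == ""] <- "UNKNOWN"
    data.frame(
        gene_symbol = df$gene_symbol,
        gene_id = suppressWarnings(as.integer(df$gene_id)),
        term = df$term,
        disease_class = df$disease_class,
        association = factor(flag, levels = c("Y", "N", "UNKNOWN")),
        publication_id = df$publication_id,
        stringsAsFactors = FALSE
    )
}

#' Write an association record table
#'
#' Inverse of [readAssociationTable()]; UNKNOWN flags are written as empty
#' cells.
#'
#' @param records data.frame as returned by [readAssociationTable()] or
#'   [simulateGadRecords()].
#' @param path output path.
#' @param delim field delimiter, default tab.
#' @return invisibly, \code{path}.
#' @export
writeAssociationTable <- function(records, path, delim = "\t") {
    out <- records[.ASSOC_COLUMNS]
    out$association <- as.character(out$association)
    out$association[out$association == "UNKNOWN"] <- ""
    out$gene_id <- ifelse(is.na(out$gene_id), "", as.character(out$gene_id))
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read an OBO 1.2 ontology subset
#'
#' Parses \code{[Term]} stanzas, consuming only \code{id}, \code{name} and
#' \code{is_a} tags; everything else in the file is ignored since the
#' pipeline uses the ontology solely to map phenotype codes to term names.
#'
#' @param path path to an OBO file.
#'
#' @return a named list (by code) of ontology terms, each a list with
#'   \code{mp_code}, \code{name} and \code{parent_codes} (character vector,
#'   possibly empty).  Parents referencing codes absent from the file are
#'   kept and flagged via the \code{"dangling"} attribute on the result.
#'
#' @export
readOBO <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    starts <- which(trimws(lines) == "[Term]")
    terms <- list()
    for (k in seq_along(starts)) {
        from <- starts[k] + 1L
        to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
        stanza <- trimws(lines[from:to])
        # a stanza ends at the next stanza header of any type
        hdr <- grep("^\\[", stanza)
        if (length(hdr)) stanza <- stanza[seq_len(hdr[1] - 1L)]
        getTag <- function(tag) {
            hit <- grep(paste0("^", tag, ":"), stanza, value = TRUE)
            trimws(sub(paste0("^", tag, ":"), "", hit))
        }
        id <- getTag("id")
        name <- getTag("name")
        if (length(id) != 1L || !nzchar(id) || length(name) != 1L)
            stop("malformed OBO [Term] stanza #", k,
                 ": need exactly one id and one name")
        isa <- getTag("is_a")
        # "MP:0000001 ! mammalian phenotype" -> code before the comment
        parents <- trimws(sub("!.*$", "", isa))
        parents <- parents[nzchar(parents)]
        if (id %in% names(terms))
            stop("duplicate ontology code ", id, " (stanza #", k, ")")
        terms[[id]] <- list(mp_code = id, name = name,
                            parent_codes = parents)
    }
    all_codes <- names(terms)
    dangling <- unique(unlist(lapply(terms, function(t)
        setdiff(t$parent_codes, all_codes)), use.names = FALSE))
    attr(terms, "dangling") <- dangling
    terms
}

#' Read mouse phenotype annotations together with their ontology
#'
#' Loads an MP-style ontology and a gene-phenotype report, returning the
#' code-to-term map, the annotation rows, and the annotations whose code
#' does not resolve in the ontology.  The report schema is configurable
#' because MGI-style \code{.rpt} files vary: columns are addressed by name.
#'
#' @param oboPath path to the ontology file (see [readOBO()]).
#' @param phenogenoPath path to a delimited gene-phenotype report with a
#'   header row.
#' @param geneColumn,codeColumn,alleleColumn,pubColumn column names in the
#'   report holding the mouse gene symbol, the MP code, and (optionally,
#'   \code{NULL} to skip) the allele and publication ids.
#' @param delim field delimiter, default tab.
#'
#' @return a list with \code{ontology} (named list from [readOBO()]),
#'   \code{annotations} (data.frame: \code{mouse_gene_symbol},
#'   \code{mp_code}, \code{allele_id}, \code{publication_id}) restricted to
#'   resolvable codes, and \code{unresolved} (data.frame of the remaining
#'   rows).
#'
#' @export
readMousePhenotypes <- function(oboPath, phenogenoPath,
                                geneColumn = "gene_symbol",
                                codeColumn = "mp_code",
                                alleleColumn = NULL,
                                pubColumn = NULL,
                                delim = "\t") {
    ontology <- readOBO(oboPath)
    df <- utils::read.delim(phenogenoPath, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "", comment.char = "", na.strings = NULL)
    for (col in c(geneColumn, codeColumn))
        if (!col %in% names(df))
            stop("phenotype report is missing column ", sQuote(col))
    ann <- data.frame(
        mouse_gene_symbol = df[[geneColumn]],
        mp_code = df[[codeColumn]],
        allele_id = if (!is.null(alleleColumn)) df[[alleleColumn]]
                    else NA_character_,
        publication_id = if (!is.null(pubColumn)) df[[pubColumn]]
                         else NA_character_,
        stringsAsFactors = FALSE
    )
    if (any(!nzchar(ann$mouse_gene_symbol)))
        stop("phenotype report contains empty gene symbols")
    bad_code <- !grepl("^MP:[0-9]+$", ann$mp_code)
    if (any(bad_code))
        stop("syntactically invalid MP code ",
             sQuote(ann$mp_code[which(bad_code)[1]]))
    ok <- ann$mp_code %in% names(ontology)
    list(ontology = ontology,
         annotations = ann[ok, , drop = FALSE],
         unresolved = ann[!ok, , drop = FALSE])
}

#' Read and write GMT gene-set collections
#'
#' The GMT format stores one gene set per line: label, description, then
#' the member symbols, all tab-separated.  Writing then reading a
#' collection is lossless: labels, member sets and their order are
#' preserved.
#'
#' @param collection a [GeneSetCollection-class]; labels must not contain
#'   tab characters.
#' @param path file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to \code{"na"}).
#'
#' @return \code{readGMT()} returns a [GeneSetCollection-class];
#'   \code{writeGMT()} invisibly returns \code{path}.
#'
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
    stopifnot(is(collection, "GeneSetCollection"))
    labs <- setLabels(collection)
    if (any(grepl("\t", labs)))
        stop("gene-set labels must not contain tab characters")
    if (is.null(descriptions)) descriptions <- rep("na", length(labs))
    lines <- vapply(seq_along(labs), function(i)
        paste(c(labs[i], descriptions[i],
                members(collection[[i]])), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1], " has fewer than 3 fields")
    labs <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(labs))
        stop("duplicate gene-set labels in GMT file: ",
             paste(unique(labs[duplicated(labs)]), collapse = ", "))
    sets <- lapply(fields, function(f) geneSet(f[1], f[-(1:2)]))
    geneSetCollection(sets)
}

## Stable 10-character PHYLIP tokens: sanitized label prefix + zero-padded
## index guarantees uniqueness regardless of label collisions.
.phylipTokens <- function(labs) {
    stub <- gsub("[^A-Za-z0-9]", "_", labs)
    sprintf("%-6.6s%04d", stub, seq_along(labs))
}

#' Write and read square PHYLIP distance matrices
#'
#' Writes the classic square PHYLIP format: a first line with the taxon
#' count, then one row per taxon starting with a 10-character name token.
#' Disease and phenotype term labels routinely exceed PHYLIP's 10-character
#' limit, so full labels always go to a sidecar name-map file (token TAB
#' label) and the matrix carries stable unique tokens.
#'
#' @param matrix a [SetDistanceMatrix-class] (symmetric, zero diagonal,
#'   unique labels).
#' @param path matrix file path.
#' @param nameMapPath sidecar name-map path; default \code{path + ".names"}.
#'   When reading, pass \code{NULL} to keep the raw tokens as labels.
#' @param digits significant digits written, default 10.
#'
#' @return \code{readPhylipMatrix()} returns a [SetDistanceMatrix-class]
#'   equal to the written one within 1e-9; \code{writePhylipMatrix()}
#'   invisibly returns \code{path}.
#'
#' @export
writePhylipMatrix <- function(matrix, path,
                              nameMapPath = paste0(path, ".names"),
                              digits = 10) {
    stopifnot(is(matrix, "SetDistanceMatrix"))
    v <- as.matrix(matrix)
    labs <- rownames(v)
    tokens <- .phylipTokens(labs)
    rows <- vapply(seq_along(labs), function(i)
        paste(c(tokens[i],
                formatC(v[i, ], digits = digits, format = "g")),
              collapse = "  "),
        character(1))
    writeLines(c(format(length(labs)), rows), path)
    if (!is.null(nameMapPath))
        writeLines(paste(tokens, labs, sep = "\t"), nameMapPath)
    invisible(path)
}

#' @rdname writePhylipMatrix
#' @export
readPhylipMatrix <- function(path, nameMapPath = paste0(path, ".names")) {
    stopifnot(file.exists(path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1]))
    if (is.na(n) || length(lines) - 1L != n)
        stop("PHYLIP matrix declares ", trimws(lines[1]), " taxa but has ",
             length(lines) - 1L, " rows")
    parts <- strsplit(trimws(lines[-1]), "[[:space:]]+")
    if (any(lengths(parts) != n + 1L))
        stop("PHYLIP matrix rows must have 1 label + ", n, " values")
    tokens <- vapply(parts, `[[`, character(1), 1L)
    v <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    labs <- tokens
    if (!is.null(nameMapPath) && file.exists(nameMapPath)) {
        nm <- utils::read.delim(nameMapPath, header = FALSE, sep = "\t",
                                colClasses = "character", quote = "")
        labs <- nm[[2]][match(tokens, nm[[1]])]
        if (anyNA(labs))
            stop("name map does not cover all matrix tokens")
    }
    v <- (v + t(v)) / 2  # absorb last-digit rounding from text serialization
    diag(v) <- 0
    dimnames(v) <- list(labs, labs)
    new("SetDistanceMatrix", values = v)
}

#' Write a tree in Newick format with fixed-precision branch lengths
#'
#' Serializes an \code{ape} \code{phylo} tree with branch lengths printed
#' at exactly 6 decimal places, so that replicate outputs are
#' byte-comparable.  Negative branch lengths (legal Neighbor-Joining
#' output) are written verbatim with a warning.
#'
#' @param tree an \code{ape::phylo} object; every tip must be labeled and
#'   every edge must carry a finite length.
#' @param path output path; \code{NULL} returns the Newick string instead.
#'
#' @return invisibly, the Newick string.
#' @seealso [readNewick()]
#' @export
writeNewick <- function(tree, path = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
        !all(nzchar(tree$tip.label)))
        stop("every leaf must be labeled")
    if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
        stop("every branch must carry a finite length")
    if (any(tree$edge.length < 0))
        warning("tree contains negative branch lengths; written verbatim")
    ntip <- length(tree$tip.label)
    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    quoteLab <- function(x) {
        needs <- grepl("[^A-Za-z0-9_.|-]", x)
        x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
        x
    }
    deparse_node <- function(node) {
        if (node <= ntip) return(quoteLab(tree$tip.label[node]))
        kid_edges <- children[[as.character(node)]]
        subs <- vapply(kid_edges, function(e)
            sprintf("%s:%.6f", deparse_node(tree$edge[e, 2]),
                    tree$edge.length[e]),
            character(1))
        paste0("(", paste(subs, collapse = ","), ")")
    }
    root <- ntip + 1L
    s <- paste0(deparse_node(root), ";")
    if (!is.null(path)) writeLines(s, path)
    invisible(s)
}

#' Read a Newick tree
#'
#' Thin wrapper over \code{ape::read.tree}; the inverse of
#' [writeNewick()] (topology and branch lengths round-trip within 1e-6).
#'
#' @param path path to a Newick file.
#' @return an \code{ape::phylo} object.
#' @export
readNewick <- function(path) {
    stopifnot(file.exists(path))
    tree <- ape::read.tree(path)
    ## ape keeps surrounding single quotes on quoted labels; strip them
    ## and undo the '' escaping so quoted round trips are lossless
    q <- grepl("^'.*'$", tree$tip.label)
    tree$tip.label[q] <- gsub("''", "'",
                              sub("^'(.*)'$", "\\1", tree$tip.label[q]))
    tree
}

#' Read a two-column mouse-to-human ortholog table
#'
#' @param path path to a delimited file with a header row and columns
#'   \code{mouse_symbol} and \code{human_symbol} (any order; extra columns
#'   ignored).
#' @param delim field delimiter, default tab.
#'
#' @return a data.frame of deduplicated (mouse_symbol, human_symbol) pairs
#'   with original case preserved; rows with an empty cell are skipped and
#'   their count reported via \code{message()} and the \code{"skipped"}
#'   attribute.  Many-to-many mappings are preserved.
#'
#' @export
readOrthologTable <- function(path, delim = "\t") {
    stopifnot(file.exists(path))
    df <- utils::read.delim(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "", na.strings = NULL)
    for (col in c("mouse_symbol", "human_symbol"))
        if (!col %in% names(df))
            stop("ortholog table is missing column ", sQuote(col))
    df <- df[c("mouse_symbol", "human_symbol")]
    empty <- !nzchar(df$mouse_symbol) | !nzchar(df$human_symbol)
    if (any(empty))
        message("skipped ", sum(empty), " ortholog row(s) with empty cells")
    df <- unique(df[!empty, , drop = FALSE])
    rownames(df) <- NULL
    attr(df, "skipped") <- sum(empty)
    df
}
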