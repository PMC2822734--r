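## Synthetic GAD-like and MGI-like inputs with planted disease-group
## structure.  K groups own disjoint core gene pools; each disease term
## draws its group's core genes with probability pIn and every other gene
## with probability pBg, so same-group terms share many genes and
## cross-group terms share few.  Known ground truth makes every pipeline
## stage testable without database downloads.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv)
            else if (exists(".Random.seed", envir = .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    expr
}

#' Configuration of the synthetic association-record generator
#'
#' Defaults define the small working preset: 5 disease groups of 8 terms
#' each, 30-gene disjoint cores in a 300-gene universe, a 60% chance that
#' a term carries each of its group's core genes and a 2% chance for any
#' other gene.  Replication counts per (gene, term) pair follow a
#' truncated Zipf law (exponent 1.5, max 70), mimicking the heavy-tailed
#' replication pattern of curated association counts, where a few
#' associations are reported dozens of times and most exactly once.
#' Flag/annotation noise defaults echo the gross composition of a
#' GAD-style dump, where roughly 26% of records are positively flagged
#' and MeSH-annotated and some 29% carry any Y/N flag at all.
#'
#' @param seed integer; fixes all randomness end-to-end.
#' @param nGenes size of the gene universe.
#' @param nTerms number of disease terms (assigned to groups round-robin).
#' @param nGroups number K of planted disease groups.
#' @param coreSize genes per group core; \code{nGroups * coreSize} must
#'   not exceed \code{nGenes}.
#' @param pIn probability a term draws each core gene of its group.
#' @param pBg probability a term draws any other gene.
#' @param countLaw Zipf exponent for per-pair replication counts.
#' @param rMax truncation of the replication-count law; 1 forces single
#'   records.
#' @param fracFlagY fraction of all emitted records flagged Y (the
#'   planted, annotated stratum); 0 flips the planted records to N.
#' @param fracFlagN fraction of all records flagged N.
#' @param fracMeshMissing fraction of all records with an empty MeSH term.
#' @param nClasses number of broad disease classes labels are drawn from.
#'
#' @return a list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(seed = 1L, nGenes = 300L, nTerms = 40L,
                            nGroups = 5L, coreSize = 30L,
                            pIn = 0.6, pBg = 0.02,
                            countLaw = 1.5, rMax = 70L,
                            fracFlagY = 0.26, fracFlagN = 0.03,
                            fracMeshMissing = 0.03,
                            nClasses = nGroups) {
    fracFlagN <- min(fracFlagN, 1 - fracFlagY)  # Y stratum takes priority
    stopifnot(pIn >= 0, pIn <= 1, pBg >= 0, pBg <= 1,
              fracFlagY >= 0, fracFlagY <= 1, fracFlagN >= 0,
              fracMeshMissing >= 0, fracMeshMissing <= 1,
              nGroups <= nTerms, rMax >= 1)
    if (nGroups * coreSize > nGenes)
        stop("infeasible config: nGroups * coreSize exceeds nGenes")
    structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                   nTerms = as.integer(nTerms),
                   nGroups = as.integer(nGroups),
                   coreSize = as.integer(coreSize),
                   pIn = pIn, pBg = pBg, countLaw = countLaw,
                   rMax = as.integer(rMax),
                   fracFlagY = fracFlagY, fracFlagN = fracFlagN,
                   fracMeshMissing = fracMeshMissing,
                   nClasses = as.integer(nClasses)),
              class = "syntheticConfig")
}

.zipfSample <- function(n, s, rMax) {
    if (rMax == 1L || n == 0L) return(rep(1L, n))
    sample.int(rMax, n, replace = TRUE, prob = (1:rMax)^(-s))
}

.humanGenes <- function(cfg) sprintf("GENE%04d", seq_len(cfg$nGenes))
.mouseGenes <- function(cfg) sprintf("Gene%04d", seq_len(cfg$nGenes))
.termGroups <- function(cfg) ((seq_len(cfg$nTerms) - 1L) %% cfg$nGroups) + 1L

## per-term planted members, shared by the GAD and MGI generators
.plantMembers <- function(cfg, genes) {
    groups <- .termGroups(cfg)
    cores <- split(genes[seq_len(cfg$nGroups * cfg$coreSize)],
                   rep(seq_len(cfg$nGroups), each = cfg$coreSize))
    lapply(seq_len(cfg$nTerms), function(t) {
        core <- cores[[groups[t]]]
        other <- setdiff(genes, core)
        c(core[stats::runif(length(core)) < cfg$pIn],
          other[stats::runif(length(other)) < cfg$pBg])
    })
}

#' Simulate a GAD-style association record table with planted structure
#'
#' Emits the planted (gene, term) pairs as positively flagged, annotated
#' records replicated per the Zipf count law, then appends noise records
#' (unannotated Y, N-flagged, unflagged) so the table's gross composition
#' matches the configured fractions and [filterRecords()] has real work.
#' The planted structure is exactly the Y + annotated stratum.  The row
#' order is shuffled; everything is deterministic under the seed.
#'
#' @param config a [syntheticConfig()].
#'
#' @return a list with \code{records} (association data.frame, see
#'   [readAssociationTable()]) and \code{truth}: \code{termGroup} (named
#'   integer vector term -> planted group), \code{coreGenes} (list of
#'   per-group core symbol vectors) and \code{termMembers} (list of the
#'   genes actually planted per term).
#' @export
simulateGadRecords <- function(config) {
    cfg <- config
    .withSeed(cfg$seed, {
        genes <- .humanGenes(cfg)
        groups <- .termGroups(cfg)
        terms <- sprintf("Synthetic Disease %02d (group %d)",
                         seq_len(cfg$nTerms), groups)
        classes <- sprintf("CLASS_%02d",
                           ((groups - 1L) %% cfg$nClasses) + 1L)
        memb <- .plantMembers(cfg, genes)
        pairs <- data.frame(
            gene = unlist(memb, use.names = FALSE),
            term = rep(terms, lengths(memb)),
            cls = rep(classes, lengths(memb)),
            stringsAsFactors = FALSE)
        reps <- .zipfSample(nrow(pairs), cfg$countLaw, cfg$rMax)
        sig <- pairs[rep(seq_len(nrow(pairs)), reps), , drop = FALSE]
        S <- nrow(sig)
        records <- data.frame(
            gene_symbol = sig$gene,
            gene_id = match(sig$gene, genes),
            term = sig$term,
            disease_class = sig$cls,
            association = "Y",
            publication_id = "",
            stringsAsFactors = FALSE)
        if (cfg$fracFlagY == 0) {
            records$association <- "N"
        } else if (cfg$fracFlagY < 1) {
            total <- round(S / cfg$fracFlagY)
            nNoise <- max(total - S, 0L)
            nN <- min(nNoise, round(total * cfg$fracFlagN))
            nEmpty <- min(nNoise, round(total * cfg$fracMeshMissing))
            noise <- data.frame(
                gene_symbol = sample(genes, nNoise, replace = TRUE),
                gene_id = NA_integer_,
                term = sample(terms, nNoise, replace = TRUE),
                disease_class = sample(classes, nNoise, replace = TRUE),
                association = rep(c("N", "UNKNOWN"),
                                  c(nN, nNoise - nN)),
                publication_id = "",
                stringsAsFactors = FALSE)
            if (nEmpty > 0 && nNoise > 0)
                noise$term[sample(nNoise, nEmpty)] <- ""
            noise$gene_id <- match(noise$gene_symbol, genes)
            records <- rbind(records, noise)
        }
        records <- records[sample(nrow(records)), , drop = FALSE]
        records$publication_id <- sprintf("PMID%06d",
                                          seq_len(nrow(records)))
        records$association <- factor(records$association,
                                      levels = c("Y", "N", "UNKNOWN"))
        rownames(records) <- NULL
        cores <- split(genes[seq_len(cfg$nGroups * cfg$coreSize)],
                       rep(seq_len(cfg$nGroups), each = cfg$coreSize))
        list(records = records,
             truth = list(
                 termGroup = stats::setNames(groups, terms),
                 coreGenes = cores,
                 termMembers = stats::setNames(
                     lapply(memb, unique), terms)))
    })
}

#' Simulate MGI-style mouse phenotype inputs with planted structure
#'
#' Generates a Mammalian-Phenotype-style ontology (a root, one top-level
#' class term per group, and one leaf term per phenotype with an is_a
#' link to its class) together with a gene-phenotype report planted with
#' the same group logic as [simulateGadRecords()], using mouse-cased gene
#' symbols.  Both outputs are parseable by [readOBO()] /
#' [readMousePhenotypes()].
#'
#' @param config a [syntheticConfig()]; the generator derives its own
#'   RNG stream from \code{seed + 1} so GAD and MGI noise differ while
#'   both stay reproducible.
#'
#' @return a list with \code{oboText} (character vector of OBO lines),
#'   \code{report} (data.frame: gene_symbol, mp_code, allele_id,
#'   publication_id) and \code{truth} (\code{termGroup} named by MP leaf
#'   code, \code{termName} code -> name map, \code{coreGenes},
#'   \code{termMembers} named by code).
#' @export
simulateMgiFiles <- function(config) {
    cfg <- config
    .withSeed(cfg$seed + 1L, {
        genes <- .mouseGenes(cfg)
        groups <- .termGroups(cfg)
        rootCode <- "MP:0000001"
        classCodes <- sprintf("MP:%07d", 1L + seq_len(cfg$nGroups))
        leafCodes <- sprintf("MP:%07d", 1000L + seq_len(cfg$nTerms))
        leafNames <- sprintf("synthetic phenotype %02d", seq_len(cfg$nTerms))
        obo <- c("format-version: 1.2", "",
                 "[Term]",
                 paste0("id: ", rootCode),
                 "name: mammalian phenotype", "")
        for (g in seq_len(cfg$nGroups))
            obo <- c(obo, "[Term]",
                     paste0("id: ", classCodes[g]),
                     sprintf("name: synthetic phenotype class %d", g),
                     paste0("is_a: ", rootCode, " ! mammalian phenotype"),
                     "")
        for (t in seq_len(cfg$nTerms))
            obo <- c(obo, "[Term]",
                     paste0("id: ", leafCodes[t]),
                     paste0("name: ", leafNames[t]),
                     paste0("is_a: ", classCodes[groups[t]]),
                     "")
        memb <- .plantMembers(cfg, genes)
        report <- data.frame(
            gene_symbol = unlist(memb, use.names = FALSE),
            mp_code = rep(leafCodes, lengths(memb)),
            allele_id = "",
            publication_id = "",
            stringsAsFactors = FALSE)
        report <- report[sample(nrow(report)), , drop = FALSE]
        report$allele_id <- sprintf("MGI:%06d", seq_len(nrow(report)))
        report$publication_id <- sprintf("J:%06d", seq_len(nrow(report)))
        rownames(report) <- NULL
        cores <- split(genes[seq_len(cfg$nGroups * cfg$coreSize)],
                       rep(seq_len(cfg$nGroups), each = cfg$coreSize))
        list(oboText = obo,
             report = report,
             truth = list(
                 termGroup = stats::setNames(groups, leafCodes),
                 termName = stats::setNames(leafNames, leafCodes),
                 coreGenes = cores,
                 termMembers = stats::setNames(
                     lapply(memb, unique), leafCodes)))
    })
}

#' Simulate a mouse-to-human ortholog map
#'
#' Maps a \code{coverage} fraction of the mouse gene universe to its
#' human counterpart (the uppercased symbol), drawn uniformly at random
#' under the config seed.
#'
#' @param config a [syntheticConfig()].
#' @param coverage fraction of mouse genes mapped, in [0, 1].
#'
#' @return a data.frame \code{(mouse_symbol, human_symbol)}; the mapped
#'   gene indices are retained in the \code{"mappedIdx"} attribute.
#' @export
simulateOrthologMap <- function(config, coverage = 1) {
    stopifnot(coverage >= 0, coverage <= 1)
    cfg <- config
    .withSeed(cfg$seed + 2L, {
        idx <- sort(sample(cfg$nGenes, round(coverage * cfg$nGenes)))
        out <- data.frame(mouse_symbol = .mouseGenes(cfg)[idx],
                          human_symbol = .humanGenes(cfg)[idx],
                          stringsAsFactors = FALSE)
        attr(out, "mappedIdx") <- idx
        out
    })
}

#' Write a complete simulated input bundle to a directory
#'
#' Convenience wrapper producing the files a real analysis would start
#' from: \code{records.tsv}, \code{mouse.obo}, \code{phenogeno.tsv},
#' \code{orthologs.tsv}, plus \code{truth.json} when \pkg{jsonlite} is
#' available.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @param coverage ortholog map coverage.
#' @return invisibly, a list of the generated objects.
#' @export
writeSimulation <- function(config, dir, coverage = 1) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gad <- simulateGadRecords(config)
    mgi <- simulateMgiFiles(config)
    orth <- simulateOrthologMap(config, coverage)
    writeAssociationTable(gad$records, file.path(dir, "records.tsv"))
    writeLines(mgi$oboText, file.path(dir, "mouse.obo"))
    utils::write.table(mgi$report, file.path(dir, "phenogeno.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(orth, file.path(dir, "orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        truth <- list(gad = gad$truth, mgi = mgi$truth,
                      orthologCoverage = coverage,
                      mappedMouse = orth$mouse_symbol)
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE)
    }
    invisible(list(gad = gad, mgi = mgi, orthologs = orth))
}
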