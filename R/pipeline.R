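# End-to-end convenience: annotation files -> classification table.

#' Classify genomes straight from dbCAN-style annotation files
#'
#' Thin end-to-end wrapper: parses each per-genome annotation table, applies
#' the score filters, assembles genes and classifies every genome. File
#' names (or the names of `files`) supply the genome identifiers; genomes
#' whose table holds zero passing hits are reported as `NO_CAZY`.
#'
#' @param files Character vector of annotation table paths, optionally
#'   named by genome identifier.
#' @param catalog A [ModuleCatalog-class] (default [defaultCatalog()]).
#' @param dialect Table dialect, see [readDbcan()].
#' @param maxEvalue,minCoverage,overlapPolicy Filter settings, see
#'   [filterHits()].
#' @param a2RequiresPair,strictAs Rule switches, see [batchClassify()] and
#'   [assignTypes()].
#' @return A list: `classification` ([batchClassify()] table), `summary`
#'   ([groupSummary()]), `genes` (the combined filtered gene table).
#' @export
classifyCorpusFiles <- function(files, catalog = defaultCatalog(),
                                dialect = "hmmscan-parser",
                                maxEvalue = 1e-15, minCoverage = 0.35,
                                overlapPolicy = "best_per_region",
                                a2RequiresPair = TRUE, strictAs = TRUE) {
  if (length(files) == 0) stop("no annotation files supplied", call. = FALSE)
  ids <- names(files)
  if (is.null(ids)) ids <- sub("\\..*$", "", basename(files))
  hits <- do.call(rbind, Map(function(f, id) {
    readDbcan(f, dialect = dialect, genome_id = id)
  }, files, ids))
  hits <- filterHits(hits, maxEvalue = maxEvalue, minCoverage = minCoverage,
                     overlapPolicy = overlapPolicy)
  genes <- buildGenes(hits)
  cls <- batchClassify(genes, catalog, genomeIds = ids,
                       a2RequiresPair = a2RequiresPair, strictAs = strictAs)
  list(classification = cls, summary = groupSummary(cls), genes = genes)
}
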