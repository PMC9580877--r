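# dbCAN-style annotation ingest: table parsing, score filtering, gene
# assembly, per-genome module abundance.

#' Parse a dbCAN-style HMM search result table
#'
#' Two dialects are understood. `"hmmscan-parser"` (the primary one): ten
#' tab-separated columns, no header -- HMM name, HMM length, query name,
#' query length, E-value, HMM start, HMM end, query start, query end,
#' coverage. `"overview"`: first column gene id, one column per annotation
#' tool, family labels joined by `"+"`, each optionally suffixed with an
#' alignment range `"(start-end)"`; E-value and coverage are absent and
#' treated as passing any filter (`e_value = 0`, `hmm_coverage = 1`).
#'
#' Family labels are normalized via [normalizeFamily()] (`".hmm"` stripped,
#' structural-module aliases resolved).
#'
#' @param path Path to the annotation table.
#' @param dialect `"hmmscan-parser"` or `"overview"`.
#' @param genome_id Genome identifier stamped on every hit; defaults to the
#'   file name with extensions removed.
#' @return A ModuleHit data.frame: `family`, `protein_id`, `genome_id`,
#'   `aa_start`, `aa_end`, `e_value`, `hmm_coverage`, plus `aa_length`
#'   (query length; `NA` for the overview dialect).
#' @seealso [filterHits()], [buildGenes()]
#' @export
readDbcan <- function(path, dialect = c("hmmscan-parser", "overview"),
                      genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read annotation table: ", path, call. = FALSE)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\..*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- .emptyHits()
    out$aa_length <- integer()
    return(out)
  }
  if (dialect == "hmmscan-parser") {
    .parseHmmscanParser(lines, genome_id, path)
  } else {
    .parseOverview(lines, genome_id, path)
  }
}

.parseHmmscanParser <- function(lines, genome_id, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10)
  if (length(bad)) {
    stop("malformed row (expected 10 tab-separated columns) at line ",
         bad[1], " of ", path, call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:10))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(v)) {
      stop("unparseable ", what, " at line ", which(is.na(v))[1], " of ",
           path, call. = FALSE)
    }
    v
  }
  ev <- num(5, "E-value")
  cov <- num(10, "coverage")
  st <- as.integer(num(8, "query start"))
  en <- as.integer(num(9, "query end"))
  qlen <- as.integer(num(4, "query length"))
  if (any(ev < 0)) {
    stop("negative E-value at line ", which(ev < 0)[1], " of ", path,
         call. = FALSE)
  }
  if (any(cov < 0 | cov > 1)) {
    stop("coverage outside [0,1] at line ", which(cov < 0 | cov > 1)[1],
         " of ", path, call. = FALSE)
  }
  if (any(st > en)) {
    stop("alignment start > end at line ", which(st > en)[1], " of ", path,
         call. = FALSE)
  }
  data.frame(family = normalizeFamily(mat[, 1]), protein_id = mat[, 3],
             genome_id = genome_id, aa_start = st, aa_end = en,
             e_value = ev, hmm_coverage = cov, aa_length = qlen,
             stringsAsFactors = FALSE)
}

.parseOverview <- function(lines, genome_id, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate (and drop) a header row
  if (grepl("gene", fields[[1]][1], ignore.case = TRUE)) {
    fields <- fields[-1]
  }
  rows <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2) {
      stop("malformed overview row at line ", i, " of ", path, call. = FALSE)
    }
    pid <- f[1]
    anns <- unlist(strsplit(f[-1], "+", fixed = TRUE))
    anns <- trimws(anns)
    anns <- anns[nzchar(anns) & anns != "-" & !grepl("^[0-9]+$", anns)]
    for (a in anns) {
      m <- regmatches(a, regexec("^(.*?)\\(([0-9]+)-([0-9]+)\\)$", a))[[1]]
      if (length(m) == 4) {
        fam <- m[2]; st <- as.integer(m[3]); en <- as.integer(m[4])
      } else {
        fam <- a; st <- NA_integer_; en <- NA_integer_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = normalizeFamily(fam), protein_id = pid,
        genome_id = genome_id, aa_start = st, aa_end = en,
        e_value = 0, hmm_coverage = 1, aa_length = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- .emptyHits()
    out$aa_length <- integer()
    return(out)
  }
  do.call(rbind, rows)
}

#' Filter module hits on E-value, HMM coverage and same-family overlap
#'
#' Retains hits with `e_value <= maxEvalue` and `hmm_coverage >=
#' minCoverage`. Under the `"best_per_region"` policy, among same-protein
#' same-family hits whose residue intervals overlap by more than half of the
#' shorter interval, only the lowest-E-value hit survives (ties broken by
#' smaller `aa_start`). The defaults mirror the HMM cutoffs commonly
#' recommended for dbCAN-style annotation and are fully configurable.
#' Filtering is idempotent.
#'
#' @param hits ModuleHit data.frame.
#' @param maxEvalue Maximum E-value retained (default `1e-15`).
#' @param minCoverage Minimum HMM coverage retained (default `0.35`).
#' @param overlapPolicy `"best_per_region"` (default) or `"keep_all"`.
#' @return The filtered ModuleHit data.frame.
#' @export
filterHits <- function(hits, maxEvalue = 1e-15, minCoverage = 0.35,
                       overlapPolicy = c("best_per_region", "keep_all")) {
  overlapPolicy <- match.arg(overlapPolicy)
  .checkHitFrame(hits)
  stopifnot(maxEvalue > 0, minCoverage >= 0, minCoverage <= 1)
  keep <- (is.na(hits$e_value) | hits$e_value <= maxEvalue) &
    (is.na(hits$hmm_coverage) | hits$hmm_coverage >= minCoverage)
  hits <- hits[keep, , drop = FALSE]
  if (overlapPolicy == "keep_all" || nrow(hits) == 0) {
    rownames(hits) <- NULL
    return(hits)
  }
  grp <- paste(hits$genome_id, hits$protein_id, hits$family, sep = "\r")
  keepIdx <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(ix) {
    if (length(ix) == 1) return(ix)
    # greedy: consider hits best-first, drop any that overlaps a kept one
    ord <- ix[order(hits$e_value[ix], hits$aa_start[ix])]
    kept <- integer()
    for (i in ord) {
      clash <- FALSE
      for (j in kept) {
        ov <- min(hits$aa_end[i], hits$aa_end[j]) -
          max(hits$aa_start[i], hits$aa_start[j]) + 1L
        shorter <- min(hits$aa_end[i] - hits$aa_start[i] + 1L,
                       hits$aa_end[j] - hits$aa_start[j] + 1L)
        if (!is.na(ov) && ov > shorter / 2) { clash <- TRUE; break }
      }
      if (!clash) kept <- c(kept, i)
    }
    kept
  }), use.names = FALSE)
  out <- hits[sort(keepIdx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble filtered hits into per-gene module architectures
#'
#' Groups hits by `(genome_id, protein_id)` and sorts each gene's hits by
#' `aa_start`, yielding the gene's ordered module architecture. Protein
#' lengths are attached from `proteins` when supplied (overriding any
#' `aa_length` already on the hits); a hit whose coordinates exceed the
#' protein length is a validation error. Genes with zero hits are simply not
#' present in the output. The result is independent of the input hit order.
#'
#' @param hits Filtered ModuleHit data.frame.
#' @param proteins Optional protein-record data.frame ([parseGenBank()] /
#'   [readFaa()]) supplying `aa_length` per `(genome_id, protein_id)`.
#' @return A gene table: the hit columns plus `aa_length`, sorted by
#'   `genome_id`, `protein_id`, `aa_start`.
#' @export
buildGenes <- function(hits, proteins = NULL) {
  .checkHitFrame(hits)
  if (!"aa_length" %in% names(hits)) hits$aa_length <- NA_integer_
  if (!is.null(proteins)) {
    key <- paste(proteins$genome_id, proteins$protein_id, sep = "\r")
    len <- stats::setNames(proteins$aa_length, key)
    hk <- .geneKey(hits)
    got <- hk %in% names(len)
    hits$aa_length[got] <- unname(len[hk[got]])
  }
  bad <- which(!is.na(hits$aa_length) & !is.na(hits$aa_end) &
                 hits$aa_end > hits$aa_length)
  if (length(bad)) {
    b <- bad[1]
    stop("hit ", hits$family[b], " on ", hits$genome_id[b], "/",
         hits$protein_id[b], " ends at residue ", hits$aa_end[b],
         " beyond protein length ", hits$aa_length[b], call. = FALSE)
  }
  bad <- which(!is.na(hits$aa_start) & hits$aa_start < 1)
  if (length(bad)) {
    stop("hit ", hits$family[bad[1]], " on ", hits$protein_id[bad[1]],
         " starts before residue 1", call. = FALSE)
  }
  ord <- order(hits$genome_id, hits$protein_id, hits$aa_start, hits$aa_end,
               hits$family)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genome CAZy module abundance
#'
#' Counts module *occurrences* per genome: a family appearing twice in one
#' gene counts twice. Genomes with zero hits are absent from the result, and
#' the grand total over genomes equals the number of input hits.
#'
#' @param genes Gene table ([buildGenes()]) or any ModuleHit data.frame.
#' @return A named list, one element per genome: a named integer vector of
#'   occurrence counts by family label.
#' @export
moduleAbundance <- function(genes) {
  .checkHitFrame(genes)
  if (nrow(genes) == 0) return(stats::setNames(list(), character()))
  lapply(split(genes$family, genes$genome_id), function(f) {
    tab <- table(f)
    stats::setNames(as.integer(tab), names(tab))
  })
}
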