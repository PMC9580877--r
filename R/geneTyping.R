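# Gene typing: per-gene role counts and the eight carbohydrate-active gene
# types.
#
# Types, over the count vector (n_slh, n_dockerin, n_cohesin, n_cgh, n_ccbm):
#   A1   scaffoldin anchored by SLH      : slh>=1 & doc==0 & coh>=3
#   A2-a scaffoldin with a dockerin tail : doc>=1 & coh>=3
#   A2-b SLH carrier for the A2-a pair   : slh>=1 & coh>=1
#   A3   free scaffoldin (no SLH route)  : slh==0 & doc==0 & coh>=3
#   A-s  cellulosomal catalytic component: doc>=1 & cgh>=1
#   B    SLH-cCBM cell-adhesion gene     : slh>=1 & ccbm>=1
#   C    cellulose-binding cellulase     : cgh>=1 & ccbm>=1
#   D    free cellulase (solitary cGH)   : cgh>=1 & ccbm==0
# Scaffold precedence A1 > A2-a > A2-b > A3 keeps only the highest scaffold
# label; non-scaffold labels stay multi-label. primary_type is the first
# satisfied label in the order A1, A2-a, A2-b, A3, A-s, B, C, D.

.geneTypeOrder <- c("A1", "A2-a", "A2-b", "A3", "A-s", "B", "C", "D")
.scaffoldTypes <- c("A1", "A2-a", "A2-b", "A3")
.cellulosomalTypes <- c("A1", "A2-a", "A2-b", "A3", "A-s")

#' Count role-tallied module occurrences for one gene
#'
#' @param geneHits ModuleHit data.frame for a single gene (all rows share
#'   one `protein_id`).
#' @param catalog A [ModuleCatalog-class].
#' @return One-row data.frame: `protein_id`, `genome_id`, `n_slh`,
#'   `n_dockerin`, `n_cohesin`, `n_cgh`, `n_ccbm`. Families with no catalog
#'   role contribute nothing.
#' @seealso [assignTypes()], [geneTypeProfiles()]
#' @export
profileGene <- function(geneHits, catalog) {
  .checkHitFrame(geneHits, "geneHits")
  if (nrow(geneHits) == 0) stop("profileGene needs >=1 hit", call. = FALSE)
  if (length(unique(geneHits$protein_id)) != 1) {
    stop("profileGene expects hits of a single gene", call. = FALSE)
  }
  geneTypeProfiles(geneHits, catalog, assign = FALSE)
}

#' Per-gene role counts for a whole gene table
#'
#' Vectorized form of [profileGene()]: one output row per
#' `(genome_id, protein_id)` gene, with [assignTypes()] applied unless
#' `assign = FALSE`.
#'
#' @param genes Gene table ([buildGenes()]).
#' @param catalog A [ModuleCatalog-class].
#' @param assign Assign types after counting? Default `TRUE`.
#' @param strictAs Passed to [assignTypes()].
#' @return A GeneTypeProfile data.frame.
#' @export
geneTypeProfiles <- function(genes, catalog, assign = TRUE, strictAs = TRUE) {
  .checkHitFrame(genes, "genes")
  stopifnot(is(catalog, "ModuleCatalog"))
  if (nrow(genes) == 0) {
    prof <- data.frame(protein_id = character(), genome_id = character(),
                       n_slh = integer(), n_dockerin = integer(),
                       n_cohesin = integer(), n_cgh = integer(),
                       n_ccbm = integer(), stringsAsFactors = FALSE)
    return(if (assign) assignTypes(prof, strictAs = strictAs) else prof)
  }
  fam <- parentFamily(normalizeFamily(genes$family))
  cgh <- cghFamilies(catalog)
  ccbm <- ccbmFamilies(catalog)
  key <- .geneKey(genes)
  ukey <- !duplicated(key)
  ksplit <- factor(key, levels = unique(key))
  countBy <- function(flag) {
    as.integer(rowsum(as.integer(flag), ksplit)[, 1])
  }
  prof <- data.frame(
    protein_id = genes$protein_id[ukey],
    genome_id = genes$genome_id[ukey],
    n_slh = countBy(fam == "SLH"),
    n_dockerin = countBy(fam == "dockerin"),
    n_cohesin = countBy(fam == "cohesin"),
    n_cgh = countBy(fam %in% cgh),
    n_ccbm = countBy(fam %in% ccbm),
    stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  if (assign) assignTypes(prof, strictAs = strictAs) else prof
}

#' Assign gene types from role counts
#'
#' Evaluates the eight type predicates on each profile row, applies the
#' scaffold precedence ladder (A1 > A2-a > A2-b > A3), and sets the primary
#' type. Non-scaffold labels are retained multi-label, so a gene can satisfy
#' e.g. both A-s and D; C and D are mutually exclusive by construction
#' (cCBM present vs absent).
#'
#' @param profiles GeneTypeProfile data.frame with the five count columns
#'   (`n_slh`, `n_dockerin`, `n_cohesin`, `n_cgh`, `n_ccbm`).
#' @param strictAs Use the strict A-s predicate `doc>=1 & cgh>=1` (default).
#'   With `FALSE`, the looser reading `doc>=1 & (cgh>=1 | ccbm>=1)` is used,
#'   which also admits dockerin-borne carbohydrate-binding components.
#' @return `profiles` with columns `satisfied_types` (comma-joined, ordered)
#'   and `primary_type` (`NA` when no type is satisfied) appended.
#' @export
assignTypes <- function(profiles, strictAs = TRUE) {
  need <- c("n_slh", "n_dockerin", "n_cohesin", "n_cgh", "n_ccbm")
  if (!all(need %in% names(profiles))) {
    stop("profiles must carry count columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  slh <- profiles$n_slh; doc <- profiles$n_dockerin
  coh <- profiles$n_cohesin; cgh <- profiles$n_cgh; ccbm <- profiles$n_ccbm
  sat <- cbind(
    "A1" = slh >= 1 & doc == 0 & coh >= 3,
    "A2-a" = doc >= 1 & coh >= 3,
    "A2-b" = slh >= 1 & coh >= 1,
    "A3" = slh == 0 & doc == 0 & coh >= 3,
    "A-s" = if (strictAs) doc >= 1 & cgh >= 1
            else doc >= 1 & (cgh >= 1 | ccbm >= 1),
    "B" = slh >= 1 & ccbm >= 1,
    "C" = cgh >= 1 & ccbm >= 1,
    "D" = cgh >= 1 & ccbm == 0)
  sat <- matrix(sat, ncol = 8,
                dimnames = list(NULL, c("A1", "A2-a", "A2-b", "A3", "A-s",
                                        "B", "C", "D")))
  # scaffold precedence: keep only the highest satisfied scaffold label
  top <- vapply(seq_len(nrow(sat)), function(i) {
    r <- sat[i, .scaffoldTypes]
    if (any(r)) which(r)[1] else NA_integer_
  }, integer(1))
  for (j in seq_along(.scaffoldTypes)) {
    drop <- !is.na(top) & top < j
    sat[drop, .scaffoldTypes[j]] <- FALSE
  }
  labs <- colnames(sat)
  profiles$satisfied_types <- vapply(seq_len(nrow(sat)), function(i) {
    paste(labs[sat[i, ]], collapse = ",")
  }, character(1))
  profiles$primary_type <- vapply(seq_len(nrow(sat)), function(i) {
    r <- sat[i, ]
    if (any(r)) labs[which(r)[1]] else NA_character_
  }, character(1))
  profiles
}

#' Write / read a gene-type report
#'
#' One row per gene: genome and protein ids, the five role counts, the
#' comma-joined satisfied types, and the primary type. Plain TSV with a
#' header; `readReport()` re-ingests any report written by `writeReport()`
#' losslessly.
#'
#' @param df Any report data.frame.
#' @param path TSV path.
#' @return `writeReport()`: the path, invisibly. `readReport()`: the
#'   data.frame.
#' @export
writeReport <- function(df, path) {
  stopifnot(is.data.frame(df))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("cannot read report: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
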