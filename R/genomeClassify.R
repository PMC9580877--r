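# Genome-level genotype classification.
#
# Decision flow over a genome's gene-type tallies and module roles:
#   0. no CAZy module at all                      -> NO_CAZY
#   1. exo- and endoglucanase roles not both seen -> II
#   2. adhering scaffold (A1, or the A2-a/A2-b pair) -> I-a
#   3. free scaffold (A3, or unpaired A2-a):
#        SLH-cCBM gene present -> I-b, else -> I-c
#   4. SLH-cCBM gene present                      -> I-d
#   5. cGH-cCBM gene present                      -> I-e
#   6. otherwise                                  -> I-f
# Gene counts are primary-type tallies, so a gene whose primary type is
# cellulosomal (A1/A2-a/A2-b/A3/A-s) never inflates the B/C/D columns.

.groupLevels <- c("I-a", "I-b", "I-c", "I-d", "I-e", "I-f", "II", "NO_CAZY")

#' Summarize one genome's gene-type profile
#'
#' Tallies genes by primary type and derives `has_exo` / `has_endo` (at
#' least one occurrence of a family carrying the respective role anywhere in
#' the genome) from the module abundance under the catalog.
#'
#' @param profiles GeneTypeProfile data.frame for one genome (output of
#'   [geneTypeProfiles()]); may have zero rows.
#' @param abundance Named integer vector of module occurrence counts for the
#'   genome (one element of [moduleAbundance()]'s result).
#' @param catalog A [ModuleCatalog-class].
#' @param genome_id Required when `profiles` has zero rows.
#' @return A one-row GenomeProfile data.frame: `genome_id`, `n_A1`, `n_A2a`,
#'   `n_A2b`, `n_A3`, `n_As`, `n_B`, `n_C`, `n_D`, `has_exo`, `has_endo`,
#'   `n_modules`.
#' @export
summarizeGenome <- function(profiles, abundance, catalog, genome_id = NULL) {
  stopifnot(is(catalog, "ModuleCatalog"))
  if (nrow(profiles) > 0) {
    gid <- unique(profiles$genome_id)
    if (length(gid) != 1) {
      stop("summarizeGenome expects profiles of a single genome; got: ",
           paste(gid, collapse = ", "), call. = FALSE)
    }
    genome_id <- gid
  } else if (is.null(genome_id)) {
    stop("genome_id required when profiles is empty", call. = FALSE)
  }
  if (!"primary_type" %in% names(profiles) && nrow(profiles) > 0) {
    profiles <- assignTypes(profiles)
  }
  cnt <- function(type) sum(profiles$primary_type %in% type)
  fam <- parentFamily(normalizeFamily(names(abundance)))
  abn <- as.integer(abundance)
  hasRole <- function(set) any(abn[fam %in% set] >= 1)
  data.frame(
    genome_id = genome_id,
    n_A1 = cnt("A1"), n_A2a = cnt("A2-a"), n_A2b = cnt("A2-b"),
    n_A3 = cnt("A3"), n_As = cnt("A-s"), n_B = cnt("B"),
    n_C = cnt("C"), n_D = cnt("D"),
    has_exo = hasRole(exoGH(catalog)),
    has_endo = hasRole(endoGH(catalog)),
    n_modules = sum(abn),
    stringsAsFactors = FALSE)
}

#' Does a genome carry an adhering (cell-anchorable) scaffold?
#'
#' True iff an A1 scaffoldin is present, or the A2-a/A2-b pair is: a
#' dockerin-tailed scaffoldin (A2-a) can only acquire the cell-anchoring SLH
#' module when an A2-b partner supplies it through a cohesin, so by default
#' an unpaired A2-a counts as a free scaffold (`a2RequiresPair = FALSE`
#' treats any A2-a as adhering).
#'
#' @param profile One-row GenomeProfile data.frame ([summarizeGenome()]).
#' @param a2RequiresPair Require the A2-a/A2-b pair (default `TRUE`).
#' @return Logical scalar.
#' @export
hasAdheringScaffold <- function(profile, a2RequiresPair = TRUE) {
  profile$n_A1 >= 1 ||
    (profile$n_A2a >= 1 && (profile$n_A2b >= 1 || !a2RequiresPair))
}

.classifyOne <- function(profile, a2RequiresPair = TRUE) {
  if (profile$n_modules == 0) {
    return(list(group = "NO_CAZY", path = "no CAZy annotation"))
  }
  if (!(profile$has_exo && profile$has_endo)) {
    return(list(group = "II", path = "exo+endo absent"))
  }
  path <- "exo+endo"
  if (hasAdheringScaffold(profile, a2RequiresPair)) {
    return(list(group = "I-a", path = paste(path, "adhering scaffold",
                                            sep = " > ")))
  }
  freeScaffold <- profile$n_A3 >= 1 ||
    (a2RequiresPair && profile$n_A2a >= 1)
  if (freeScaffold) {
    path <- paste(path, "free scaffold", sep = " > ")
    if (profile$n_B >= 1) {
      return(list(group = "I-b", path = paste(path, "SLH-cCBM gene",
                                              sep = " > ")))
    }
    return(list(group = "I-c", path = paste(path, "no SLH-cCBM gene",
                                            sep = " > ")))
  }
  path <- paste(path, "no scaffold", sep = " > ")
  if (profile$n_B >= 1) {
    return(list(group = "I-d", path = paste(path, "SLH-cCBM gene",
                                            sep = " > ")))
  }
  if (profile$n_C >= 1) {
    return(list(group = "I-e", path = paste(path, "cGH-cCBM gene",
                                            sep = " > ")))
  }
  list(group = "I-f", path = paste(path, "solitary cGH only", sep = " > "))
}

#' Classify one genome into a cellulolytic genotype group
#'
#' @param profile One-row GenomeProfile data.frame ([summarizeGenome()]).
#' @param a2RequiresPair See [hasAdheringScaffold()].
#' @return A length-1 character group label: one of `I-a` .. `I-f`, `II`,
#'   `NO_CAZY`.
#' @seealso [batchClassify()]
#' @export
classifyGenome <- function(profile, a2RequiresPair = TRUE) {
  .classifyOne(profile, a2RequiresPair)$group
}

#' Classify a corpus of genomes
#'
#' Runs the full per-genome summary and classification over a gene table.
#' Genomes listed in `genomeIds` but absent from the annotation (zero hits)
#' are reported as `NO_CAZY`, so a batch over N genomes always yields N rows.
#'
#' @param genes Gene table ([buildGenes()]).
#' @param catalog A [ModuleCatalog-class].
#' @param genomeIds Optional character vector of all genome identifiers in
#'   the corpus (to surface annotation-free genomes).
#' @param a2RequiresPair See [hasAdheringScaffold()].
#' @param strictAs See [assignTypes()].
#' @return A data.frame with one row per genome: `genome_id`, `group`, the
#'   eight gene-type counts, `has_exo`, `has_endo`, `n_modules`,
#'   `decision_path`.
#' @export
batchClassify <- function(genes, catalog, genomeIds = NULL,
                          a2RequiresPair = TRUE, strictAs = TRUE) {
  .checkHitFrame(genes, "genes")
  stopifnot(is(catalog, "ModuleCatalog"))
  abund <- moduleAbundance(genes)
  ids <- sort(unique(c(names(abund), genomeIds)))
  if (length(ids) == 0) {
    out <- data.frame(genome_id = character(), group = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  profAll <- if (nrow(genes) > 0) {
    geneTypeProfiles(genes, catalog, strictAs = strictAs)
  } else NULL
  rows <- lapply(ids, function(g) {
    prof <- if (!is.null(profAll)) {
      profAll[profAll$genome_id == g, , drop = FALSE]
    } else {
      geneTypeProfiles(.emptyHits(), catalog)[0, ]
    }
    abn <- if (g %in% names(abund)) abund[[g]] else integer()
    gp <- summarizeGenome(prof, abn, catalog, genome_id = g)
    cls <- .classifyOne(gp, a2RequiresPair)
    gp$group <- cls$group
    gp$decision_path <- cls$path
    gp
  })
  out <- do.call(rbind, rows)
  out <- out[, c("genome_id", "group", "n_A1", "n_A2a", "n_A2b", "n_A3",
                 "n_As", "n_B", "n_C", "n_D", "has_exo", "has_endo",
                 "n_modules", "decision_path")]
  rownames(out) <- NULL
  out
}

#' Per-group membership counts of a classification table
#'
#' @param classification Output of [batchClassify()].
#' @return A data.frame `group`, `n_genomes`, covering all eight labels
#'   (zero-count groups included).
#' @export
groupSummary <- function(classification) {
  tab <- table(factor(classification$group, levels = .groupLevels))
  data.frame(group = names(tab), n_genomes = as.integer(tab),
             stringsAsFactors = FALSE)
}
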