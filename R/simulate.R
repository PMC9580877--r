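# Synthetic annotated genomes with known gene types and genotype groups.
#
# Each genotype group has a blueprint of genes, built bottom-up from the
# type predicates at their minimal counts; surplus material (duplicated
# blueprint genes and decoy modules drawn from families with no catalog
# role) cannot flip a gene's primary type or a genome's group. Generation is
# a pure function of (design, seed): dbCAN-dialect hit tables, a protein
# FASTA and a truth table come out identical on regeneration.

.decoyFamilies <- c("GT2", "GT4", "GH13", "GH23", "CE1", "CE4", "PL1",
                    "CBM50", "CBM48")

# per-group gene blueprints (module label vectors) under the default catalog
.groupBlueprints <- function() {
  list(
    "I-a" = list(c("SLH", "cohesin", "cohesin", "cohesin"),
                 c("dockerin", "GH48"),
                 c("dockerin", "GH5", "CBM3"),
                 c("GH9")),
    "I-b" = list(c("cohesin", "cohesin", "cohesin"),
                 c("SLH", "CBM3"),
                 c("dockerin", "GH48"),
                 c("GH5", "CBM3"),
                 c("GH9")),
    "I-c" = list(c("cohesin", "cohesin", "cohesin"),
                 c("dockerin", "GH48"),
                 c("GH5", "CBM3"),
                 c("GH9")),
    "I-d" = list(c("SLH", "CBM3"),
                 c("GH48", "CBM2"),
                 c("GH5"),
                 c("GH9")),
    "I-e" = list(c("GH48", "CBM3"),
                 c("GH5", "CBM2"),
                 c("GH9")),
    "I-f" = list(c("GH48"),
                 c("GH5")),
    "II" = list(c("GH5", "CBM3"),
                c("GH10"),
                c("GH13")),
    "NO_CAZY" = list())
}

#' Design of a synthetic annotated-genome corpus
#'
#' @param perGroup Named integer vector: genotype group -> number of genomes
#'   to generate. Defaults to three genomes of every group including `II`
#'   and `NO_CAZY`.
#' @param decoyRate Probability that a gene additionally carries one decoy
#'   module from a family with no catalog role (default 0.2).
#' @param seed Integer RNG seed; generation is a pure function of the
#'   design, so equal designs give identical corpora.
#' @param moduleLength Residue length range modules are drawn from.
#' @param geneGap Residue gap range between consecutive modules in a gene.
#' @return A list of class `"CorpusDesign"`.
#' @export
corpusDesign <- function(perGroup = NULL, decoyRate = 0.2, seed = 1,
                         moduleLength = c(60L, 200L), geneGap = c(5L, 25L)) {
  if (is.null(perGroup)) {
    perGroup <- stats::setNames(rep(3L, length(.groupLevels)), .groupLevels)
  }
  bad <- setdiff(names(perGroup), .groupLevels)
  if (length(bad)) {
    stop("unknown genotype group(s) in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(perGroup < 0)) stop("negative genome counts in design", call. = FALSE)
  if (sum(perGroup) == 0) stop("design requests no genomes", call. = FALSE)
  stopifnot(decoyRate >= 0, decoyRate <= 1)
  structure(list(perGroup = perGroup, decoyRate = decoyRate,
                 seed = as.integer(seed),
                 moduleLength = as.integer(moduleLength),
                 geneGap = as.integer(geneGap)),
            class = "CorpusDesign")
}

# build one gene's hits from a module-label vector; returns a hit frame
.buildSyntheticGene <- function(modules, genome_id, protein_id, design) {
  cursor <- sample(seq(design$geneGap[1], design$geneGap[2]), 1L)
  rows <- lapply(modules, function(m) {
    len <- sample(seq(design$moduleLength[1], design$moduleLength[2]), 1L)
    st <- cursor
    en <- cursor + len - 1L
    cursor <<- en + sample(seq(design$geneGap[1], design$geneGap[2]), 1L)
    data.frame(family = m, protein_id = protein_id, genome_id = genome_id,
               aa_start = st, aa_end = en,
               e_value = 10^-stats::runif(1, 20, 50),
               hmm_coverage = round(stats::runif(1, 0.5, 0.98), 3),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$aa_length <- max(df$aa_end) + sample(seq(design$geneGap[1],
                                              design$geneGap[2]), 1L)
  df
}

#' Generate a synthetic annotated corpus with ground-truth labels
#'
#' For every requested genome, emits a per-genome hit table in the dbCAN
#' `"hmmscan-parser"` dialect (family names carry a `".hmm"` suffix, scores
#' pass the default filters), a combined protein FASTA of random amino-acid
#' sequences of consistent lengths, and truth tables recording each genome's
#' intended genotype group and each gene's intended primary type. `NO_CAZY`
#' genomes get an empty hit table (they are present in the FASTA but absent
#' from the annotation).
#'
#' @param design A [corpusDesign()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `dir`, `hitFiles` (named by genome), `faa`,
#'   `truthFile`, `geneTruthFile`, `designFile`, plus in-memory `truth`,
#'   `geneTruth` and `hits` data.frames.
#' @export
generateCorpus <- function(design, dir) {
  stopifnot(inherits(design, "CorpusDesign"))
  catalog <- defaultCatalog()
  bp <- .groupBlueprints()
  if (!"SLH" %in% unlist(bp[["I-a"]])) {
    stop("unsatisfiable design: I-a requires an SLH-bearing scaffold",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(design$seed)

  groups <- names(design$perGroup)[design$perGroup > 0]
  truth <- list(); geneTruth <- list(); allHits <- list()
  hitFiles <- character(); proteins <- list()

  for (grp in groups) {
    for (i in seq_len(design$perGroup[[grp]])) {
      gid <- sprintf("%s_g%02d", gsub("[^A-Za-z]", "", grp), i)
      genes <- bp[[grp]]
      # surplus: duplicate up to two blueprint genes (presence-based
      # classification is unaffected by copy number)
      if (length(genes) > 0) {
        extra <- sample(0:2, 1L)
        if (extra > 0) {
          genes <- c(genes, genes[sample(seq_along(genes), extra,
                                         replace = TRUE)])
        }
      }
      ghits <- list(); gtruth <- list()
      for (j in seq_along(genes)) {
        mods <- genes[[j]]
        if (stats::runif(1) < design$decoyRate) {
          mods <- c(mods, sample(.decoyFamilies, 1L))
        }
        pid <- sprintf("%s_p%03d", gid, j)
        hit <- .buildSyntheticGene(mods, gid, pid, design)
        ghits[[j]] <- hit
        gtruth[[j]] <- data.frame(genome_id = gid, protein_id = pid,
                                  stringsAsFactors = FALSE)
      }
      gh <- if (length(ghits)) do.call(rbind, ghits) else {
        h <- .emptyHits(); h$aa_length <- integer(); h
      }
      # intended primary types, recomputed from the blueprint counts
      if (length(ghits)) {
        gt <- do.call(rbind, gtruth)
        prof <- geneTypeProfiles(gh, catalog)
        gt$intended_type <- prof$primary_type[match(gt$protein_id,
                                                    prof$protein_id)]
      } else {
        gt <- data.frame(genome_id = character(), protein_id = character(),
                         intended_type = character(),
                         stringsAsFactors = FALSE)
      }
      # proteins: every gene, plus two annotation-free proteins per genome
      prot <- data.frame(
        protein_id = c(unique(gh$protein_id),
                       sprintf("%s_x%02d", gid, 1:2)),
        genome_id = gid, stringsAsFactors = FALSE)
      lens <- c(vapply(unique(gh$protein_id), function(p) {
        gh$aa_length[gh$protein_id == p][1]
      }, integer(1) + 0L), sample(120:400, 2L, replace = TRUE))
      prot$aa_length <- as.integer(lens)
      prot$aa_sequence <- vapply(prot$aa_length, function(n) {
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                     replace = TRUE), collapse = "")
      }, character(1))

      f <- file.path(dir, paste0(gid, ".dbcan.tsv"))
      .writeHmmscanParser(gh, f)
      hitFiles[gid] <- f
      truth[[gid]] <- data.frame(genome_id = gid, group = grp,
                                 stringsAsFactors = FALSE)
      geneTruth[[gid]] <- gt
      allHits[[gid]] <- gh
      proteins[[gid]] <- prot
    }
  }

  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  geneTruth <- do.call(rbind, geneTruth); rownames(geneTruth) <- NULL
  hits <- do.call(rbind, allHits); rownames(hits) <- NULL
  prot <- do.call(rbind, proteins); rownames(prot) <- NULL

  faa <- file.path(dir, "proteins.faa")
  writeFaa(prot, faa)
  truthFile <- file.path(dir, "truth.tsv")
  writeReport(truth, truthFile)
  geneTruthFile <- file.path(dir, "gene_truth.tsv")
  writeReport(geneTruth, geneTruthFile)
  designFile <- file.path(dir, "design.yml")
  yaml::write_yaml(list(perGroup = as.list(design$perGroup),
                        decoyRate = design$decoyRate, seed = design$seed,
                        moduleLength = design$moduleLength,
                        geneGap = design$geneGap), designFile)

  invisible(list(dir = dir, hitFiles = hitFiles, faa = faa,
                 truthFile = truthFile, geneTruthFile = geneTruthFile,
                 designFile = designFile, truth = truth,
                 geneTruth = geneTruth, hits = hits, proteins = prot))
}

# write hits in the 10-column hmmscan-parser dialect (".hmm" suffixed names)
.writeHmmscanParser <- function(hits, path) {
  if (nrow(hits) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  len <- hits$aa_end - hits$aa_start + 1L
  rows <- sprintf("%s.hmm\t%d\t%s\t%d\t%s\t%d\t%d\t%d\t%d\t%s",
                  hits$family, len, hits$protein_id, hits$aa_length,
                  format(hits$e_value, scientific = TRUE, digits = 3),
                  1L, len, hits$aa_start, hits$aa_end,
                  formatC(hits$hmm_coverage, digits = 3, format = "f"))
  writeLines(rows, path)
  invisible(path)
}

#' Apply a minimal deterministic edit to a synthetic genome
#'
#' Edits operate on one genome's hit table and produce the documented group
#' transition when reclassified: adding an A1 scaffoldin sends any Group-I
#' genome to I-a; adding an SLH-cCBM (B) gene sends I-c to I-b and I-e to
#' I-d; removing all B genes reverses that; stripping SLH from scaffoldins
#' turns A1 scaffolds into free A3 scaffolds.
#'
#' @param hits ModuleHit data.frame of a single genome.
#' @param edit One of `"add_A1_gene"`, `"add_B_gene"`, `"remove_B_genes"`,
#'   `"strip_slh_from_scaffolds"`.
#' @param catalog Catalog used to locate B genes / scaffolds (default
#'   [defaultCatalog()]).
#' @return The edited hit table.
#' @export
mutateGenome <- function(hits, edit = c("add_A1_gene", "add_B_gene",
                                        "remove_B_genes",
                                        "strip_slh_from_scaffolds"),
                         catalog = defaultCatalog()) {
  edit <- match.arg(edit)
  .checkHitFrame(hits)
  gid <- unique(hits$genome_id)
  if (length(gid) != 1) {
    stop("mutateGenome expects hits of a single genome", call. = FALSE)
  }
  addGene <- function(modules, tag) {
    pid <- paste0(gid, "_", tag)
    n <- length(modules)
    st <- 10L + 110L * (seq_len(n) - 1L)
    df <- data.frame(family = modules, protein_id = pid, genome_id = gid,
                     aa_start = st, aa_end = st + 99L,
                     e_value = 1e-30, hmm_coverage = 0.9,
                     stringsAsFactors = FALSE)
    if ("aa_length" %in% names(hits)) df$aa_length <- max(df$aa_end) + 10L
    rbind(hits, df[, names(hits)])
  }
  if (edit == "add_A1_gene") {
    return(addGene(c("SLH", "cohesin", "cohesin", "cohesin"), "mutA1"))
  }
  if (edit == "add_B_gene") {
    return(addGene(c("SLH", "CBM3"), "mutB"))
  }
  prof <- geneTypeProfiles(hits, catalog)
  if (edit == "remove_B_genes") {
    bGenes <- prof$protein_id[prof$primary_type %in% "B"]
    if (length(bGenes) == 0) {
      stop("edit not applicable: genome ", gid, " has no B genes",
           call. = FALSE)
    }
    out <- hits[!hits$protein_id %in% bGenes, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # strip_slh_from_scaffolds
  scaf <- prof$protein_id[prof$n_cohesin >= 3 & prof$n_slh >= 1]
  if (length(scaf) == 0) {
    stop("edit not applicable: genome ", gid,
         " has no SLH-bearing scaffoldin", call. = FALSE)
  }
  fam <- parentFamily(normalizeFamily(hits$family))
  out <- hits[!(hits$protein_id %in% scaf & fam == "SLH"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
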