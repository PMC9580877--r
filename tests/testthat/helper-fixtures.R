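# Builders for in-code fixtures: module-hit frames and toy GenBank files.

# one gene's hits from a family vector, modules laid end to end
mkGene <- function(families, protein = "p1", genome = "G1",
                   start = 1L, modLen = 100L, gap = 10L,
                   e = 1e-30, cov = 0.9) {
  n <- length(families)
  st <- start + (modLen + gap) * (seq_len(n) - 1L)
  data.frame(family = families, protein_id = protein, genome_id = genome,
             aa_start = st, aa_end = st + modLen - 1L,
             e_value = e, hmm_coverage = cov, stringsAsFactors = FALSE)
}

# several genes in one genome: list of family vectors
mkGenome <- function(geneList, genome = "G1", prefix = "p") {
  do.call(rbind, lapply(seq_along(geneList), function(i) {
    mkGene(geneList[[i]], protein = sprintf("%s%02d", prefix, i),
           genome = genome)
  }))
}

# a syntactically valid single-record GenBank file; cds is a list of lists
# with fields: location, qualifiers (named character vector or list)
writeToyGbk <- function(path, locus = "TOY1", version = "TOY1.1",
                        cds = list(), origin = NULL) {
  wrap <- function(s) paste0("                     ", s)
  lines <- c(
    sprintf("LOCUS       %s              %d bp    DNA     circular BCT 01-JAN-2020",
            locus, if (is.null(origin)) 60L else nchar(origin)),
    "DEFINITION  Toy replicon.",
    sprintf("ACCESSION   %s", locus),
    sprintf("VERSION     %s", version),
    "FEATURES             Location/Qualifiers",
    "     source          1..60")
  for (f in cds) {
    lines <- c(lines, sprintf("     CDS             %s", f$location))
    for (qn in names(f$qualifiers)) {
      qv <- f$qualifiers[[qn]]
      if (isTRUE(qv)) {
        lines <- c(lines, wrap(sprintf("/%s", qn)))
      } else {
        lines <- c(lines, wrap(sprintf('/%s="%s"', qn, qv)))
      }
    }
  }
  if (!is.null(origin)) {
    lines <- c(lines, "ORIGIN")
    pos <- seq(1L, nchar(origin), by = 60L)
    for (p in pos) {
      chunk <- substr(origin, p, min(p + 59L, nchar(origin)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

# independent brute-force evaluator of the eight gene-type predicates plus
# scaffold precedence; deliberately written as plain per-case logic
oracleAssign <- function(slh, doc, coh, cgh, ccbm, strictAs = TRUE) {
  sat <- character()
  if (slh >= 1 && doc == 0 && coh >= 3) sat <- c(sat, "A1")
  if (doc >= 1 && coh >= 3) sat <- c(sat, "A2-a")
  if (slh >= 1 && coh >= 1) sat <- c(sat, "A2-b")
  if (slh == 0 && doc == 0 && coh >= 3) sat <- c(sat, "A3")
  asOk <- if (strictAs) doc >= 1 && cgh >= 1
          else doc >= 1 && (cgh >= 1 || ccbm >= 1)
  if (asOk) sat <- c(sat, "A-s")
  if (slh >= 1 && ccbm >= 1) sat <- c(sat, "B")
  if (cgh >= 1 && ccbm >= 1) sat <- c(sat, "C")
  if (cgh >= 1 && ccbm == 0) sat <- c(sat, "D")
  scaffolds <- c("A1", "A2-a", "A2-b", "A3")
  present <- scaffolds[scaffolds %in% sat]
  if (length(present) > 1) {
    sat <- setdiff(sat, setdiff(present, present[1]))
  }
  order <- c("A1", "A2-a", "A2-b", "A3", "A-s", "B", "C", "D")
  sat <- order[order %in% sat]
  list(satisfied = sat,
       primary = if (length(sat)) sat[1] else NA_character_)
}

# independent row matcher for the genotype decision table: literal rows of
# the published categorization (adhering, free, B, C, D presence -> group)
tableRowMatch <- function(adhering, free, b, c, d) {
  rows <- list(
    list(adh = TRUE,  free = NA,    b = NA,    c = NA,    d = NA,    grp = "I-a"),
    list(adh = FALSE, free = TRUE,  b = TRUE,  c = TRUE,  d = TRUE,  grp = "I-b"),
    list(adh = FALSE, free = TRUE,  b = FALSE, c = TRUE,  d = TRUE,  grp = "I-c"),
    list(adh = FALSE, free = FALSE, b = TRUE,  c = TRUE,  d = TRUE,  grp = "I-d"),
    list(adh = FALSE, free = FALSE, b = TRUE,  c = TRUE,  d = NA,    grp = "I-d"),
    list(adh = FALSE, free = FALSE, b = TRUE,  c = NA,    d = TRUE,  grp = "I-d"),
    list(adh = FALSE, free = FALSE, b = FALSE, c = TRUE,  d = TRUE,  grp = "I-e"),
    list(adh = FALSE, free = FALSE, b = FALSE, c = TRUE,  d = FALSE, grp = "I-e"),
    list(adh = FALSE, free = FALSE, b = FALSE, c = FALSE, d = TRUE,  grp = "I-f"))
  for (r in rows) {
    ok <- (is.na(r$adh) || r$adh == adhering) &&
      (is.na(r$free) || r$free == free) &&
      (is.na(r$b) || r$b == b) &&
      (is.na(r$c) || r$c == c) &&
      (is.na(r$d) || r$d == d)
    if (ok) return(r$grp)
  }
  NA_character_
}

# GenomeProfile row from presence/absence booleans (for decision-tree sweeps)
profileFromFlags <- function(adhering, free, b, c, d, exoEndo = TRUE,
                             anyModules = TRUE) {
  data.frame(genome_id = "G", n_A1 = as.integer(adhering),
             n_A2a = 0L, n_A2b = 0L, n_A3 = as.integer(free),
             n_As = 0L, n_B = as.integer(b), n_C = as.integer(c),
             n_D = as.integer(d), has_exo = exoEndo, has_endo = exoEndo,
             n_modules = as.integer(anyModules), stringsAsFactors = FALSE)
}

# brute-force per-gene-scan co-occurrence tally following the three-step
# recipe: per focal, genes containing it, N = focal occurrences there,
# n_i = partner occurrences there
oracleCooccur <- function(genes, focal) {
  fam <- Cellulotype::parentFamily(Cellulotype::normalizeFamily(genes$family))
  key <- paste(genes$genome_id, genes$protein_id)
  out <- list()
  for (m in focal) {
    N <- 0L
    n <- integer()
    for (k in unique(key)) {
      f <- fam[key == k]
      if (!(m %in% f)) next
      N <- N + sum(f == m)
      for (i in f) {
        if (i == m) next
        n[i] <- (if (i %in% names(n)) n[[i]] else 0L) + 1L
      }
    }
    out[[m]] <- list(N = N, n = n,
                     freq = if (N > 0) 100 * n / N else n * NA_real_)
  }
  out
}
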