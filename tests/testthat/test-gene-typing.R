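# Gene typing: role counts, the eight type predicates, scaffold precedence.

test_that("role counts tally module occurrences by catalog role", {
  cat <- defaultCatalog()
  scaffold <- profileGene(mkGene(c("cohesin", "cohesin", "cohesin", "SLH")),
                          cat)
  expect_equal(unlist(scaffold[c("n_slh", "n_dockerin", "n_cohesin",
                                 "n_cgh", "n_ccbm")], use.names = FALSE),
               c(1L, 0L, 3L, 0L, 0L))
  cellulase <- profileGene(mkGene(c("GH48", "CBM3")), cat)
  expect_equal(unlist(cellulase[c("n_slh", "n_dockerin", "n_cohesin",
                                  "n_cgh", "n_ccbm")], use.names = FALSE),
               c(0L, 0L, 0L, 1L, 1L))
  nonCazy <- profileGene(mkGene("GT2"), cat)
  expect_equal(sum(unlist(nonCazy[c("n_slh", "n_dockerin", "n_cohesin",
                                    "n_cgh", "n_ccbm")])), 0L)
})

mkProfile <- function(slh, doc, coh, cgh, ccbm) {
  data.frame(protein_id = "p", genome_id = "G", n_slh = slh,
             n_dockerin = doc, n_cohesin = coh, n_cgh = cgh, n_ccbm = ccbm,
             stringsAsFactors = FALSE)
}

test_that("characteristic architectures get their documented types", {
  cases <- list(
    # counts (slh, doc, coh, cgh, ccbm) -> satisfied set, primary
    list(c(1, 0, 3, 0, 0), "A1", "A1"),          # SLH-anchored scaffoldin
    list(c(0, 1, 3, 0, 0), c("A2-a"), "A2-a"),   # dockerin-tailed scaffoldin
    list(c(1, 0, 1, 0, 0), "A2-b", "A2-b"),      # SLH carrier via cohesin
    list(c(0, 0, 3, 0, 0), "A3", "A3"),          # free scaffoldin
    list(c(1, 0, 0, 0, 1), "B", "B"),            # SLH-cCBM adhesion gene
    list(c(0, 1, 0, 1, 0), c("A-s", "D"), "A-s"),# cellulosomal catalytic
    list(c(0, 0, 0, 1, 1), "C", "C"),            # cellulose-binding cellulase
    list(c(0, 0, 0, 1, 0), "D", "D"),            # free cellulase
    list(c(0, 0, 0, 0, 0), character(), NA_character_),
    # scaffold precedence keeps A1, drops A2-b; B and C co-satisfied
    list(c(1, 0, 3, 1, 1), c("A1", "B", "C"), "A1"))
  for (cs in cases) {
    p <- assignTypes(mkProfile(cs[[1]][1], cs[[1]][2], cs[[1]][3],
                               cs[[1]][4], cs[[1]][5]))
    got <- if (nzchar(p$satisfied_types))
      strsplit(p$satisfied_types, ",")[[1]] else character()
    expect_setequal(got, cs[[2]])
    expect_equal(p$primary_type, cs[[3]],
                 info = paste(cs[[1]], collapse = ","))
  }
})

test_that("the loose A-s reading admits dockerin + cCBM-only genes", {
  p <- mkProfile(0, 1, 0, 0, 1)
  expect_false(grepl("A-s", assignTypes(p)$satisfied_types))
  expect_true(grepl("A-s", assignTypes(p, strictAs = FALSE)$satisfied_types))
})

test_that("typing matches the brute-force oracle over a sampled grid", {
  set.seed(11)
  grid <- expand.grid(slh = 0:2, doc = 0:2, coh = 0:4, cgh = 0:2, ccbm = 0:2)
  pick <- grid[sample(nrow(grid), 200), ]
  prof <- data.frame(protein_id = paste0("p", seq_len(nrow(pick))),
                     genome_id = "G", n_slh = pick$slh,
                     n_dockerin = pick$doc, n_cohesin = pick$coh,
                     n_cgh = pick$cgh, n_ccbm = pick$ccbm)
  got <- assignTypes(prof)
  for (i in seq_len(nrow(pick))) {
    want <- oracleAssign(pick$slh[i], pick$doc[i], pick$coh[i],
                         pick$cgh[i], pick$ccbm[i])
    gotSat <- if (nzchar(got$satisfied_types[i]))
      strsplit(got$satisfied_types[i], ",")[[1]] else character()
    expect_identical(sort(gotSat), sort(want$satisfied))
    expect_identical(got$primary_type[i], want$primary)
  }
})

test_that("type assignment is monotone in the documented directions", {
  set.seed(12)
  for (rep in 1:50) {
    v <- c(slh = sample(0:3, 1), doc = sample(0:3, 1), coh = sample(0:4, 1),
           cgh = sample(0:3, 1), ccbm = sample(0:3, 1))
    base <- assignTypes(mkProfile(v["slh"], v["doc"], v["coh"], v["cgh"],
                                  v["ccbm"]))
    # adding an SLH occurrence never removes B
    moreSlh <- assignTypes(mkProfile(v["slh"] + 1, v["doc"], v["coh"],
                                     v["cgh"], v["ccbm"]))
    if (grepl("(^|,)B(,|$)", base$satisfied_types)) {
      expect_true(grepl("(^|,)B(,|$)", moreSlh$satisfied_types))
    }
    # adding a cohesin never demotes a satisfied scaffold label
    moreCoh <- assignTypes(mkProfile(v["slh"], v["doc"], v["coh"] + 1,
                                     v["cgh"], v["ccbm"]))
    scafOrder <- c("A1" = 1, "A2-a" = 2, "A2-b" = 3, "A3" = 4)
    rank <- function(p) {
      s <- intersect(names(scafOrder),
                     strsplit(p$satisfied_types, ",")[[1]])
      if (length(s)) scafOrder[[s[1]]] else 5
    }
    expect_lte(rank(moreCoh), rank(base))
  }
})

test_that("gene-type reports round-trip through TSV", {
  cat <- defaultCatalog()
  genes <- rbind(mkGenome(list(c("SLH", "cohesin", "cohesin", "cohesin"),
                               c("GH48", "CBM3")), genome = "G1"),
                 mkGenome(list(c("dockerin", "GH5")), genome = "G2"))
  prof <- geneTypeProfiles(genes, cat)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeReport(prof, tsv)
  expect_equal(readReport(tsv), prof)
})
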