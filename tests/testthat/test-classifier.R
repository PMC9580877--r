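# Genome-level summaries and the genotype decision tree.

test_that("genome summary tallies primary types and role presence", {
  cat <- defaultCatalog()
  genes <- mkGenome(list(c("SLH", "cohesin", "cohesin", "cohesin"),
                         c("dockerin", "GH48"),
                         c("GH5")), genome = "G1")
  prof <- geneTypeProfiles(genes, cat)
  gp <- summarizeGenome(prof, moduleAbundance(genes)$G1, cat)
  expect_equal(gp$n_A1, 1L)
  expect_equal(gp$n_As, 1L)
  expect_equal(gp$n_D, 1L)
  expect_true(gp$has_exo && gp$has_endo)
  # a gene satisfying both A-s and D contributes to n_As only
  expect_equal(gp$n_As + gp$n_D, 2L)
  expect_error(
    summarizeGenome(rbind(prof, transform(prof, genome_id = "G2")),
                    moduleAbundance(genes)$G1, cat),
    "single genome")
})

test_that("adhering scaffolds need A1 or the assembled A2 pair", {
  base <- profileFromFlags(FALSE, FALSE, FALSE, FALSE, FALSE)
  a1 <- transform(base, n_A1 = 1L)
  expect_true(hasAdheringScaffold(a1))
  a2only <- transform(base, n_A2a = 1L)
  expect_false(hasAdheringScaffold(a2only))      # unassembled backbone
  expect_true(hasAdheringScaffold(a2only, a2RequiresPair = FALSE))
  pair <- transform(base, n_A2a = 1L, n_A2b = 1L)
  expect_true(hasAdheringScaffold(pair))
  expect_false(hasAdheringScaffold(base))
})

test_that("the decision flow reproduces the published genotype criteria", {
  # literal decision-table rows
  expect_equal(classifyGenome(profileFromFlags(TRUE, FALSE, FALSE, FALSE,
                                               FALSE)), "I-a")
  expect_equal(classifyGenome(profileFromFlags(FALSE, TRUE, TRUE, TRUE,
                                               TRUE)), "I-b")
  expect_equal(classifyGenome(profileFromFlags(FALSE, TRUE, FALSE, TRUE,
                                               TRUE)), "I-c")
  expect_equal(classifyGenome(profileFromFlags(FALSE, FALSE, TRUE, TRUE,
                                               TRUE)), "I-d")
  expect_equal(classifyGenome(profileFromFlags(FALSE, FALSE, FALSE, TRUE,
                                               TRUE)), "I-e")
  expect_equal(classifyGenome(profileFromFlags(FALSE, FALSE, FALSE, TRUE,
                                               FALSE)), "I-e")
  expect_equal(classifyGenome(profileFromFlags(FALSE, FALSE, FALSE, FALSE,
                                               TRUE)), "I-f")
  # missing exo or endo role -> Group II even with CAZy modules present
  expect_equal(classifyGenome(profileFromFlags(TRUE, TRUE, TRUE, TRUE, TRUE,
                                               exoEndo = FALSE)), "II")
  # absent from the annotation output entirely
  expect_equal(classifyGenome(profileFromFlags(FALSE, FALSE, FALSE, FALSE,
                                               FALSE, exoEndo = FALSE,
                                               anyModules = FALSE)),
               "NO_CAZY")
  # unpaired A2-a routes to the free-scaffold branch by default
  a2 <- profileFromFlags(FALSE, FALSE, FALSE, TRUE, TRUE)
  a2$n_A2a <- 1L
  expect_equal(classifyGenome(a2), "I-c")
  expect_equal(classifyGenome(a2, a2RequiresPair = FALSE), "I-a")
})

test_that("every presence/absence combination gets exactly one label and
           matches the row matcher where a row exists", {
  combos <- expand.grid(adh = c(FALSE, TRUE), free = c(FALSE, TRUE),
                        b = c(FALSE, TRUE), c = c(FALSE, TRUE),
                        d = c(FALSE, TRUE), exoEndo = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    got <- classifyGenome(profileFromFlags(cb$adh, cb$free, cb$b, cb$c,
                                           cb$d, exoEndo = cb$exoEndo))
    expect_length(got, 1L)
    expect_true(got %in% c("I-a", "I-b", "I-c", "I-d", "I-e", "I-f", "II"))
    if (!cb$exoEndo) {
      expect_equal(got, "II")
      next
    }
    want <- tableRowMatch(cb$adh, cb$free, cb$b, cb$c, cb$d)
    if (!is.na(want)) {
      expect_equal(got, want,
                   info = paste(unlist(cb), collapse = ","))
    }
  }
})

test_that("adding genes produces the documented group transitions", {
  # I-c + B gene -> I-b; I-e + B gene -> I-d; any Group I + A1 gene -> I-a
  ic <- profileFromFlags(FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(classifyGenome(ic), "I-c")
  expect_equal(classifyGenome(transform(ic, n_B = 1L)), "I-b")
  ie <- profileFromFlags(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(classifyGenome(ie), "I-e")
  expect_equal(classifyGenome(transform(ie, n_B = 1L)), "I-d")
  for (p in list(ic, ie, profileFromFlags(FALSE, FALSE, FALSE, FALSE, TRUE))) {
    expect_equal(classifyGenome(transform(p, n_A1 = 1L)), "I-a")
  }
})

test_that("batch classification is gene-order invariant and drops nothing", {
  cat <- defaultCatalog()
  genes <- rbind(
    mkGenome(list(c("SLH", "cohesin", "cohesin", "cohesin"),
                  c("dockerin", "GH48"), c("GH5")), genome = "A"),
    mkGenome(list(c("GH5", "CBM3")), genome = "B"),       # endo only -> II
    mkGenome(list(c("GH48", "CBM3"), c("GH5")), genome = "C"))
  cls <- batchClassify(genes, cat, genomeIds = c("A", "B", "C", "D"))
  expect_equal(nrow(cls), 4L)
  expect_equal(cls$group[match(c("A", "B", "C", "D"), cls$genome_id)],
               c("I-a", "II", "I-e", "NO_CAZY"))
  perm <- genes[sample(nrow(genes)), ]
  expect_equal(batchClassify(perm, cat, genomeIds = c("A", "B", "C", "D")),
               cls)
  smry <- groupSummary(cls)
  expect_equal(sum(smry$n_genomes), 4L)
  expect_equal(smry$n_genomes[smry$group == "NO_CAZY"], 1L)
  # classification TSV round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeReport(cls, tsv)
  expect_equal(readReport(tsv), cls)
})
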