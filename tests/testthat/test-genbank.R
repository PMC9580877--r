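# GenBank CDS extraction, replicon aggregation, FASTA round trips.

test_that("CDS features with translations become protein records", {
  gbk <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    cds = list(list(location = "1..9",
                    qualifiers = list(protein_id = "AAA1",
                                      translation = "MKL"))))
  rec <- parseGenBank(gbk, genome_id = "toy")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$protein_id, "AAA1")
  expect_equal(rec$aa_sequence, "MKL")
  expect_equal(rec$aa_length, 3L)
  expect_equal(rec$genome_id, "toy")
  expect_equal(rec$replicon_id, "TOY1.1")
  expect_equal(rec$nt_start, 1L)
  expect_equal(rec$nt_end, 9L)
})

test_that("two CDS on opposite strands come back ordered by start", {
  gbk <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    cds = list(
      list(location = "complement(20..31)",
           qualifiers = list(protein_id = "REV", translation = "MIVH")),
      list(location = "1..9",
           qualifiers = list(protein_id = "FWD", translation = "MKL"))))
  rec <- parseGenBank(gbk)
  expect_equal(rec$protein_id, c("FWD", "REV"))
  expect_setequal(rec$strand, c("+", "-"))
  expect_true(all(diff(rec$nt_start) > 0))
})

test_that("CDS without a translation qualifier is translated under table 11", {
  # 1..12 of the origin: ATG AAA CTG TAA -> MKL with the stop stripped
  origin <- paste0("atgaaactgtaa", paste(rep("c", 48), collapse = ""))
  gbk <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    cds = list(list(location = "1..12",
                    qualifiers = list(locus_tag = "nt_only"))),
    origin = origin)
  rec <- parseGenBank(gbk)
  expect_equal(rec$aa_sequence, "MKL")   # frozen from the codon table
  expect_equal(rec$aa_length, 3L)
})

test_that("pseudo CDS are skipped and join locations collapse to a span", {
  origin <- paste0("atgaaactgtaa", paste(rep("c", 48), collapse = ""))
  gbk <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    cds = list(
      list(location = "join(1..6,10..15)",
           qualifiers = list(protein_id = "J1", translation = "MKLV")),
      list(location = "40..48",
           qualifiers = list(protein_id = "PS", pseudo = TRUE))),
    origin = origin)
  expect_message(rec <- parseGenBank(gbk), "pseudo")
  expect_equal(rec$protein_id, "J1")
  expect_equal(rec$nt_start, 1L)
  expect_equal(rec$nt_end, 15L)
  expect_true(rec$multi_segment)
})

test_that("unreadable and malformed inputs raise informative errors", {
  expect_error(parseGenBank("does/not/exist.gbk"), "does/not/exist")
  bad <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("DEFINITION  no locus", "//"), bad)
  expect_error(parseGenBank(bad), "LOCUS")
})

test_that("strain aggregation joins replicons and disambiguates id collisions", {
  chrom <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    locus = "CHR", version = "CHR.1",
    cds = list(
      list(location = "1..9",
           qualifiers = list(protein_id = "p1", translation = "MKL")),
      list(location = "20..28",
           qualifiers = list(protein_id = "p2", translation = "MAA"))))
  plasm <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    locus = "PLS", version = "PLS.1",
    cds = list(list(location = "1..9",
                    qualifiers = list(protein_id = "p3",
                                      translation = "MCC"))))
  agg <- aggregateStrain(list(genome_id = "strainX",
                              replicon_files = c(chrom, plasm)))
  expect_equal(nrow(agg), 3L)
  expect_equal(unique(agg$genome_id), "strainX")
  expect_equal(sum(agg$replicon_id == "CHR.1"), 2L)

  # same protein_id on both replicons -> replicon-prefixed on both sides
  plasm2 <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    locus = "PLS", version = "PLS.1",
    cds = list(list(location = "1..9",
                    qualifiers = list(protein_id = "p1",
                                      translation = "MCC"))))
  agg2 <- aggregateStrain(list(genome_id = "strainX",
                               replicon_files = c(chrom, plasm2)))
  expect_setequal(agg2$protein_id, c("CHR.1:p1", "PLS.1:p1", "p2"))

  # permuting the replicon files yields the same multiset of records
  agg3 <- aggregateStrain(list(genome_id = "strainX",
                               replicon_files = c(plasm, chrom)))
  o <- function(d) d[order(d$protein_id), c("protein_id", "aa_sequence")]
  expect_equal(o(agg3), o(agg), ignore_attr = TRUE)

  expect_error(aggregateStrain(list(genome_id = "s",
                                    replicon_files = character())),
               "empty")
})

test_that("FASTA export round-trips ids, sequences and coordinates", {
  gbk <- writeToyGbk(withr::local_tempfile(fileext = ".gbk"),
    cds = list(
      list(location = "1..9",
           qualifiers = list(protein_id = "AAA1", translation = "MKL")),
      list(location = "complement(20..31)",
           qualifiers = list(protein_id = "AAA2",
                             translation = "MIVHAGILKWERTY"))))
  rec <- parseGenBank(gbk, genome_id = "toy")
  faa <- withr::local_tempfile(fileext = ".faa")
  writeFaa(rec, faa)
  back <- readFaa(faa)
  for (col in c("protein_id", "genome_id", "replicon_id", "aa_sequence",
                "aa_length", "nt_start", "nt_end", "strand")) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
  # 60-column wrapping: one header + one sequence line per short protein
  lines <- readLines(faa)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  expect_error(writeFaa(rec[0, ], withr::local_tempfile()), "non-empty")
})
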