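# GenBank flat-file ingestion: CDS -> protein records, replicon aggregation.
#
# The parser targets the subset of the flat-file grammar needed to pull
# protein-coding features out of prokaryote chromosome/plasmid records:
# LOCUS/VERSION headers, the FEATURES table (CDS keys with location strings
# spanning lines, qualifiers at column 22), and the ORIGIN sequence block.

#' Extract protein records from a GenBank flat file
#'
#' Returns one row per CDS feature. Features carrying a `/translation`
#' qualifier use it verbatim; CDS without a translation are conceptually
#' translated from the nucleotide span under the bacterial/archaeal genetic
#' code (translation table 11) with a trailing stop codon stripped. Features
#' flagged `/pseudo` are skipped with a message. Coordinates are GenBank
#' 1-based inclusive; join/compound locations are stored as the minimal
#' start and maximal end with `multi_segment = TRUE`.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @param genome_id Strain identifier to stamp on the records; defaults to
#'   the replicon identifier of the first record.
#' @return A data.frame with columns `protein_id`, `genome_id`,
#'   `replicon_id`, `aa_sequence`, `aa_length`, `nt_start`, `nt_end`,
#'   `strand`, `multi_segment`, ordered by `nt_start` within each replicon.
#' @seealso [aggregateStrain()], [writeFaa()]
#' @export
parseGenBank <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read GenBank file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  out <- lapply(recs, function(rl) .parseGenBankRecord(rl, path))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    stop("no GenBank records found in ", path, call. = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(genome_id)) genome_id <- df$replicon_id[1]
  df$genome_id <- genome_id
  rownames(df) <- NULL
  df[, c("protein_id", "genome_id", "replicon_id", "aa_sequence",
         "aa_length", "nt_start", "nt_end", "strand", "multi_segment")]
}

.parseGenBankRecord <- function(rl, path) {
  rl <- rl[!grepl("^//\\s*$", rl)]
  if (all(!nzchar(trimws(rl)))) return(NULL)
  locus <- grep("^LOCUS", rl, value = TRUE)
  if (length(locus) == 0) {
    stop("malformed GenBank record (no LOCUS line) in ", path, call. = FALSE)
  }
  locus_name <- strsplit(trimws(locus[1]), "\\s+")[[1]][2]
  ver <- grep("^VERSION\\s+\\S", rl, value = TRUE)
  acc <- grep("^ACCESSION\\s+\\S", rl, value = TRUE)
  replicon_id <- if (length(ver)) strsplit(trimws(ver[1]), "\\s+")[[1]][2]
    else if (length(acc)) strsplit(trimws(acc[1]), "\\s+")[[1]][2]
    else locus_name

  fstart <- grep("^FEATURES", rl)
  ostart <- grep("^ORIGIN", rl)
  nt_seq <- ""
  if (length(ostart)) {
    oend <- length(rl)
    oblock <- rl[seq.int(ostart[1] + 1L, oend)]
    nt_seq <- toupper(gsub("[^A-Za-z]", "", paste(oblock, collapse = "")))
  }
  if (length(fstart) == 0) return(NULL)
  fend <- if (length(ostart)) ostart[1] - 1L else length(rl)
  if (fend <= fstart[1]) return(NULL)
  fl <- rl[seq.int(fstart[1] + 1L, fend)]

  # feature key lines have the key at column 6; everything else continues
  is_key <- grepl("^ {5}\\S", fl)
  idx <- cumsum(is_key)
  feats <- split(fl, idx)
  if (length(feats) && !is_key[1]) feats <- feats[-1]

  rows <- list()
  cds_i <- 0L
  for (ft in feats) {
    key <- strsplit(trimws(ft[1]), "\\s+")[[1]][1]
    if (!identical(key, "CDS")) next
    cds_i <- cds_i + 1L
    parsed <- .parseFeatureBlock(ft)
    q <- parsed$qualifiers
    if ("pseudo" %in% names(q) || "pseudogene" %in% names(q)) {
      message("skipping pseudo CDS at ", parsed$location, " in ", replicon_id)
      next
    }
    loc <- tryCatch(.parseLocation(parsed$location),
                    error = function(e) stop("malformed CDS location '",
                        parsed$location, "' in record ", replicon_id,
                        call. = FALSE))
    pid <- q[["protein_id"]] %||% q[["locus_tag"]] %||%
      sprintf("%s_cds%03d", replicon_id, cds_i)
    aa <- q[["translation"]]
    if (is.null(aa)) {
      if (!nzchar(nt_seq)) {
        stop("CDS ", pid, " in record ", replicon_id,
             " has no translation and the record has no ORIGIN sequence",
             call. = FALSE)
      }
      aa <- .spliceTranslate(nt_seq, loc)
    } else {
      aa <- gsub("[^A-Za-z*]", "", aa)
    }
    aa <- sub("\\*$", "", aa)
    if (!nzchar(aa)) {
      stop("CDS ", pid, " in record ", replicon_id,
           " yields an empty protein sequence", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, replicon_id = replicon_id, aa_sequence = aa,
      aa_length = nchar(aa), nt_start = loc$start, nt_end = loc$end,
      strand = loc$strand, multi_segment = loc$multi,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  df <- do.call(rbind, rows)
  df[order(df$nt_start), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split one feature block into its location string and a named qualifier list
.parseFeatureBlock <- function(ft) {
  body <- trimws(ft)
  body[1] <- sub("^\\S+\\s*", "", body[1])   # drop the feature key
  qstart <- grepl("^/", body)
  pieces <- split(body, cumsum(qstart))
  location <- ""
  quals <- list()
  for (nm in names(pieces)) {
    txt <- pieces[[nm]]
    if (nm == "0") {
      location <- gsub("\\s+", "", paste(txt, collapse = ""))
      next
    }
    joined <- paste(txt, collapse = "\n")
    m <- regmatches(joined, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", joined))[[1]]
    if (length(m) == 0) next
    qname <- m[2]
    qval <- if (nchar(m[4])) m[4] else TRUE
    if (is.character(qval)) {
      qval <- gsub('"', "", qval)
      if (identical(qname, "translation")) {
        qval <- gsub("\\s+", "", qval)
      } else {
        qval <- gsub("\n\\s*", " ", qval)
      }
    }
    quals[[qname]] <- qval
  }
  list(location = location, qualifiers = quals)
}

# GenBank location string -> list(start, end, strand, multi, segments)
.parseLocation <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
  segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (length(segs) == 0) stop("empty location")
  mat <- t(vapply(segs, function(s) {
    p <- strsplit(s, "\\.\\.")[[1]]
    a <- as.integer(p[1])
    b <- if (length(p) > 1) as.integer(p[2]) else a
    if (is.na(a) || is.na(b) || a > b) stop("bad segment '", s, "'")
    c(a, b)
  }, integer(2)))
  list(start = min(mat[, 1]), end = max(mat[, 2]), strand = strand,
       multi = nrow(mat) > 1L, segments = mat)
}

# splice CDS segments out of the replicon sequence and translate (table 11)
.spliceTranslate <- function(nt_seq, loc) {
  segs <- loc$segments
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    substr(nt_seq, segs[i, 1], segs[i, 2])
  }, character(1))
  cds <- paste(parts, collapse = "")
  dna <- Biostrings::DNAString(cds)
  if (identical(loc$strand, "-")) dna <- Biostrings::reverseComplement(dna)
  n3 <- 3L * (length(dna) %/% 3L)
  if (n3 < length(dna)) {
    warning("CDS length not a multiple of 3; trailing bases ignored",
            call. = FALSE)
    dna <- dna[seq_len(n3)]
  }
  aa <- Biostrings::translate(dna, genetic.code = Biostrings::getGeneticCode("11"),
                              if.fuzzy.codon = "solve")
  sub("\\*$", "", as.character(aa))
}

#' Aggregate the replicons of one strain into a single protein set
#'
#' Chromosome and plasmid(s) of the same strain live in separate GenBank
#' files; this concatenates their protein records under one `genome_id`.
#' Protein identifiers that collide across replicons are disambiguated by
#' replicon-prefixing (`"<replicon_id>:<protein_id>"`) on every colliding
#' record, deterministically.
#'
#' @param manifest A list with elements `genome_id` (length-1 character) and
#'   `replicon_files` (character vector of GenBank file paths), or a
#'   two-column data.frame (`genome_id`, `file`) restricted to one strain.
#' @return A protein-record data.frame as from [parseGenBank()].
#' @seealso [readStrainManifest()]
#' @export
aggregateStrain <- function(manifest) {
  if (is.data.frame(manifest)) {
    if (nrow(manifest) == 0) stop("empty strain manifest", call. = FALSE)
    gid <- unique(manifest$genome_id)
    if (length(gid) != 1) {
      stop("aggregateStrain expects a single strain; got genome_ids: ",
           paste(gid, collapse = ", "), call. = FALSE)
    }
    manifest <- list(genome_id = gid, replicon_files = manifest$file)
  }
  files <- manifest$replicon_files
  if (is.null(files) || length(files) == 0) {
    stop("empty strain manifest: no replicon files", call. = FALSE)
  }
  recs <- lapply(files, parseGenBank, genome_id = manifest$genome_id)
  df <- do.call(rbind, recs)
  # prefix every record of an id that occurs on more than one replicon
  multi <- vapply(split(df$replicon_id, df$protein_id),
                  function(r) length(unique(r)) > 1, logical(1))
  hit <- df$protein_id %in% names(multi)[multi]
  df$protein_id[hit] <- paste(df$replicon_id[hit], df$protein_id[hit],
                              sep = ":")
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id within one replicon of strain ",
         manifest$genome_id, call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a strain manifest (genome -> GenBank files)
#'
#' TSV layout: two columns `genome_id` and `file` with a header, one row per
#' replicon file. YAML layout: a list of maps, each with keys `genome_id`
#' and `files`.
#'
#' @param path Manifest path (`.tsv` or `.yml`/`.yaml`).
#' @return A data.frame with columns `genome_id`, `file`.
#' @export
readStrainManifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(raw, function(e) {
      data.frame(genome_id = e$genome_id,
                 file = as.character(unlist(e$files)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("genome_id", "file") %in% names(df))) {
      stop("manifest TSV needs columns 'genome_id' and 'file'", call. = FALSE)
    }
  }
  if (nrow(df) == 0) stop("empty manifest: ", path, call. = FALSE)
  df
}
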