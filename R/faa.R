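# Protein FASTA export/import with a parseable header layout.
#
# Header layout (space-separated, fields after the id are optional):
#   >protein_id genome=GENOME replicon=REPLICON loc=START..END(STRAND)
# Sequences are wrapped at 60 columns. readFaa() inverts the layout, so a
# parse -> writeFaa -> readFaa round trip preserves ids, sequences and
# coordinates.

#' Write protein records to an amino-acid FASTA file
#'
#' @param records Protein-record data.frame (see [parseGenBank()]); at
#'   minimum columns `protein_id`, `genome_id`, `aa_sequence`. Coordinate
#'   columns, when present and non-`NA`, are encoded in the header.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
writeFaa <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("writeFaa needs a non-empty protein-record data.frame", call. = FALSE)
  }
  need <- c("protein_id", "genome_id", "aa_sequence")
  if (!all(need %in% names(records))) {
    stop("records must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hdr <- paste0(records$protein_id, " genome=", records$genome_id)
  if ("replicon_id" %in% names(records)) {
    has <- !is.na(records$replicon_id)
    hdr[has] <- paste0(hdr[has], " replicon=", records$replicon_id[has])
  }
  if (all(c("nt_start", "nt_end", "strand") %in% names(records))) {
    has <- !is.na(records$nt_start) & !is.na(records$nt_end)
    hdr[has] <- paste0(hdr[has], " loc=", records$nt_start[has], "..",
                       records$nt_end[has], "(", records$strand[has], ")")
  }
  aa <- Biostrings::AAStringSet(records$aa_sequence)
  names(aa) <- hdr
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' Read an amino-acid FASTA file into a protein-record data.frame
#'
#' Understands the header layout written by [writeFaa()]; plain FASTA headers
#' degrade gracefully (the first whitespace-delimited token becomes
#' `protein_id`, metadata fields come back `NA`).
#'
#' @param path FASTA path.
#' @return A data.frame with columns `protein_id`, `genome_id`,
#'   `replicon_id`, `aa_sequence`, `aa_length`, `nt_start`, `nt_end`,
#'   `strand`.
#' @export
readFaa <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  grab <- function(pat) {
    m <- regmatches(hdr, regexec(pat, hdr))
    vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
           character(1))
  }
  loc <- grab("loc=([0-9]+\\.\\.[0-9]+\\([+-]\\))")
  nt_start <- suppressWarnings(as.integer(sub("\\.\\..*$", "", loc)))
  nt_end <- suppressWarnings(as.integer(sub("^.*\\.\\.([0-9]+)\\(.*$", "\\1", loc)))
  strand <- sub("^.*\\(([+-])\\)$", "\\1", loc)
  strand[is.na(loc)] <- NA_character_
  df <- data.frame(
    protein_id = vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L),
    genome_id = grab("genome=(\\S+)"),
    replicon_id = grab("replicon=(\\S+)"),
    aa_sequence = unname(as.character(aa)),
    aa_length = Biostrings::width(aa),
    nt_start = nt_start, nt_end = nt_end, strand = strand,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
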