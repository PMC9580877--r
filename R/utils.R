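# Shared helpers: family-label normalization and small validators.

#' Normalize CAZy module family labels
#'
#' Strips any trailing `".hmm"` suffix (as emitted by dbCAN HMM profile names)
#' and maps common spellings of the structural cellulosome modules onto the
#' canonical labels `SLH`, `cohesin` and `dockerin` (case-insensitively;
#' `"cohesion"` and `"DOC"` are accepted aliases). Case of other family
#' labels is preserved.
#'
#' @param x Character vector of family labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalizeFamily(c("GH48.hmm", "Cohesion", "doc", "SLH"))
#' @export
normalizeFamily <- function(x) {
  x <- sub("\\.hmm$", "", as.character(x), ignore.case = TRUE)
  lx <- tolower(x)
  x[lx == "slh"] <- "SLH"
  x[lx %in% c("cohesin", "cohesion", "coh")] <- "cohesin"
  x[lx %in% c("dockerin", "doc")] <- "dockerin"
  x
}

#' Collapse CAZy subfamily labels onto their parent family
#'
#' Subfamily labels such as `"GH5_4"` are resolved to their parent family
#' (`"GH5"`) for role lookup; all other labels pass through unchanged. Reports
#' retain the full label, only role assignment works at the family level.
#'
#' @param x Character vector of (normalized) family labels.
#' @return Character vector of parent-family labels.
#' @examples
#' parentFamily(c("GH5_4", "GH48", "CBM3"))
#' @export
parentFamily <- function(x) {
  sub("^([A-Za-z]+[0-9]+)_[0-9]+$", "\\1", as.character(x))
}

# columns every ModuleHit table must carry
.hitColumns <- c("family", "protein_id", "genome_id",
                 "aa_start", "aa_end", "e_value", "hmm_coverage")

.checkHitFrame <- function(hits, what = "hits") {
  if (!is.data.frame(hits)) {
    stop(what, " must be a data.frame of module hits", call. = FALSE)
  }
  missing <- setdiff(.hitColumns, names(hits))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(hits)
}

# gene key used to group hits into genes
.geneKey <- function(hits) paste(hits$genome_id, hits$protein_id, sep = "\r")

# empty ModuleHit frame with the canonical columns
.emptyHits <- function() {
  data.frame(family = character(), protein_id = character(),
             genome_id = character(), aa_start = integer(),
             aa_end = integer(), e_value = numeric(),
             hmm_coverage = numeric(), stringsAsFactors = FALSE)
}
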