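# Gene-architecture diagrams: one horizontal track per gene, one colored bar
# per module, written as standalone SVG. The emitter prints fixed-format
# integers only, so identical input yields byte-identical files.

#' Color scheme for gene-architecture diagrams
#'
#' GH modules green, CBM modules yellow, SLH blue, dockerin pink, cohesin
#' purple; anything else grey.
#'
#' @return Named character vector of hex colors.
#' @export
geneMapColors <- function() {
  c(GH = "#3cb44b", CBM = "#ffe119", SLH = "#4363d8",
    dockerin = "#f7a8c8", cohesin = "#911eb4", other = "#bdbdbd")
}

.moduleColorClass <- function(family) {
  fam <- parentFamily(normalizeFamily(family))
  out <- rep("other", length(fam))
  out[grepl("^GH[0-9]+$", fam)] <- "GH"
  out[grepl("^CBM[0-9]+$", fam)] <- "CBM"
  out[fam == "SLH"] <- "SLH"
  out[fam == "dockerin"] <- "dockerin"
  out[fam == "cohesin"] <- "cohesin"
  out
}

#' Render a gene-architecture diagram to SVG
#'
#' One track per gene: a thin backbone line spanning the gene and one
#' colored bar per module hit, the bar's x-extent being the module's
#' `aa_start..aa_end` scaled to the chosen coordinate unit (`"nt"` widths
#' are exactly 3x the `"aa"` widths). Gene label (and type annotation, when
#' a `type` column or `labels` vector is supplied) is printed left of each
#' track. Output is deterministic: two renders of the same input are
#' byte-identical.
#'
#' @param genes Gene table ([buildGenes()]) with at least one hit.
#' @param file Output SVG path.
#' @param unit Coordinate unit, `"aa"` (default) or `"nt"`.
#' @param labels Optional named character vector (`protein_id` -> type
#'   annotation) appended to gene labels.
#' @param colors Color scheme, see [geneMapColors()].
#' @param pxPerUnit Horizontal scale in pixels per residue/nucleotide.
#' @return The path, invisibly.
#' @export
renderGeneMap <- function(genes, file, unit = c("aa", "nt"), labels = NULL,
                          colors = geneMapColors(), pxPerUnit = 1) {
  unit <- match.arg(unit)
  .checkHitFrame(genes, "genes")
  if (nrow(genes) == 0) {
    stop("renderGeneMap needs at least one gene with at least one hit",
         call. = FALSE)
  }
  scale <- if (unit == "nt") 3L else 1L
  key <- .geneKey(genes)
  byGene <- split(seq_len(nrow(genes)), factor(key, levels = unique(key)))

  trackH <- 34L; barH <- 14L; padL <- 220L; padT <- 20L; padR <- 20L
  hasLen <- "aa_length" %in% names(genes)
  geneLens <- vapply(byGene, function(ix) {
    len <- if (hasLen) genes$aa_length[ix][1] else NA_integer_
    if (is.na(len)) len <- max(genes$aa_end[ix], na.rm = TRUE)
    as.integer(len)
  }, integer(1))
  width <- padL + padR + as.integer(ceiling(max(geneLens) * scale * pxPerUnit))
  height <- padT * 2L + trackH * length(byGene)

  px <- function(v) as.integer(round(v * scale * pxPerUnit))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            width, height))
  for (t in seq_along(byGene)) {
    ix <- byGene[[t]]
    gid <- genes$genome_id[ix][1]
    pid <- genes$protein_id[ix][1]
    lab <- paste0(gid, " / ", pid)
    extra <- NULL
    if (!is.null(labels) && pid %in% names(labels)) {
      extra <- labels[[pid]]
    } else if ("type" %in% names(genes)) {
      extra <- genes$type[ix][1]
    }
    if (!is.null(extra) && !is.na(extra) && nzchar(extra)) {
      lab <- paste0(lab, " [", extra, "]")
    }
    y0 <- padT + trackH * (t - 1L)
    ymid <- y0 + trackH %/% 2L
    out <- c(out,
      sprintf('<text x="%d" y="%d" font-family="monospace" font-size="11">%s</text>',
              8L, ymid + 4L, esc(lab)),
      sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#444444" stroke-width="2"/>',
              padL, ymid, padL + px(geneLens[t]), ymid))
    ord <- ix[order(genes$aa_start[ix], genes$aa_end[ix])]
    for (i in ord) {
      cls <- .moduleColorClass(genes$family[i])
      col <- colors[[cls]]
      x0 <- padL + px(genes$aa_start[i] - 1L)
      w <- max(1L, px(genes$aa_end[i] - genes$aa_start[i] + 1L))
      out <- c(out,
        sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#222222" stroke-width="1"><title>%s %d-%d</title></rect>',
                x0, ymid - barH %/% 2L, w, barH, col,
                esc(genes$family[i]), genes$aa_start[i], genes$aa_end[i]))
    }
  }
  out <- c(out, "</svg>")
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(file)
}
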