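# Module co-occurrence frequencies across a genome collection.
#
# Recipe, per focal module m: (1) retrieve every gene containing >=1 m and
# count the total occurrences of m in those genes as N; (2) count the total
# occurrences of each co-occurring module i in those same genes as n_i;
# (3) report 100 * n_i / N as the frequency at which module i is identified
# in the same gene as m. Genes are double-counted independently per focal
# module, and frequencies can exceed 100% when partners outnumber the focal
# module.

#' Module co-occurrence table over a gene corpus
#'
#' Family labels are normalized and subfamilies collapsed onto their parent
#' family before counting. Self-co-occurrence is excluded from the partner
#' axis by default; with `includeSelf = TRUE` the focal module's own column
#' instead reports extra copies, `n_self = N_m - (number of focal genes)`,
#' i.e. occurrences beyond the first per gene.
#'
#' @param genes Gene table ([buildGenes()]) drawn from one or more genomes.
#' @param focal Character vector of focal family labels; defaults to
#'   [focalModules()] of `catalog` when supplied.
#' @param catalog Optional [ModuleCatalog-class] supplying the default focal
#'   list.
#' @param includeSelf Report extra-copy self-frequencies? Default `FALSE`.
#' @return A [CooccurrenceTable-class]. Focal modules absent from the corpus
#'   get `N = 0` and an all-`NA` row (flagged with a message).
#' @seealso [heatmapTransform()], [writeCooccurrence()]
#' @export
cooccurrence <- function(genes, focal = NULL, catalog = NULL,
                         includeSelf = FALSE) {
  .checkHitFrame(genes, "genes")
  if (is.null(focal)) {
    if (is.null(catalog)) {
      stop("supply 'focal' modules or a 'catalog' with a default focal list",
           call. = FALSE)
    }
    focal <- focalModules(catalog)
  }
  focal <- unique(parentFamily(normalizeFamily(focal)))
  if (length(focal) == 0) stop("empty focal module list", call. = FALSE)
  fam <- parentFamily(normalizeFamily(genes$family))
  key <- .geneKey(genes)
  byGene <- split(fam, key)

  perFocal <- lapply(focal, function(m) {
    sel <- byGene[vapply(byGene, function(f) m %in% f, logical(1))]
    if (length(sel) == 0) {
      return(list(N = 0L, n = integer(), nGenes = 0L))
    }
    all <- unlist(sel, use.names = FALSE)
    N <- sum(all == m)
    tab <- table(all)
    n <- stats::setNames(as.integer(tab), names(tab))
    list(N = N, n = n, nGenes = length(sel))
  })
  names(perFocal) <- focal

  # partner axis: every family observed in a focal gene, plus the focal
  # modules themselves (a never-co-occurring focal pair must report 0%)
  partners <- sort(unique(c(unlist(lapply(perFocal,
                                          function(p) names(p$n))), focal)))
  n <- matrix(0L, nrow = length(focal), ncol = length(partners),
              dimnames = list(focal, partners))
  for (m in focal) {
    p <- perFocal[[m]]
    cnt <- p$n
    if (length(cnt) == 0) next
    if (includeSelf) {
      cnt[m] <- p$N - p$nGenes   # extra copies beyond one per gene
    } else {
      cnt <- cnt[names(cnt) != m]
    }
    n[m, names(cnt)] <- cnt
  }
  N <- vapply(perFocal, function(p) as.numeric(p$N), numeric(1))
  freq <- sweep(n, 1, N, "/") * 100
  freq[N == 0, ] <- NA_real_
  if (!includeSelf) {
    # self cells are excluded, not zero: mark them uninformative
    self <- intersect(focal, partners)
    freq[cbind(self, self)] <- NA_real_
    n[cbind(self, self)] <- NA_integer_
  }
  if (any(N == 0)) {
    message("focal module(s) absent from the corpus: ",
            paste(focal[N == 0], collapse = ", "))
  }
  new("CooccurrenceTable", focal = focal, partners = colnames(n),
      N = N, n = n, freq = freq)
}

#' @describeIn cooccurrence frequency matrix accessor (percentages).
#' @param x A `CooccurrenceTable`.
#' @export
freqMatrix <- function(x) x@freq

#' @describeIn cooccurrence raw partner-count matrix accessor.
#' @export
countMatrix <- function(x) x@n

#' @describeIn cooccurrence per-focal totals `N` accessor.
#' @export
focalTotals <- function(x) x@N

setMethod("show", "CooccurrenceTable", function(object) {
  cat("CooccurrenceTable:", length(object@focal), "focal x",
      length(object@partners), "partner modules\n")
  cat("  focal totals N in [", min(object@N), ",", max(object@N), "]\n")
  empty <- sum(object@N == 0)
  if (empty) cat("  ", empty, "focal module(s) absent from the corpus\n")
})

#' Heatmap transform for co-occurrence frequencies
#'
#' `log10(freq + 0.01)`, mapping 0% to exactly -2 and 99.99% to exactly 2.
#'
#' @param freq Numeric vector/matrix of percentages (must be >= 0; `NA`
#'   passes through).
#' @return Transformed values, same shape.
#' @export
heatmapTransform <- function(freq) {
  if (any(freq < 0, na.rm = TRUE)) {
    stop("negative frequency passed to heatmapTransform", call. = FALSE)
  }
  log10(freq + 0.01)
}

#' Write a co-occurrence table as TSV reports
#'
#' @param x A [CooccurrenceTable-class].
#' @param wide Optional path for the wide report (focal x partner
#'   percentage matrix, first column `focal`, plus `N`).
#' @param long Optional path for the long report (`focal`, `partner`, `N`,
#'   `n`, `freq`).
#' @return Invisibly, the paths written.
#' @export
writeCooccurrence <- function(x, wide = NULL, long = NULL) {
  stopifnot(is(x, "CooccurrenceTable"))
  out <- character()
  if (!is.null(wide)) {
    df <- data.frame(focal = x@focal, N = unname(x@N),
                     as.data.frame(x@freq, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    writeReport(df, wide)
    out <- c(out, wide)
  }
  if (!is.null(long)) {
    df <- data.frame(
      focal = rep(x@focal, each = length(x@partners)),
      partner = rep(x@partners, times = length(x@focal)),
      N = rep(unname(x@N), each = length(x@partners)),
      n = as.integer(t(x@n)),
      freq = as.numeric(t(x@freq)),
      stringsAsFactors = FALSE)
    writeReport(df, long)
    out <- c(out, long)
  }
  invisible(out)
}

#' Rebuild a co-occurrence table from its long TSV report
#'
#' @param path Long-report path written by [writeCooccurrence()].
#' @return A [CooccurrenceTable-class].
#' @export
readCooccurrence <- function(path) {
  df <- readReport(path)
  need <- c("focal", "partner", "N", "n", "freq")
  if (!all(need %in% names(df))) {
    stop("not a co-occurrence long report: ", path, call. = FALSE)
  }
  focal <- unique(df$focal)
  partners <- unique(df$partner)
  n <- matrix(0L, length(focal), length(partners),
              dimnames = list(focal, partners))
  freq <- matrix(NA_real_, length(focal), length(partners),
                 dimnames = list(focal, partners))
  n[cbind(df$focal, df$partner)] <- df$n
  freq[cbind(df$focal, df$partner)] <- df$freq
  N <- stats::setNames(df$N[!duplicated(df$focal)], focal)
  new("CooccurrenceTable", focal = focal, partners = partners,
      N = N, n = n, freq = freq)
}

#' How often do cGH-CBM genes carry a cellulose-binding CBM?
#'
#' Over all genes carrying at least one cGH-role module together with at
#' least one CBM module of any family, counts how many carry a
#' cellulose-binding (cCBM) family among their CBMs.
#'
#' @param genes Gene table ([buildGenes()]).
#' @param catalog A [ModuleCatalog-class].
#' @return A one-row data.frame: `n_cgh_cbm_genes`, `n_with_ccbm`, `pct`
#'   (`NA` when no gene has both roles).
#' @export
cghCbmPartnership <- function(genes, catalog) {
  .checkHitFrame(genes, "genes")
  stopifnot(is(catalog, "ModuleCatalog"))
  fam <- parentFamily(normalizeFamily(genes$family))
  key <- .geneKey(genes)
  cgh <- cghFamilies(catalog)
  ccbm <- ccbmFamilies(catalog)
  byGene <- split(fam, key)
  hasCgh <- vapply(byGene, function(f) any(f %in% cgh), logical(1))
  cbms <- lapply(byGene, function(f) f[grepl("^CBM[0-9]+$", f)])
  hasCbm <- lengths(cbms) > 0
  denomSel <- hasCgh & hasCbm
  denom <- sum(denomSel)
  num <- sum(vapply(cbms[denomSel], function(f) any(f %in% ccbm), logical(1)))
  data.frame(n_cgh_cbm_genes = denom, n_with_ccbm = num,
             pct = if (denom > 0) 100 * num / denom else NA_real_)
}
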