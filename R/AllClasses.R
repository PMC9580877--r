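#' @import methods
NULL

#' ModuleCatalog: role vocabularies for CAZy module families
#'
#' A `ModuleCatalog` holds the configurable family sets that drive every
#' downstream rule: the exoglucanase, endoglucanase and xylanase GH families,
#' the LPMO (lytic polysaccharide monooxygenase) families, and the
#' cellulose-binding CBM (cCBM) families. The structural cellulosome modules
#' (`SLH`, `cohesin`, `dockerin`) are fixed and not configurable. The derived
#' role *cGH* -- GH/AA families with documented exo- or endoglucanase or LPMO
#' activity -- is the union of the `exoGH`, `endoGH` and `lpmo` slots.
#'
#' A family may legitimately sit in more than one role set: GH9, for example,
#' is predominantly an endoglucanase module but exoglucanase activity is also
#' documented, so it carries both roles.
#'
#' @slot exoGH character vector of exoglucanase GH families.
#' @slot endoGH character vector of endoglucanase GH families.
#' @slot xylanaseGH character vector of xylanase GH families.
#' @slot lpmo character vector of LPMO families.
#' @slot ccbm character vector of cellulose-binding CBM families.
#'
#' @seealso [defaultCatalog()], [readCatalog()], [rolesOf()]
#' @export
setClass("ModuleCatalog",
         representation(exoGH = "character", endoGH = "character",
                        xylanaseGH = "character", lpmo = "character",
                        ccbm = "character"))

setValidity("ModuleCatalog", function(object) {
  msgs <- character()
  for (nm in c("exoGH", "endoGH", "xylanaseGH", "lpmo", "ccbm")) {
    fam <- slot(object, nm)
    if (anyNA(fam) || any(!nzchar(fam))) {
      msgs <- c(msgs, paste0("empty or NA family label in role '", nm, "'"))
    }
    if (anyDuplicated(fam)) {
      msgs <- c(msgs, paste0("duplicated family label in role '", nm, "'"))
    }
  }
  cgh <- union(union(object@exoGH, object@endoGH), object@lpmo)
  if (length(cgh) == 0) {
    msgs <- c(msgs, "catalog defines no cGH-forming families (exoGH, endoGH and lpmo all empty)")
  }
  if (length(object@exoGH) == 0) {
    msgs <- c(msgs, "catalog defines no exoglucanase families")
  }
  if (length(object@endoGH) == 0) {
    msgs <- c(msgs, "catalog defines no endoglucanase families")
  }
  if (length(msgs)) msgs else TRUE
})

#' CooccurrenceTable: module co-occurrence frequencies across a corpus
#'
#' Holds, for each focal module `m`, the total occurrence count `N_m` of `m`
#' over all genes containing at least one `m`, the raw partner occurrence
#' counts `n_i` tallied over those same genes, and the derived frequencies
#' `freq[m, i] = 100 * n_i / N_m` (percentages; values above 100 are possible
#' when partner modules outnumber the focal module within focal genes).
#'
#' @slot focal character vector of focal family labels (rows).
#' @slot partners character vector of partner family labels (columns).
#' @slot N named numeric vector of per-focal totals.
#' @slot n integer matrix of raw partner counts (focal x partner).
#' @slot freq numeric matrix of percentages (focal x partner); rows with
#'   `N == 0` are all-`NA`.
#'
#' @seealso [cooccurrence()], [heatmapTransform()]
#' @export
setClass("CooccurrenceTable",
         representation(focal = "character", partners = "character",
                        N = "numeric", n = "matrix", freq = "matrix"))

setValidity("CooccurrenceTable", function(object) {
  msgs <- character()
  if (!identical(dim(object@n), dim(object@freq))) {
    msgs <- c(msgs, "count and frequency matrices differ in shape")
  }
  if (nrow(object@freq) != length(object@focal) ||
      ncol(object@freq) != length(object@partners)) {
    msgs <- c(msgs, "matrix dimensions do not match focal/partner labels")
  }
  if (length(object@N) != length(object@focal)) {
    msgs <- c(msgs, "one N per focal module required")
  }
  if (any(object@freq < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "negative frequencies")
  }
  if (length(msgs)) msgs else TRUE
})
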