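# Role catalog: construction, accessors, YAML/TSV serialization, role lookup.

.structuralModules <- c("SLH", "cohesin", "dockerin")
.catalogRoles <- c("exo_gh", "endo_gh", "xylanase_gh", "lpmo", "ccbm")
.roleSlot <- c(exo_gh = "exoGH", endo_gh = "endoGH",
               xylanase_gh = "xylanaseGH", lpmo = "lpmo", ccbm = "ccbm")

#' Construct a ModuleCatalog
#'
#' Family labels are normalized as in [normalizeFamily()]; duplicate labels
#' within one role raise a warning and are deduplicated.
#'
#' @param exoGH,endoGH,xylanaseGH,lpmo,ccbm character vectors of family
#'   labels for each role.
#' @return A validated [ModuleCatalog-class] object.
#' @examples
#' cat <- moduleCatalog(exoGH = "GH48", endoGH = c("GH5", "GH9"),
#'                      xylanaseGH = "GH10", lpmo = "AA10", ccbm = "CBM3")
#' @export
moduleCatalog <- function(exoGH, endoGH, xylanaseGH = character(),
                          lpmo = character(), ccbm = character()) {
  dedup <- function(fam, role) {
    fam <- normalizeFamily(fam)
    if (anyDuplicated(fam)) {
      warning("duplicate family label(s) in role '", role, "' deduplicated",
              call. = FALSE)
      fam <- unique(fam)
    }
    fam
  }
  new("ModuleCatalog",
      exoGH = dedup(exoGH, "exo_gh"),
      endoGH = dedup(endoGH, "endo_gh"),
      xylanaseGH = dedup(xylanaseGH, "xylanase_gh"),
      lpmo = dedup(lpmo, "lpmo"),
      ccbm = dedup(ccbm, "ccbm"))
}

#' Built-in default module catalog
#'
#' An implementer-curated default covering the role sets used throughout:
#' four exoglucanase GH families, seven endoglucanase GH families, seven
#' xylanase GH families, three LPMO families, and a set of cellulose-binding
#' CBM families compiled from CAZy activity documentation. GH9 appears in
#' both the exo- and endoglucanase sets (its predominant activity is
#' endoglucanase, EC 3.2.1.4, but exoglucanase activity, EC 3.2.1.91, is also
#' documented). The catalog is a stand-in for any lab-specific vocabulary and
#' is fully replaceable via [readCatalog()] without code changes.
#'
#' @return A [ModuleCatalog-class].
#' @examples
#' defaultCatalog()
#' @export
defaultCatalog <- function() {
  moduleCatalog(
    exoGH = c("GH6", "GH7", "GH9", "GH48"),
    endoGH = c("GH5", "GH8", "GH9", "GH12", "GH44", "GH45", "GH74"),
    xylanaseGH = c("GH10", "GH11", "GH30", "GH43", "GH62", "GH98", "GH141"),
    lpmo = c("AA9", "AA10", "AA11"),
    ccbm = c("CBM1", "CBM2", "CBM3", "CBM4", "CBM6", "CBM8", "CBM9",
             "CBM10", "CBM16", "CBM17", "CBM28", "CBM30", "CBM37",
             "CBM44", "CBM46", "CBM49", "CBM63", "CBM64"))
}

#' @describeIn moduleCatalog exoglucanase GH families.
#' @param x A `ModuleCatalog`.
#' @export
exoGH <- function(x) x@exoGH

#' @describeIn moduleCatalog endoglucanase GH families.
#' @export
endoGH <- function(x) x@endoGH

#' @describeIn moduleCatalog xylanase GH families.
#' @export
xylanaseGH <- function(x) x@xylanaseGH

#' @describeIn moduleCatalog LPMO families.
#' @export
lpmoFamilies <- function(x) x@lpmo

#' @describeIn moduleCatalog cellulose-binding CBM families.
#' @export
ccbmFamilies <- function(x) x@ccbm

#' @describeIn moduleCatalog the derived cGH role: union of exoglucanase,
#'   endoglucanase and LPMO families.
#' @export
cghFamilies <- function(x) unique(c(x@exoGH, x@endoGH, x@lpmo))

#' @describeIn moduleCatalog the fixed structural cellulosome modules
#'   (`SLH`, `cohesin`, `dockerin`).
#' @export
structuralModules <- function(x) .structuralModules

#' @describeIn moduleCatalog the default focal-module list for co-occurrence
#'   analysis: the exoglucanase, endoglucanase and xylanase GH families plus
#'   the three structural modules.
#' @export
focalModules <- function(x) {
  unique(c(x@exoGH, x@endoGH, x@xylanaseGH, .structuralModules))
}

setMethod("show", "ModuleCatalog", function(object) {
  cat("ModuleCatalog\n")
  cat("  exoglucanase GH :", paste(object@exoGH, collapse = ", "), "\n")
  cat("  endoglucanase GH:", paste(object@endoGH, collapse = ", "), "\n")
  cat("  xylanase GH     :", paste(object@xylanaseGH, collapse = ", "), "\n")
  cat("  LPMO            :", paste(object@lpmo, collapse = ", "), "\n")
  cat("  cCBM            :", length(object@ccbm), "cellulose-binding CBM families\n")
  cat("  structural      :", paste(.structuralModules, collapse = ", "),
      "(fixed)\n")
  cat("  cGH (derived)   :", length(cghFamilies(object)), "families\n")
})

#' Read a module catalog from a YAML or TSV file
#'
#' YAML layout: top-level keys are the role names `exo_gh`, `endo_gh`,
#' `xylanase_gh`, `lpmo`, `ccbm`, each a list of family labels. TSV layout:
#' two columns `role` and `family`, one row per (role, family) pair, with a
#' header. Unknown role keys are rejected; the structural modules are fixed
#' and must not be listed.
#'
#' @param path Path to a `.yml`/`.yaml` or `.tsv` catalog file.
#' @return A validated [ModuleCatalog-class].
#' @seealso [writeCatalog()]
#' @export
readCatalog <- function(path) {
  if (!file.exists(path)) stop("cannot read catalog file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    if (!is.list(raw)) stop("catalog YAML must map roles to family lists", call. = FALSE)
    roles <- lapply(raw, function(v) as.character(unlist(v)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("role", "family") %in% names(tab))) {
      stop("catalog TSV needs columns 'role' and 'family'", call. = FALSE)
    }
    roles <- split(tab$family, tab$role)
  }
  unknown <- setdiff(names(roles), .catalogRoles)
  if (length(unknown)) {
    stop("unknown role key(s) in catalog: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get0role <- function(r) if (r %in% names(roles)) roles[[r]] else character()
  moduleCatalog(exoGH = get0role("exo_gh"), endoGH = get0role("endo_gh"),
                xylanaseGH = get0role("xylanase_gh"), lpmo = get0role("lpmo"),
                ccbm = get0role("ccbm"))
}

#' Write a module catalog to a YAML file
#'
#' @param catalog A [ModuleCatalog-class].
#' @param path Output path (`.yml`).
#' @return The path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "ModuleCatalog"))
  yaml::write_yaml(list(exo_gh = as.list(catalog@exoGH),
                        endo_gh = as.list(catalog@endoGH),
                        xylanase_gh = as.list(catalog@xylanaseGH),
                        lpmo = as.list(catalog@lpmo),
                        ccbm = as.list(catalog@ccbm)), path)
  invisible(path)
}

#' MD5 checksum of a catalog's canonical serialization
#'
#' Used in logs so group labels are traceable to the vocabulary that produced
#' them.
#'
#' @param catalog A [ModuleCatalog-class].
#' @return A length-1 character MD5 digest.
#' @export
catalogChecksum <- function(catalog) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeCatalog(catalog, tmp)
  unname(tools::md5sum(tmp))
}

#' Roles of module families under a catalog
#'
#' Pure lookup from family label to role set. Labels are normalized and
#' subfamilies resolved to their parent family before lookup. The derived
#' role `cgh` is present whenever `exo`, `endo` or `lpmo` is. Families
#' unknown to the catalog get an empty role set.
#'
#' @param family Character vector of family labels.
#' @param catalog A [ModuleCatalog-class].
#' @return A named list (one element per input label) of character vectors
#'   drawn from `exo`, `endo`, `xylanase`, `lpmo`, `ccbm`, `slh`, `cohesin`,
#'   `dockerin`, `cgh`.
#' @examples
#' rolesOf(c("GH48", "SLH", "GT2"), defaultCatalog())
#' @export
rolesOf <- function(family, catalog) {
  stopifnot(is(catalog, "ModuleCatalog"))
  fam <- parentFamily(normalizeFamily(family))
  out <- lapply(fam, function(f) {
    r <- character()
    if (f %in% catalog@exoGH) r <- c(r, "exo")
    if (f %in% catalog@endoGH) r <- c(r, "endo")
    if (f %in% catalog@xylanaseGH) r <- c(r, "xylanase")
    if (f %in% catalog@lpmo) r <- c(r, "lpmo")
    if (any(c("exo", "endo", "lpmo") %in% r)) r <- c(r, "cgh")
    if (f %in% catalog@ccbm) r <- c(r, "ccbm")
    if (f == "SLH") r <- c(r, "slh")
    if (f == "cohesin") r <- c(r, "cohesin")
    if (f == "dockerin") r <- c(r, "dockerin")
    r
  })
  names(out) <- as.character(family)
  out
}
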