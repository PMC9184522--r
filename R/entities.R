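#' Canonical form of a protein entity
#'
#' An entity is one or more gene symbols; more than one denotes a heteromeric
#' complex. The canonical string form upper-cases and trims each subunit,
#' drops duplicates, sorts lexicographically and joins with \code{"_"}.
#' No alias resolution is attempted.
#'
#' @param x a single entity string, subunits joined by \code{"_"}
#' @return the canonical entity string
#' @examples
#' canonicalEntity("itgb1_Itga1")  # "ITGA1_ITGB1"
#' @export
canonicalEntity <- function(x) {
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    sub <- entitySubunits(x)
    if (length(sub) == 0L) stop("empty entity string")
    paste(sub, collapse = "_")
}

#' Subunit gene symbols of an entity
#'
#' @param x a single entity string
#' @return character vector of upper-cased, deduplicated, sorted subunits
#' @export
entitySubunits <- function(x) {
    sub <- toupper(trimws(strsplit(x, "_", fixed = TRUE)[[1]]))
    sub <- sub[nzchar(sub)]
    sort(unique(sub))
}

# vectorised canonicalisation
.canonVec <- function(x) vapply(x, canonicalEntity, "", USE.NAMES = FALSE)

# identity key for a (source, target, ligand, receptor) combination
.comboId <- function(source, target, ligand, receptor)
    paste(source, target, ligand, receptor, sep = "^")
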