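#' @import methods
#' @importFrom stats pbeta pnorm pwilcox quantile var sd median cor
#'   fisher.test p.adjust lm rnbinom rlnorm rgamma rnorm runif setNames
#'   complete.cases
#' @importFrom utils head read.delim write.table combn read.csv
NULL

#' Ligand-receptor interaction resource
#'
#' An S4 container for ligand-receptor prior knowledge. Each row of the
#' underlying table is one interaction between a transmitter (ligand-side)
#' entity and a receiver (receptor-side) entity. Entities may be heteromeric
#' complexes: subunit gene symbols are upper-cased, lexicographically sorted
#' and joined with \code{"_"}, which is the canonical form used for identity.
#'
#' @slot interactions a \code{data.frame} with character columns
#'   \code{source_genesymbol}, \code{target_genesymbol} (canonical entity
#'   strings), \code{resource} (provenance label), and optional
#'   \code{category} (semicolon-separated labels) and \code{curation_effort}
#'   (non-negative integer count of literature references).
#'
#' @seealso [lrResource()], [dissociateComplexes()], [overlapStats()]
#' @export
setClass("LRResource", representation(interactions = "data.frame"))

setValidity("LRResource", function(object) {
    tab <- object@interactions
    need <- c("source_genesymbol", "target_genesymbol", "resource")
    if (!all(need %in% colnames(tab)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(tab)), collapse = ", ")))
    if (nrow(tab) == 0L) return(TRUE)
    if (any(!nzchar(tab$source_genesymbol)) || any(!nzchar(tab$target_genesymbol)))
        return("empty entity strings")
    canon_s <- vapply(tab$source_genesymbol, canonicalEntity, "")
    canon_t <- vapply(tab$target_genesymbol, canonicalEntity, "")
    if (!identical(unname(canon_s), tab$source_genesymbol) ||
        !identical(unname(canon_t), tab$target_genesymbol))
        return("entity strings are not canonical (upper-case, sorted subunits)")
    id <- paste(tab$resource, tab$source_genesymbol, tab$target_genesymbol,
                sep = "\r")
    if (anyDuplicated(id))
        return("duplicate interaction identities within a resource")
    if ("curation_effort" %in% colnames(tab) &&
        any(tab$curation_effort < 0, na.rm = TRUE))
        return("negative curation_effort")
    TRUE
})

#' Per-gene, per-cluster summary statistics
#'
#' Holds every cluster-level summary the scoring systems consume: linear and
#' log-scale cluster means, the fraction of expressing cells, one-vs-rest
#' log2 fold changes, cross-cluster z-scores of the log means, one-vs-rest
#' Wilcoxon p-values, and the dataset-wide mean \code{mu} of the normalized
#' layer (the regularisation constant of the SingleCellSignalR LRscore).
#'
#' @slot meanLin genes x clusters matrix of de-logged normalized means.
#' @slot meanLog genes x clusters matrix of means of the log-normalized layer.
#' @slot prop genes x clusters matrix, fraction of cells expressing.
#' @slot log2fc genes x clusters matrix, one-vs-rest log2 fold change.
#' @slot zscore genes x clusters matrix, z-score of cluster log means.
#' @slot deP genes x clusters matrix, two-sided one-vs-rest Wilcoxon p.
#' @slot mu numeric(1), mean over all entries of the normalized matrix.
#' @slot nCells named integer, cells per cluster.
#'
#' @seealso [summarizeClusters()], [entityClusterSummary()]
#' @export
setClass("ClusterStats", representation(
    meanLin = "matrix", meanLog = "matrix", prop = "matrix",
    log2fc = "matrix", zscore = "matrix", deP = "matrix",
    mu = "numeric", nCells = "integer"))

setValidity("ClusterStats", function(object) {
    dims <- lapply(list(object@meanLin, object@meanLog, object@prop,
                        object@log2fc, object@zscore, object@deP), dim)
    if (length(unique(dims)) != 1L) return("matrix dimensions differ")
    if (ncol(object@meanLin) < 2L) return("need >= 2 clusters")
    if (length(object@mu) != 1L || !is.finite(object@mu))
        return("mu must be a finite scalar")
    if (any(object@prop < 0 | object@prop > 1)) return("prop outside [0,1]")
    if (any(object@deP < 0 | object@deP > 1, na.rm = TRUE))
        return("de_p outside [0,1]")
    TRUE
})

#' @describeIn LRResource number of interaction records
#' @param x an \code{LRResource}
#' @export
setMethod("length", "LRResource", function(x) nrow(x@interactions))

setMethod("show", "LRResource", function(object) {
    tab <- object@interactions
    res <- unique(tab$resource)
    cat("LRResource with", nrow(tab), "interactions from",
        length(res), if (length(res) == 1L) "resource\n" else "resources\n")
    ncx <- sum(grepl("_", tab$source_genesymbol) |
               grepl("_", tab$target_genesymbol))
    cat("  complex-containing records:", ncx, "\n")
    if (length(res) <= 8L) cat("  resources:", paste(res, collapse = ", "), "\n")
})

setMethod("show", "ClusterStats", function(object) {
    cat("ClusterStats:", nrow(object@meanLog), "genes x",
        ncol(object@meanLog), "clusters\n")
    cat("  cells per cluster:", paste0(names(object@nCells), "=",
        object@nCells, collapse = ", "), "\n")
    cat("  dataset mean (mu):", signif(object@mu, 4), "\n")
})

#' @rdname ClusterStats-accessors
#' @name ClusterStats-accessors
#' @title Accessors for ClusterStats
#' @param x a \code{ClusterStats} object
#' @param which one of \code{"mean_lin"}, \code{"mean_log"}, \code{"prop"},
#'   \code{"log2fc"}, \code{"zscore"}, \code{"de_p"}
#' @return \code{statMatrix}: the requested genes x clusters matrix;
#'   \code{datasetMean}: the scalar mean of the normalized layer;
#'   \code{clusterNames}/\code{geneNames}: character vectors.
#' @export
statMatrix <- function(x, which = c("mean_lin", "mean_log", "prop",
                                    "log2fc", "zscore", "de_p")) {
    stopifnot(is(x, "ClusterStats"))
    switch(match.arg(which),
           mean_lin = x@meanLin, mean_log = x@meanLog, prop = x@prop,
           log2fc = x@log2fc, zscore = x@zscore, de_p = x@deP)
}

#' @rdname ClusterStats-accessors
#' @export
datasetMean <- function(x) { stopifnot(is(x, "ClusterStats")); x@mu }

#' @rdname ClusterStats-accessors
#' @export
clusterNames <- function(x) { stopifnot(is(x, "ClusterStats")); colnames(x@meanLog) }

#' @rdname ClusterStats-accessors
#' @export
geneNames <- function(x) { stopifnot(is(x, "ClusterStats")); rownames(x@meanLog) }

#' @rdname LRResource-accessors
#' @name LRResource-accessors
#' @title Accessors for LRResource
#' @param x an \code{LRResource}
#' @param ... unused
#' @return \code{interactions}: the underlying \code{data.frame}.
#' @export
interactions <- function(x) { stopifnot(is(x, "LRResource")); x@interactions }

#' @rdname LRResource-accessors
#' @param row.names,optional see \code{\link[base]{as.data.frame}}
#' @export
as.data.frame.LRResource <- function(x, row.names = NULL, optional = FALSE, ...)
    x@interactions
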