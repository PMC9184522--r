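#' Library-size normalize and log-transform counts
#'
#' Scales each cell to a common total, then applies \code{ln(1 + x)}.
#'
#' @param counts genes x cells non-negative matrix (dense or sparse)
#' @param target_sum per-cell total after scaling (default 10000)
#' @return dense genes x cells matrix of log-normalized expression
#' @examples
#' m <- matrix(c(9, 0), 2, 1, dimnames = list(c("A", "B"), "c1"))
#' normalizeCounts(m, target_sum = 9)[1, 1]  # log(10)
#' @export
normalizeCounts <- function(counts, target_sum = 1e4) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative counts")
    tot <- colSums(counts)
    if (any(tot == 0)) {
        bad <- colnames(counts)[tot == 0]
        if (is.null(bad)) bad <- which(tot == 0)
        stop("cells with zero total counts: ",
             paste(head(bad, 5), collapse = ", "))
    }
    log1p(sweep(counts, 2, target_sum / tot, "*"))
}

# Extract (norm matrix, counts-or-NULL, cluster factor) from supported inputs
.datasetParts <- function(x, clusters = NULL) {
    if (is(x, "SummarizedExperiment")) {
        anames <- SummarizedExperiment::assayNames(x)
        norm <- if ("logcounts" %in% anames)
            as.matrix(SummarizedExperiment::assay(x, "logcounts"))
        else normalizeCounts(SummarizedExperiment::assay(x, "counts"))
        counts <- if ("counts" %in% anames)
            as.matrix(SummarizedExperiment::assay(x, "counts")) else NULL
        if (is.null(clusters)) {
            cd <- SummarizedExperiment::colData(x)
            if (!"cluster" %in% colnames(cd))
                stop("colData lacks a 'cluster' column")
            clusters <- cd$cluster
        }
    } else {
        norm <- as.matrix(x)
        counts <- NULL
        if (is.null(clusters)) stop("clusters required for matrix input")
    }
    if (length(clusters) != ncol(norm)) stop("cluster labels do not match cells")
    if (any(is.na(clusters) | !nzchar(as.character(clusters)))) {
        bad <- colnames(norm)[is.na(clusters) | !nzchar(as.character(clusters))]
        stop("unlabelled cells: ", paste(head(bad, 5), collapse = ", "))
    }
    list(norm = norm, counts = counts,
         clusters = factor(as.character(clusters)))
}

# Vectorised two-sided one-vs-rest Wilcoxon rank-sum p-values.
# Exact via pwilcox when a gene has no ties and both groups < 50; otherwise
# normal approximation with tie and continuity correction (as wilcox.test).
# Per-gene ranks and tie terms are computed once and reused across clusters.
.wilcoxonPrep <- function(norm) {
    n <- ncol(norm)
    ranks <- matrix(0, nrow(norm), n)
    tieterm <- numeric(nrow(norm))
    hasties <- logical(nrow(norm))
    for (g in seq_len(nrow(norm))) {
        xg <- norm[g, ]
        ranks[g, ] <- rank(xg)
        tt <- rle(sort(xg))$lengths
        tieterm[g] <- sum(tt^3 - tt)
        hasties[g] <- length(tt) < n
    }
    list(ranks = ranks, tieterm = tieterm, hasties = hasties, n = n)
}

.wilcoxonFromPrep <- function(prep, in_group) {
    n <- prep$n; n1 <- sum(in_group); n2 <- n - n1
    if (n1 == 0L || n2 == 0L) return(rep(NA_real_, nrow(prep$ranks)))
    tieterm <- prep$tieterm; hasties <- prep$hasties
    W1 <- prep$ranks[, in_group, drop = FALSE] %*% rep(1, n1)
    U <- as.numeric(W1) - n1 * (n1 + 1) / 2
    p <- rep(NA_real_, nrow(prep$ranks))
    exact <- !hasties & n1 < 50 & n2 < 50
    if (any(exact)) {
        u <- U[exact]
        lo <- pwilcox(u, n1, n2)
        hi <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
        p[exact] <- pmin(1, 2 * pmin(lo, hi))
    }
    if (any(!exact)) {
        sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieterm[!exact] / (n * (n - 1)))
        z <- U[!exact] - n1 * n2 / 2
        z <- z - sign(z) * 0.5  # continuity correction
        pv <- 2 * pnorm(-abs(z) / sqrt(sigma2))
        pv[sigma2 <= 0] <- 1
        p[!exact] <- pmin(1, pv)
    }
    p
}

#' One-vs-rest Wilcoxon rank-sum p-values for each row
#'
#' Two-sided p-values comparing, per gene, the cells of one group against all
#' others. Exact (via the null rank-sum distribution) for untied genes with
#' both group sizes below 50, else a normal approximation with tie and
#' continuity corrections, mirroring \code{stats::wilcox.test}.
#'
#' @param norm genes x cells numeric matrix
#' @param in_group logical vector over cells
#' @return numeric vector of p-values, one per row
#' @export
wilcoxonRankSumP <- function(norm, in_group) {
    norm <- as.matrix(norm)
    stopifnot(length(in_group) == ncol(norm), is.logical(in_group))
    .wilcoxonFromPrep(.wilcoxonPrep(norm), in_group)
}

#' Summarize expression per gene and cluster
#'
#' Computes every cluster-level statistic the scoring systems need: cluster
#' means of the log-normalized layer and of its de-logged values, the
#' fraction of expressing cells, one-vs-rest log2 fold changes
#' \code{log2((mean_lin_in + 1)/(mean_lin_rest + 1))}, z-scores of each
#' gene's cluster log-means across clusters (0 when the cross-cluster sd is
#' 0), one-vs-rest Wilcoxon p-values on the log-normalized values, and the
#' dataset-wide mean \code{mu} of the normalized layer.
#'
#' @param x a \code{SingleCellExperiment}/\code{SummarizedExperiment} with a
#'   \code{logcounts} assay (computed from \code{counts} when absent) and a
#'   \code{cluster} column in \code{colData}, or a genes x cells
#'   log-normalized matrix
#' @param clusters cluster labels per cell (required for matrix input)
#' @param compute_de compute Wilcoxon p-values (the slowest part); when
#'   \code{FALSE} the \code{de_p} slot is all-\code{NA}
#' @return a [ClusterStats-class]
#' @export
setGeneric("summarizeClusters", function(x, clusters = NULL,
                                         compute_de = TRUE)
    standardGeneric("summarizeClusters"))

.summarizeClustersImpl <- function(norm, clusters, compute_de = TRUE) {
    cl <- factor(as.character(clusters))
    if (nlevels(cl) < 2L) stop("need >= 2 clusters")
    small <- table(cl) < 3L
    if (any(small))
        warning("clusters with < 3 cells: ",
                paste(names(which(small)), collapse = ", "))
    if (is.null(rownames(norm)))
        rownames(norm) <- paste0("G", seq_len(nrow(norm)))
    n <- ncol(norm)
    ind <- stats::model.matrix(~ 0 + cl)
    colnames(ind) <- levels(cl)
    sizes <- colSums(ind)
    sumLog <- norm %*% ind
    lin <- expm1(norm)
    sumLin <- lin %*% ind
    meanLog <- sweep(sumLog, 2, sizes, "/")
    meanLin <- sweep(sumLin, 2, sizes, "/")
    prop <- sweep((norm > 0) %*% ind, 2, sizes, "/")
    totLin <- rowSums(sumLin)
    restMean <- (totLin - sumLin) / matrix(n - sizes, nrow(norm),
                                           length(sizes), byrow = TRUE)
    log2fc <- log2((meanLin + 1) / (restMean + 1))
    mrow <- rowMeans(meanLog)
    srow <- apply(meanLog, 1, sd)
    zscore <- (meanLog - mrow) / ifelse(srow == 0, Inf, srow)
    deP <- matrix(NA_real_, nrow(norm), nlevels(cl),
                  dimnames = list(rownames(norm), levels(cl)))
    if (compute_de) {
        prep <- .wilcoxonPrep(norm)
        for (c_ in levels(cl))
            deP[, c_] <- .wilcoxonFromPrep(prep, cl == c_)
    }
    dn <- list(rownames(norm), levels(cl))
    fix <- function(m) { dimnames(m) <- dn; as.matrix(m) }
    new("ClusterStats",
        meanLin = fix(meanLin), meanLog = fix(meanLog), prop = fix(prop),
        log2fc = fix(log2fc), zscore = fix(zscore), deP = deP,
        mu = mean(norm),
        nCells = setNames(as.integer(sizes), levels(cl)))
}

#' @rdname summarizeClusters
#' @export
setMethod("summarizeClusters", "ANY", function(x, clusters = NULL,
                                               compute_de = TRUE) {
    parts <- .datasetParts(x, clusters)
    .summarizeClustersImpl(parts$norm, parts$clusters, compute_de)
})

#' Cluster summary of a (possibly complex) entity
#'
#' For a heteromeric complex the representative subunit in each cluster is
#' the one with the minimum cluster log-mean (lexicographic subunit order
#' breaks ties); every field is taken from that subunit except \code{prop},
#' which is the minimum across subunits. An entity with any subunit absent
#' from the statistics is undetected.
#'
#' @param entity entity string (subunits joined by \code{"_"})
#' @param cluster cluster label
#' @param stats a [ClusterStats-class]
#' @return list with \code{mean_lin}, \code{mean_log}, \code{prop},
#'   \code{log2fc}, \code{zscore}, \code{detected}
#' @export
entityClusterSummary <- function(entity, cluster, stats) {
    stopifnot(is(stats, "ClusterStats"))
    sub <- entitySubunits(entity)
    genes <- geneNames(stats)
    if (!all(sub %in% genes))
        return(list(mean_lin = NA_real_, mean_log = NA_real_,
                    prop = NA_real_, log2fc = NA_real_, zscore = NA_real_,
                    detected = FALSE))
    ml <- stats@meanLog[sub, cluster]
    pick <- sub[which.min(ml)]  # sub is sorted: ties break lexicographically
    list(mean_lin = stats@meanLin[pick, cluster],
         mean_log = stats@meanLog[pick, cluster],
         prop = min(stats@prop[sub, cluster]),
         log2fc = stats@log2fc[pick, cluster],
         zscore = stats@zscore[pick, cluster],
         detected = TRUE)
}
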