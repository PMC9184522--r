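#' Top-ranked interactions, ties included
#'
#' Keeps every interaction whose rank is at or below the rank of the k-th
#' item, so ties crossing the boundary are retained and the returned set may
#' exceed the nominal k.
#'
#' @param ranking output of [rankInteractions()] (a scored table with a
#'   \code{rank} column)
#' @param k number of interactions to keep
#' @param fraction alternatively, the top fraction in (0, 1] of the ranking
#'   universe (k is its ceiling)
#' @param label,resource optional labels carried on the result for grouping
#' @return an object of class \code{TopSet}: list with \code{ids}
#'   (interaction identity strings), \code{table} (the kept rows),
#'   \code{nominal_k}, \code{label}, \code{method}, \code{resource}
#' @export
topRanked <- function(ranking, k = 1000, fraction = NULL, label = NULL,
                      resource = NA_character_) {
    if (!"rank" %in% colnames(ranking))
        stop("ranking must carry a rank column (see rankInteractions)")
    n <- nrow(ranking)
    if (!is.null(fraction)) {
        stopifnot(fraction > 0, fraction <= 1)
        k <- ceiling(fraction * n)
    }
    if (k < 1) stop("k must be >= 1")
    if (k > n) {
        warning("k exceeds the universe; returning all interactions")
        k <- n
    }
    cutoff <- sort(ranking$rank, partial = k)[k]
    keep <- ranking[ranking$rank <= cutoff, , drop = FALSE]
    method <- if ("method" %in% colnames(keep) && nrow(keep))
        unique(keep$method)[1] else NA_character_
    structure(list(
        ids = .comboId(keep$source, keep$target, keep$ligand_complex,
                       keep$receptor_complex),
        table = keep, nominal_k = k,
        label = if (is.null(label)) paste(method, resource, sep = "|")
                else label,
        method = method, resource = resource), class = "TopSet")
}

#' @export
print.TopSet <- function(x, ...) {
    cat("TopSet", x$label, ":", length(x$ids), "interactions (nominal k =",
        x$nominal_k, ")\n")
    invisible(x)
}

#' Pairwise Jaccard overlap of top sets
#'
#' Jaccard index between the interaction-identity sets of each pair of runs,
#' plus the median pairwise index among runs sharing a method (overlap
#' across resources) or sharing a resource (overlap across methods).
#'
#' @param topsets list of \code{TopSet} objects (>= 2)
#' @param group_by \code{"method"} or \code{"resource"}: medians are taken
#'   over off-diagonal pairs within each group
#' @return list with \code{jaccard} matrix and \code{group_medians}
#' @export
jaccardMatrix <- function(topsets, group_by = c("method", "resource")) {
    group_by <- match.arg(group_by)
    if (length(topsets) < 2L) stop("need >= 2 top sets")
    labels <- vapply(topsets, `[[`, "", "label")
    n <- length(topsets)
    J <- matrix(1, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        a <- topsets[[i]]$ids; b <- topsets[[j]]$ids
        u <- length(union(a, b))
        J[i, j] <- J[j, i] <- if (u == 0L) 0 else
            length(intersect(a, b)) / u
    }
    grp <- vapply(topsets, function(t) as.character(t[[group_by]]), "")
    meds <- vapply(unique(grp), function(g) {
        idx <- which(grp == g)
        if (length(idx) < 2L) return(NA_real_)
        median(J[idx, idx][upper.tri(J[idx, idx])])
    }, 0)
    list(jaccard = J, group_medians = meds)
}

#' Cell-type interaction frequencies in a top set
#'
#' The proportion of top-ranked interactions that stem from (role
#' \code{"source"}) or lead to (role \code{"target"}) each cluster.
#'
#' @param topset a \code{TopSet}
#' @param role \code{"source"} or \code{"target"}
#' @return \code{data.frame(cluster, frequency)}; frequencies sum to 1
#' @export
celltypeFrequencies <- function(topset, role = c("source", "target")) {
    role <- match.arg(role)
    tab <- topset$table
    if (nrow(tab) == 0L) stop("empty top set")
    f <- table(tab[[role]]) / nrow(tab)
    data.frame(cluster = names(f), frequency = as.numeric(f),
               stringsAsFactors = FALSE)
}

#' Relative interaction strength per cell type
#'
#' Min-max scales a method's scores to \[0, 1\], then divides the mean scaled
#' score of each cluster's edges (as source and as target) by the mean
#' scaled score over all predictions. Values above 1 mark clusters holding
#' stronger-than-average predicted interactions.
#'
#' @param scored long-format scored table
#' @param method method label present in \code{scored}
#' @param score_col which score to regularise (default the method's ranking
#'   score: specificity where defined, magnitude for \code{sca})
#' @return \code{data.frame(cluster, role, rel_strength)}
#' @export
relativeStrength <- function(scored, method, score_col = NULL) {
    tab <- scored[scored$method == method, , drop = FALSE]
    if (nrow(tab) == 0L) stop("method not present: ", method)
    if (is.null(score_col))
        score_col <- if (method %in% c("sca", "cellphonedb"))
            "score_magnitude" else "score_specificity"
    v <- tab[[score_col]]
    rng <- range(v)
    if (rng[1] == rng[2]) {
        warning("constant scores; scaled values set to 0.5")
        sv <- rep(0.5, length(v))
    } else sv <- (v - rng[1]) / (rng[2] - rng[1])
    overall <- mean(sv)
    out <- do.call(rbind, lapply(c("source", "target"), function(role) {
        m <- tapply(sv, tab[[role]], mean)
        data.frame(cluster = names(m), role = role,
                   rel_strength = as.numeric(m) / overall,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
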