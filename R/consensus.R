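#' Recommended ranking key per scoring method
#'
#' Orders a method's scored interactions by its recommended single-condition
#' key: ascending permutation p (magnitude breaks ties) for
#' \code{cellphonedb}; descending \code{weight_scale} for \code{connectome};
#' descending specificity for \code{natmi}; descending LRscore for
#' \code{sca}; descending mean log2FC for \code{logfc}; descending crosstalk
#' score for \code{crosstalk}; ascending corrected score for
#' \code{consensus}.
#'
#' @param scored long-format scored table (one method, or filtered to one)
#' @param method method label
#' @return the scored table with a \code{rank} column (1 = most preferred,
#'   average ranks on ties), ordered by rank
#' @export
rankInteractions <- function(scored, method) {
    if (!missing(method)) scored <- scored[scored$method == method, ,
                                           drop = FALSE]
    m <- unique(scored$method)
    if (length(m) != 1L) stop("rankInteractions expects a single method")
    if (!m %in% c(scoringMethods(), "consensus"))
        stop("unknown method label: ", m)
    if (m == "cellphonedb") {
        ord <- order(scored$p_value, -scored$score_magnitude)
        pos <- integer(nrow(scored)); pos[ord] <- seq_len(nrow(scored))
        key <- paste(scored$p_value, scored$score_magnitude)
        r <- stats::ave(pos, key, FUN = mean)
    } else {
        v <- switch(m,
            connectome = -scored$score_specificity,
            natmi = -scored$score_specificity,
            sca = -scored$score_magnitude,
            logfc = -scored$score_specificity,
            crosstalk = -scored$score_specificity,
            consensus = scored$score_magnitude)
        r <- rank(v, ties.method = "average")
    }
    scored$rank <- r
    scored[order(scored$rank), , drop = FALSE]
}

#' Normalized rank matrix across methods
#'
#' Rows are interaction identities (the union universe across all methods'
#' post-filter predictions), columns are methods. Entries are within-method
#' ranks divided by the universe size, so they lie in (0, 1]; interactions a
#' method filtered out are imputed at the maximum rank 1.
#'
#' @param scored long-format scored table holding several methods
#' @param methods methods to include (default: those present)
#' @return numeric matrix with interaction-identity rownames
#' @export
buildRankMatrix <- function(scored, methods = NULL) {
    if (is.null(methods)) methods <- unique(scored$method)
    ids_all <- unique(.comboId(scored$source, scored$target,
                               scored$ligand_complex,
                               scored$receptor_complex))
    U <- length(ids_all)
    M <- matrix(1, U, length(methods), dimnames = list(ids_all, methods))
    for (m in methods) {
        rk <- rankInteractions(scored, m)
        ids <- .comboId(rk$source, rk$target, rk$ligand_complex,
                        rk$receptor_complex)
        M[ids, m] <- rk$rank / U
    }
    M
}

#' Robust rank aggregation
#'
#' For each row of normalized ranks \code{r(1) <= ... <= r(K)}, the rho
#' statistic is the minimum over k of the Beta(k, K - k + 1) CDF evaluated
#' at \code{r(k)} (the probability that the k-th uniform order statistic is
#' at most \code{r(k)}), and the corrected score is the Bonferroni-adjusted
#' \code{min(rho K, 1)}. Small corrected scores mark interactions
#' consistently ranked high across methods.
#'
#' @param rank_matrix matrix from [buildRankMatrix()]; entries in (0, 1]
#' @return \code{data.frame(interaction, rho, corrected_score)}, ascending
#'   by corrected score
#' @examples
#' aggregateRRA(matrix(c(0.1, 0.2, 0.3), 1, 3,
#'                     dimnames = list("a", NULL)))  # rho 0.027
#' @export
aggregateRRA <- function(rank_matrix) {
    rank_matrix <- as.matrix(rank_matrix)
    if (any(rank_matrix <= 0 | rank_matrix > 1))
        stop("normalized ranks must lie in (0, 1]")
    if (is.null(rownames(rank_matrix)))
        rownames(rank_matrix) <- as.character(seq_len(nrow(rank_matrix)))
    K <- ncol(rank_matrix)
    rho <- apply(rank_matrix, 1, function(r) {
        r <- sort(r)
        min(pbeta(r, seq_len(K), K - seq_len(K) + 1))
    })
    out <- data.frame(interaction = rownames(rank_matrix), rho = rho,
                      corrected_score = pmin(rho * K, 1),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$corrected_score, out$rho), , drop = FALSE]
}

#' Append a consensus ranking to a scored table
#'
#' Builds the normalized rank matrix over all methods present, aggregates it
#' with [aggregateRRA()], and appends rows with \code{method = "consensus"},
#' \code{score_magnitude} the corrected score and \code{score_specificity}
#' its complement \code{1 - corrected_score}.
#'
#' @param scored long-format scored table with >= 1 method
#' @return the input with consensus rows appended; the aggregation table is
#'   attached as attribute \code{"rra"}
#' @export
consensusRank <- function(scored) {
    M <- buildRankMatrix(scored)
    agg <- aggregateRRA(M)
    parts <- strsplit(agg$interaction, "^", fixed = TRUE)
    cons <- data.frame(source = vapply(parts, `[`, "", 1),
                       target = vapply(parts, `[`, "", 2),
                       ligand_complex = vapply(parts, `[`, "", 3),
                       receptor_complex = vapply(parts, `[`, "", 4),
                       method = "consensus",
                       score_magnitude = agg$corrected_score,
                       score_specificity = 1 - agg$corrected_score,
                       p_value = NA_real_, stringsAsFactors = FALSE)
    out <- rbind(scored[, colnames(cons), drop = FALSE], cons)
    attr(out, "rra") <- agg
    out
}
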