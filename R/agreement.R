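#' Pseudobulk expression profiles per cluster
#'
#' Sums raw counts within each cluster and log2-transforms (\code{log2(1 +
#' sum)}). Per cluster, genes expressed in fewer than 10 percent of the
#' cluster's cells or with a summed raw count not above 5 are dropped from
#' that cluster's profile (reported as \code{NA}).
#'
#' @param counts genes x cells raw count matrix
#' @param clusters cluster labels per cell
#' @param min_prop minimum fraction of expressing cells (default 0.10,
#'   inclusive)
#' @param min_count summed-count threshold; genes kept when the sum is
#'   strictly above it (default 5)
#' @return genes x clusters matrix; filtered entries are \code{NA}
#' @export
buildPseudobulk <- function(counts, clusters, min_prop = 0.10,
                            min_count = 5) {
    counts <- as.matrix(counts)
    cl <- if (is.factor(clusters)) clusters else factor(as.character(clusters))
    if (any(table(cl) == 0L)) stop("empty cluster")
    cl <- droplevels(cl)
    ind <- stats::model.matrix(~ 0 + cl)
    colnames(ind) <- levels(cl)
    sizes <- colSums(ind)
    sums <- counts %*% ind
    prop <- sweep((counts > 0) %*% ind, 2, sizes, "/")
    out <- log2(1 + sums)
    out[!(prop >= min_prop & sums > min_count)] <- NA_real_
    dimnames(out) <- list(rownames(counts), levels(cl))
    as.matrix(out)
}

#' Cytokine activities by multivariate linear model
#'
#' Regresses one cluster's pseudobulk profile jointly on all cytokine
#' signature columns (intercept included). The activity score of each
#' cytokine is its coefficient t-value; p-values are two-sided and
#' Benjamini-Hochberg corrected across cytokines.
#'
#' @param profile named numeric vector (one pseudobulk column; \code{NA}
#'   entries are dropped)
#' @param signatures genes x cytokines numeric weight matrix
#' @param min_genes minimum shared genes required (default 5)
#' @return \code{data.frame(cytokine, score, p, fdr)}
#' @export
mlmActivities <- function(profile, signatures, min_genes = 5) {
    signatures <- as.matrix(signatures)
    if (ncol(signatures) < 2L) stop("need >= 2 cytokine signatures")
    profile <- profile[!is.na(profile)]
    genes <- intersect(names(profile), rownames(signatures))
    if (length(genes) < min_genes)
        stop("fewer than ", min_genes, " genes shared with the signatures")
    X <- signatures[genes, , drop = FALSE]
    y <- profile[genes]
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
        drop_col <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L,
                                              ncol(X) + 1L)] - 1L]
        stop("rank-deficient signature design; collinear signatures: ",
             paste(drop_col, collapse = ", "))
    }
    fit <- lm(y ~ X)
    cf <- summary(fit)$coefficients[-1, , drop = FALSE]
    data.frame(cytokine = colnames(X), score = cf[, "t value"],
               p = cf[, "Pr(>|t|)"],
               fdr = p.adjust(cf[, "Pr(>|t|)"], method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

.modalityCalls <- function(positive, negative) {
    stopifnot(length(intersect(positive, negative)) == 0L)
    structure(list(positive = positive, negative = negative,
                   universe = c(positive, negative)),
              class = "ModalityCalls")
}

#' @export
print.ModalityCalls <- function(x, ...) {
    cat("ModalityCalls:", length(x$positive), "positive /",
        length(x$negative), "negative\n")
    invisible(x)
}

#' Call active cytokines per cluster
#'
#' A (cytokine, cluster) pair is positive when its activity score is
#' positive and the FDR-corrected p-value is at or below 0.05; the remainder
#' of the signature x cluster universe is negative. Keys are
#' \code{"cytokine|cluster"}.
#'
#' @param activities named list of [mlmActivities()] tables, one per cluster
#' @param fdr_threshold default 0.05 (inclusive)
#' @return a \code{ModalityCalls} object
#' @export
callActiveCytokines <- function(activities, fdr_threshold = 0.05) {
    pos <- character(); neg <- character()
    for (cluster in names(activities)) {
        tab <- activities[[cluster]]
        key <- paste(tab$cytokine, cluster, sep = "|")
        hit <- tab$score > 0 & tab$fdr <= fdr_threshold
        pos <- c(pos, key[hit]); neg <- c(neg, key[!hit])
    }
    .modalityCalls(pos, neg)
}

.pairKey <- function(a, b) {
    swap <- a > b
    paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

#' Colocalized cluster pairs from spot proportions
#'
#' Correlates cluster proportion vectors across spatial spots (Pearson),
#' z-scales the off-diagonal coefficient distribution, and calls a cluster
#' pair colocalized when its z-score is at least 1.645. Pairs are unordered;
#' a constant proportion column makes its correlations undefined and those
#' pairs negative, with a warning.
#'
#' @param proportions spots x clusters matrix; rows should sum to about 1
#' @param z_threshold default 1.645 (inclusive)
#' @param min_spots minimum rows required (default 10)
#' @return a \code{ModalityCalls} over \code{"A|B"} cluster-pair keys, with
#'   the z-score table attached as attribute \code{"z"}
#' @export
colocalizationFromProportions <- function(proportions, z_threshold = 1.645,
                                          min_spots = 10) {
    P <- as.matrix(proportions)
    if (nrow(P) < min_spots) stop("need >= ", min_spots, " spots")
    if (any(abs(rowSums(P) - 1) > 0.05))
        warning("spot proportions do not sum to 1")
    cm <- suppressWarnings(cor(P))
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    vals <- cm[ut]
    if (anyNA(vals)) {
        warning("constant proportion columns; affected pairs set negative")
    }
    z <- (vals - mean(vals, na.rm = TRUE)) / sd(vals, na.rm = TRUE)
    keys <- .pairKey(colnames(P)[ut[, 1]], colnames(P)[ut[, 2]])
    hit <- !is.na(z) & z >= z_threshold
    out <- .modalityCalls(keys[hit], keys[!hit])
    attr(out, "z") <- data.frame(pair = keys, cor = vals, z = z,
                                 stringsAsFactors = FALSE)
    out
}

#' Colocalized cluster pairs from neighborhood-enrichment z-scores
#'
#' Thresholds a pairwise neighborhood-enrichment z-score matrix at 1.645.
#' Calls are made over unordered pairs using the larger of the two directed
#' entries, so a symmetric input yields symmetric calls.
#'
#' @param zmat square clusters x clusters z-score matrix
#' @param z_threshold default 1.645 (inclusive)
#' @param include_self include autocrine (diagonal) pairs (default FALSE)
#' @return a \code{ModalityCalls} over \code{"A|B"} keys
#' @export
colocalizationFromZscores <- function(zmat, z_threshold = 1.645,
                                      include_self = FALSE) {
    Z <- as.matrix(zmat)
    if (nrow(Z) != ncol(Z)) stop("z-score matrix must be square")
    idx <- which(upper.tri(Z, diag = include_self), arr.ind = TRUE)
    zz <- pmax(Z[idx], Z[cbind(idx[, 2], idx[, 1])])
    keys <- .pairKey(rownames(Z)[idx[, 1]], colnames(Z)[idx[, 2]])
    hit <- zz >= z_threshold
    .modalityCalls(keys[hit], keys[!hit])
}

#' Odds-ratio agreement curve over rank intervals
#'
#' At each rank cutoff N, cross-tabulates membership in the top N of the
#' ranking against the positive/negative modality call and reports the
#' sample odds ratio (Haldane-corrected on zero cells) with the two-sided
#' exact-test p-value on the raw counts. The ranking is first restricted to
#' interactions mappable into the calls' universe.
#'
#' @param ranking output of [rankInteractions()] (ordered, with \code{rank})
#' @param calls a \code{ModalityCalls}
#' @param key_fun function mapping one row of the ranking to a call key (or
#'   \code{NA} when unmappable)
#' @param cutoffs strictly increasing rank cutoffs (default
#'   \code{c(100, 250, 500, 1000, 2500, 5000, 10000)}, the span used for
#'   rank-interval evaluation)
#' @return \code{data.frame(cutoff, odds_ratio, fisher_p, n_top, n_pos,
#'   capped)}; \code{capped} flags tables with a zero cell, whose otherwise
#'   infinite (or zero) sample odds ratio is reported under the Haldane
#'   correction
#' @export
oddsRatioCurve <- function(ranking, calls, key_fun,
                           cutoffs = c(100, 250, 500, 1000, 2500, 5000,
                                       10000)) {
    if (any(diff(cutoffs) <= 0)) stop("cutoffs must be strictly increasing")
    keys <- vapply(seq_len(nrow(ranking)),
                   function(i) as.character(key_fun(ranking[i, ])), "")
    ok <- !is.na(keys) & keys %in% calls$universe
    if (!any(ok)) stop("no interactions map into the calls' universe")
    ranking <- ranking[ok, , drop = FALSE]
    keys <- keys[ok]
    ord <- order(ranking$rank)
    ranking <- ranking[ord, , drop = FALSE]
    keys <- keys[ord]
    is_pos <- keys %in% calls$positive
    n <- nrow(ranking)
    rows <- lapply(cutoffs, function(N) {
        top <- seq_len(n) <= min(N, n)
        a <- sum(top & is_pos); b <- sum(top & !is_pos)
        c_ <- sum(!top & is_pos); d <- sum(!top & !is_pos)
        data.frame(cutoff = N,
                   odds_ratio = sampleOddsRatio(c(a, b, c_, d)),
                   fisher_p = fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                   n_top = sum(top), n_pos = a,
                   capped = any(c(a, b, c_, d) == 0))
    })
    do.call(rbind, rows)
}

#' Centred log-ratio transform of abundance profiles
#'
#' \code{clr(x) = ln(x + 1) - mean(ln(x + 1))}, applied per profile
#' (column).
#'
#' @param x receptors x clusters (or features x cells) non-negative matrix
#' @return transformed matrix
#' @export
clrTransform <- function(x) {
    lx <- log(as.matrix(x) + 1)
    sweep(lx, 2, colMeans(lx), "-")
}

# area under the precision-recall step curve, scores descending
.auprc <- function(scores, labels) {
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]
    tp <- cumsum(lab)
    fp <- cumsum(!lab)
    prec <- tp / (tp + fp)
    rec <- tp / sum(lab)
    sum(diff(c(0, rec)) * prec)
}

#' Evaluate predictions against receptor protein specificity
#'
#' Positives are (receptor, cluster) cells whose protein abundance z-score
#' across clusters (after an optional centred log-ratio transform) is at
#' least 1.645. AUROC is computed over the supplied prediction scores;
#' AUPRC is the mean over seeded draws in which the negative class is
#' downsampled to the number of positives, binding the random expectation to
#' 0.5.
#'
#' @param predictions \code{data.frame(receptor, cluster, score)}; pairs
#'   of the abundance universe without a prediction rank last
#' @param abundance receptors x clusters protein abundance matrix
#' @param clr apply [clrTransform()] first (default TRUE; pass FALSE for
#'   already-transformed input)
#' @param z_threshold default 1.645 (inclusive)
#' @param n_draws negative-downsampling repetitions (default 100)
#' @param seed RNG seed for the draws
#' @return list with \code{auroc}, \code{auprc} (mean), \code{auprc_draws},
#'   \code{positives}
#' @export
receptorSpecificityEval <- function(predictions, abundance, clr = TRUE,
                                    z_threshold = 1.645, n_draws = 100,
                                    seed = 1L) {
    A <- as.matrix(abundance)
    if (clr) A <- clrTransform(A)
    Z <- t(scale(t(A)))  # z across clusters, per receptor
    Z[is.nan(Z)] <- 0
    pos_mask <- Z >= z_threshold
    if (sum(pos_mask) < 2L) stop("fewer than 2 specifically abundant receptors")
    keys <- outer(rownames(A), colnames(A), paste, sep = "|")
    labels <- as.vector(pos_mask)
    pk <- paste(predictions$receptor, predictions$cluster, sep = "|")
    agg <- tapply(predictions$score, pk, max)
    scores <- rep(min(agg, na.rm = TRUE) - 1, length(labels))
    hit <- match(as.vector(keys), names(agg))
    scores[!is.na(hit)] <- agg[hit[!is.na(hit)]]
    auroc <- as.numeric(pROC::auc(response = labels, predictor = scores,
                                  direction = "<", quiet = TRUE,
                                  levels = c(FALSE, TRUE)))
    npos <- sum(labels)
    neg_idx <- which(!labels)
    pos_idx <- which(labels)
    draws <- .withSeed(seed, vapply(seq_len(n_draws), function(d) {
        sub <- c(pos_idx, sample(neg_idx, npos))
        .auprc(scores[sub], labels[sub])
    }, 0))
    list(auroc = auroc, auprc = mean(draws), auprc_draws = draws,
         positives = as.vector(keys)[labels])
}
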