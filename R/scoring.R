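#' Scoring configuration
#'
#' Shared tunables of the six scoring systems.
#'
#' @param prop_threshold minimum fraction of expressing cells for both
#'   entities (default 0.10; the boundary value passes)
#' @param n_permutations label permutations for the permutation p-value
#'   (default 1000)
#' @param seed RNG seed for permutations
#' @param de_p_threshold Wilcoxon p cutoff for the differential-expression
#'   filter (default 0.05, inclusive)
#' @param sca_lr_threshold LRscore cutoff (default 0.5, inclusive keep)
#' @param sca_logfc_threshold absolute log2FC cutoff of the SCA
#'   differential-expression prefilter (default 1.5)
#' @param sca_de_filter,sca_lr_filter toggles for the two SCA filters
#' @param crosstalk_bins equal-frequency bins for mutual information
#'   (default 4)
#' @param eps small constant guarding the autocrine inverse transform
#' @return a list of class \code{MethodConfig}
#' @export
methodConfig <- function(prop_threshold = 0.10, n_permutations = 1000,
                         seed = 1L, de_p_threshold = 0.05,
                         sca_lr_threshold = 0.5, sca_logfc_threshold = 1.5,
                         sca_de_filter = TRUE, sca_lr_filter = TRUE,
                         crosstalk_bins = 4L, eps = 1e-9) {
    stopifnot(prop_threshold >= 0, prop_threshold <= 1,
              n_permutations >= 1, de_p_threshold >= 0, de_p_threshold <= 1,
              crosstalk_bins >= 2, eps > 0)
    structure(list(prop_threshold = prop_threshold,
                   n_permutations = as.integer(n_permutations),
                   seed = as.integer(seed),
                   de_p_threshold = de_p_threshold,
                   sca_lr_threshold = sca_lr_threshold,
                   sca_logfc_threshold = sca_logfc_threshold,
                   sca_de_filter = isTRUE(sca_de_filter),
                   sca_lr_filter = isTRUE(sca_lr_filter),
                   crosstalk_bins = as.integer(crosstalk_bins), eps = eps),
              class = "MethodConfig")
}

#' Registered scoring methods
#' @return character vector of method labels
#' @export
scoringMethods <- function()
    c("cellphonedb", "connectome", "natmi", "sca", "logfc", "crosstalk")

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

.minmax <- function(x) {
    r <- range(x, finite = TRUE)
    if (!all(is.finite(r)) || r[1] == r[2]) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
}

# Entity-level stat matrices under the min-subunit rule.
# For each entity and cluster the representative subunit is the one with the
# minimum cluster log-mean (lexicographic tie-break via sorted subunits);
# prop is the minimum across subunits; deOk requires every subunit to pass.
.entityStats <- function(stats, resource, de_p_threshold = 0.05) {
    tab <- interactions(resource)
    id <- paste(tab$source_genesymbol, tab$target_genesymbol, sep = "^")
    tab <- tab[!duplicated(id), , drop = FALSE]
    ents <- unique(c(tab$source_genesymbol, tab$target_genesymbol))
    genes <- geneNames(stats)
    C <- length(clusterNames(stats))
    subs <- lapply(ents, entitySubunits)
    detected <- vapply(subs, function(s) all(s %in% genes), NA)
    nE <- length(ents)
    selIdx <- matrix(NA_integer_, nE, C)  # gene row index per entity/cluster
    prop <- matrix(NA_real_, nE, C)
    deOk <- matrix(NA, nE, C)
    for (e in seq_len(nE)) {
        if (!detected[e]) next
        gi <- match(subs[[e]], genes)
        if (length(gi) == 1L) {
            selIdx[e, ] <- gi
            prop[e, ] <- stats@prop[gi, ]
            deOk[e, ] <- stats@deP[gi, ] <= de_p_threshold
        } else {
            ml <- stats@meanLog[gi, , drop = FALSE]
            pick <- apply(ml, 2, which.min)  # first (lexicographic) on ties
            selIdx[e, ] <- gi[pick]
            prop[e, ] <- apply(stats@prop[gi, , drop = FALSE], 2, min)
            deOk[e, ] <- apply(stats@deP[gi, , drop = FALSE] <=
                               de_p_threshold, 2, all)
        }
    }
    colidx <- matrix(seq_len(C), nE, C, byrow = TRUE)
    pickMat <- function(m) {
        out <- matrix(NA_real_, nE, C, dimnames = list(ents, clusterNames(stats)))
        ok <- !is.na(selIdx)
        out[ok] <- m[cbind(selIdx[ok], colidx[ok])]
        out
    }
    dimnames(prop) <- dimnames(deOk) <- list(ents, clusterNames(stats))
    keep <- tab$source_genesymbol %in% ents[detected] &
            tab$target_genesymbol %in% ents[detected]
    dropped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    list(entities = ents, subunits = subs, detected = detected,
         selIdx = selIdx,
         meanLog = pickMat(stats@meanLog), meanLin = pickMat(stats@meanLin),
         log2fc = pickMat(stats@log2fc), zscore = pickMat(stats@zscore),
         prop = prop, deOk = deOk,
         lig = tab$source_genesymbol, rec = tab$target_genesymbol,
         ligIdx = match(tab$source_genesymbol, ents),
         recIdx = match(tab$target_genesymbol, ents),
         clusters = clusterNames(stats), n_undetected = dropped)
}

# All (interaction, source, target) combinations passing the shared
# proportion-of-expressing-cells filter (autocrine pairs included).
.comboFrame <- function(es, prop_threshold) {
    C <- length(es$clusters)
    nI <- length(es$lig)
    if (nI == 0L)
        return(data.frame(i = integer(), s = integer(), t = integer()))
    grid <- expand.grid(i = seq_len(nI), s = seq_len(C), t = seq_len(C))
    keep <- es$prop[cbind(es$ligIdx[grid$i], grid$s)] >= prop_threshold &
            es$prop[cbind(es$recIdx[grid$i], grid$t)] >= prop_threshold
    grid[keep, , drop = FALSE]
}

.scoredFrame <- function(es, combos, method, magnitude, specificity,
                         p_value = NA_real_) {
    data.frame(source = es$clusters[combos$s],
               target = es$clusters[combos$t],
               ligand_complex = es$lig[combos$i],
               receptor_complex = es$rec[combos$i],
               method = method,
               score_magnitude = magnitude,
               score_specificity = specificity,
               p_value = p_value,
               stringsAsFactors = FALSE, row.names = NULL)
}

.prepScoring <- function(x, resource, config, clusters = NULL, stats = NULL) {
    parts <- .datasetParts(x, clusters)
    if (is.null(stats))
        stats <- .summarizeClustersImpl(parts$norm, parts$clusters)
    es <- .entityStats(stats, resource, config$de_p_threshold)
    list(parts = parts, stats = stats, es = es)
}

#' CellPhoneDB-style permutation scoring
#'
#' Magnitude is the mean of the ligand and receptor cluster log-means (with
#' the min-subunit rule for complexes). Cluster labels are reshuffled
#' globally \code{n_permutations} times and a one-sided empirical p-value is
#' the fraction of permutations whose magnitude reaches the observed value
#' (ties counted, 0/N allowed). Both entities must be expressed in at least
#' \code{prop_threshold} of their cluster's cells. Specificity is
#' \code{1 - p}.
#'
#' @param x dataset (\code{SingleCellExperiment} with \code{logcounts} and a
#'   \code{cluster} column, or a log-normalized matrix)
#' @param resource an [LRResource-class]
#' @param config a [methodConfig()]
#' @param clusters cluster labels (matrix input)
#' @param stats optional precomputed [ClusterStats-class]
#' @return long-format \code{data.frame} of scored interactions
#' @export
scoreCellPhoneDB <- function(x, resource, config = methodConfig(),
                             clusters = NULL, stats = NULL) {
    if (config$n_permutations < 1L) stop("n_permutations must be >= 1")
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    combos <- .comboFrame(es, config$prop_threshold)
    if (nrow(combos) == 0L)
        return(.scoredFrame(es, combos, "cellphonedb", numeric(), numeric(),
                            numeric()))
    norm <- pr$parts$norm
    cl <- pr$parts$clusters
    genes_res <- sort(unique(unlist(es$subunits[es$detected])))
    X <- norm[genes_res, , drop = FALSE]
    ind <- stats::model.matrix(~ 0 + cl)
    sizes <- colSums(ind)
    C <- ncol(ind)
    # entity reduction of a permuted gene x cluster mean matrix
    singles <- which(es$detected & lengths(es$subunits) == 1L)
    multis <- which(es$detected & lengths(es$subunits) > 1L)
    sidx <- match(vapply(es$subunits[singles], identity, ""), genes_res)
    midx <- lapply(es$subunits[multis], match, genes_res)
    reduceE <- function(M) {
        E <- matrix(NA_real_, length(es$entities), C)
        E[singles, ] <- M[sidx, , drop = FALSE]
        for (k in seq_along(multis)) {
            rows <- M[midx[[k]], , drop = FALSE]
            E[multis[k], ] <- apply(rows, 2, min)
        }
        E
    }
    magOf <- function(E)
        (E[cbind(es$ligIdx[combos$i], combos$s)] +
         E[cbind(es$recIdx[combos$i], combos$t)]) / 2
    obs <- magOf(reduceE(sweep(X %*% ind, 2, sizes, "/")))
    ge_count <- integer(nrow(combos))
    .withSeed(config$seed, {
        for (b in seq_len(config$n_permutations)) {
            perm <- sample.int(ncol(X))
            Mb <- sweep(X %*% ind[perm, , drop = FALSE], 2, sizes, "/")
            ge_count <- ge_count + (magOf(reduceE(Mb)) >= obs)
        }
    })
    p <- ge_count / config$n_permutations
    .scoredFrame(es, combos, "cellphonedb", obs, 1 - p, p)
}

#' Connectome-style scoring
#'
#' \code{weight_norm} (magnitude) is the product of ligand and receptor
#' cluster log-means; \code{weight_scale} (specificity) is the mean of their
#' cross-cluster z-scores. Every subunit of both entities must be
#' differentially expressed (one-vs-rest Wilcoxon p at or below
#' \code{de_p_threshold}) in its cluster.
#'
#' @inheritParams scoreCellPhoneDB
#' @return long-format \code{data.frame}
#' @export
scoreConnectome <- function(x, resource, config = methodConfig(),
                            clusters = NULL, stats = NULL) {
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    combos <- .comboFrame(es, config$prop_threshold)
    de <- es$deOk[cbind(es$ligIdx[combos$i], combos$s)] &
          es$deOk[cbind(es$recIdx[combos$i], combos$t)]
    de[is.na(de)] <- FALSE
    combos <- combos[de, , drop = FALSE]
    mag <- es$meanLog[cbind(es$ligIdx[combos$i], combos$s)] *
           es$meanLog[cbind(es$recIdx[combos$i], combos$t)]
    spec <- (es$zscore[cbind(es$ligIdx[combos$i], combos$s)] +
             es$zscore[cbind(es$recIdx[combos$i], combos$t)]) / 2
    .scoredFrame(es, combos, "connectome", mag, spec)
}

#' NATMI-style specificity edge weights
#'
#' Magnitude is the product of cluster log-means; specificity multiplies the
#' ligand's share of its summed cluster means by the receptor's share
#' (\code{m_ls / sum_c m_lc} times \code{m_rt / sum_c m_rc}); the sums run
#' over all clusters and a zero denominator yields specificity 0.
#'
#' @inheritParams scoreCellPhoneDB
#' @return long-format \code{data.frame}
#' @export
scoreNATMI <- function(x, resource, config = methodConfig(),
                       clusters = NULL, stats = NULL) {
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    combos <- .comboFrame(es, config$prop_threshold)
    tot <- rowSums(es$meanLog)
    frac <- es$meanLog / ifelse(tot == 0, Inf, tot)
    mag <- es$meanLog[cbind(es$ligIdx[combos$i], combos$s)] *
           es$meanLog[cbind(es$recIdx[combos$i], combos$t)]
    spec <- frac[cbind(es$ligIdx[combos$i], combos$s)] *
            frac[cbind(es$recIdx[combos$i], combos$t)]
    .scoredFrame(es, combos, "natmi", mag, spec)
}

#' SingleCellSignalR-style regularised LRscore
#'
#' \code{LRscore = sqrt(l r) / (mu + sqrt(l r))} with \code{l}, \code{r} the
#' ligand and receptor cluster log-means and \code{mu} the dataset-wide mean
#' of the normalized matrix. Optional filters mirror the method's
#' differential-expression prefilter (\code{|log2FC| >= 1.5} on both
#' entities) and the suggested \code{LRscore >= 0.5} cutoff. Magnitude-only:
#' specificity is reported as \code{NA}.
#'
#' @inheritParams scoreCellPhoneDB
#' @return long-format \code{data.frame}
#' @export
scoreSCA <- function(x, resource, config = methodConfig(),
                     clusters = NULL, stats = NULL) {
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    mu <- datasetMean(pr$stats)
    if (mu <= 0) stop("degenerate dataset: mu <= 0")
    combos <- .comboFrame(es, config$prop_threshold)
    if (config$sca_de_filter) {
        de <- abs(es$log2fc[cbind(es$ligIdx[combos$i], combos$s)]) >=
                  config$sca_logfc_threshold &
              abs(es$log2fc[cbind(es$recIdx[combos$i], combos$t)]) >=
                  config$sca_logfc_threshold
        combos <- combos[de, , drop = FALSE]
    }
    sq <- sqrt(es$meanLog[cbind(es$ligIdx[combos$i], combos$s)] *
               es$meanLog[cbind(es$recIdx[combos$i], combos$t)])
    lr <- sq / (mu + sq)
    if (config$sca_lr_filter) {
        keep <- lr >= config$sca_lr_threshold
        combos <- combos[keep, , drop = FALSE]
        lr <- lr[keep]
    }
    .scoredFrame(es, combos, "sca", lr, NA_real_)
}

#' Mean one-vs-rest log2 fold change
#'
#' The average of the ligand's log2FC in the source cluster and the
#' receptor's log2FC in the target cluster; a single-score method (magnitude
#' and specificity coincide).
#'
#' @inheritParams scoreCellPhoneDB
#' @return long-format \code{data.frame}
#' @export
scoreLogFCMean <- function(x, resource, config = methodConfig(),
                           clusters = NULL, stats = NULL) {
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    combos <- .comboFrame(es, config$prop_threshold)
    v <- (es$log2fc[cbind(es$ligIdx[combos$i], combos$s)] +
          es$log2fc[cbind(es$recIdx[combos$i], combos$t)]) / 2
    .scoredFrame(es, combos, "logfc", v, v)
}

.efreqBin <- function(x, B) {
    br <- unique(quantile(x, seq(0, 1, length.out = B + 1), type = 1,
                          names = FALSE))
    if (length(br) == 1L) return(rep(1L, length(x)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

.mutualInfo2 <- function(bx, by) {
    nb <- max(bx); mb <- max(by)
    joint <- tabulate((bx - 1L) * mb + by, nb * mb) / length(bx)
    px <- tabulate(bx, nb) / length(bx)
    py <- tabulate(by, mb) / length(by)
    pij <- matrix(joint, nb, mb, byrow = TRUE)
    ex <- outer(px, py)
    nz <- pij > 0
    sum(pij[nz] * log2(pij[nz] / ex[nz]))
}

#' CytoTalk-inspired crosstalk scores
#'
#' Combines a preferential expression measure (PEM) with a non-self-talk
#' (NST) penalty. \code{PEM_gc = max(0, log10(S_gc / E_gc))} where \code{S}
#' sums normalized expression per gene and cluster and \code{E} is its
#' expectation from the matrix margins (0 where \code{S_gc = 0}); the pair
#' PEM is the mean of the ligand's PEM in the source and the receptor's in
#' the target. NST is built from the mutual information (base 2, after
#' equal-frequency binning into \code{crosstalk_bins} bins) of ligand and
#' receptor across the source cluster's cells: paracrine pairs get
#' \code{1 - minmax(MI)}, autocrine pairs the minmax-rescaled inverse
#' \code{1/(1 - minmax(MI) + eps)}. The score is the product of the
#' minmax-normalised pair PEM and NST, forced to 0 whenever either entity's
#' PEM is 0.
#'
#' @inheritParams scoreCellPhoneDB
#' @return long-format \code{data.frame}
#' @export
scoreCrosstalk <- function(x, resource, config = methodConfig(),
                           clusters = NULL, stats = NULL) {
    pr <- .prepScoring(x, resource, config, clusters, stats)
    es <- pr$es
    combos <- .comboFrame(es, config$prop_threshold)
    if (nrow(combos) == 0L)
        return(.scoredFrame(es, combos, "crosstalk", numeric(), numeric()))
    norm <- pr$parts$norm
    cl <- pr$parts$clusters
    C <- length(es$clusters)
    ind <- stats::model.matrix(~ 0 + cl)
    sizes <- colSums(ind)
    # PEM on resource genes, margins over the whole matrix
    genes_res <- sort(unique(unlist(es$subunits[es$detected])))
    S <- norm[genes_res, , drop = FALSE] %*% ind
    rowTot <- rowSums(norm[genes_res, , drop = FALSE])
    colTot <- as.numeric(colSums(norm) %*% ind)
    grand <- sum(colTot)
    E <- outer(rowTot, colTot) / grand
    PEMg <- matrix(0, length(genes_res), C,
                   dimnames = list(genes_res, es$clusters))
    pos <- S > 0 & E > 0
    PEMg[pos] <- pmax(0, log10(S[pos] / E[pos]))
    PEMe <- matrix(NA_real_, length(es$entities), C)
    ok <- !is.na(es$selIdx)
    PEMe[ok] <- PEMg[cbind(match(geneNames(pr$stats)[es$selIdx[ok]], genes_res),
                           col(es$selIdx)[ok])]
    # mutual information per (interaction, source cluster)
    nI <- length(es$lig)
    needMI <- matrix(FALSE, nI, C)
    needMI[cbind(combos$i, combos$s)] <- TRUE
    MI <- matrix(NA_real_, nI, C)
    warned <- FALSE
    cells_of <- split(seq_along(cl), cl)
    for (s in seq_len(C)) {
        idx <- cells_of[[es$clusters[s]]]
        B <- config$crosstalk_bins
        if (length(idx) < B) {
            B <- max(2L, length(idx))
            if (!warned) {
                warning("cluster smaller than bin count; reducing bins")
                warned <- TRUE
            }
        }
        for (i in which(needMI[, s])) {
            lg <- geneNames(pr$stats)[es$selIdx[es$ligIdx[i], s]]
            rg <- geneNames(pr$stats)[es$selIdx[es$recIdx[i], s]]
            MI[i, s] <- .mutualInfo2(.efreqBin(norm[lg, idx], B),
                                     .efreqBin(norm[rg, idx], B))
        }
    }
    mm <- MI
    fin <- is.finite(MI)
    mm[fin] <- .minmax(MI[fin])
    nst <- numeric(nrow(combos))
    para <- combos$s != combos$t
    nst[para] <- 1 - mm[cbind(combos$i[para], combos$s[para])]
    if (any(!para)) {
        raw <- 1 / (1 - mm[cbind(combos$i[!para], combos$s[!para])] +
                    config$eps)
        nst[!para] <- .minmax(raw)
    }
    pem_l <- PEMe[cbind(es$ligIdx[combos$i], combos$s)]
    pem_r <- PEMe[cbind(es$recIdx[combos$i], combos$t)]
    pairPEM <- (pem_l + pem_r) / 2
    score <- .minmax(pairPEM) * .minmax(nst)
    score[pem_l == 0 | pem_r == 0] <- 0
    .scoredFrame(es, combos, "crosstalk", score, score)
}

#' Run several scoring methods on one dataset
#'
#' Computes cluster statistics once and applies each requested scoring
#' system, returning a single long-format table (one row per scored
#' interaction per method) with columns \code{source}, \code{target},
#' \code{ligand_complex}, \code{receptor_complex}, \code{method},
#' \code{score_magnitude}, \code{score_specificity}, \code{p_value}.
#'
#' @inheritParams scoreCellPhoneDB
#' @param methods subset of [scoringMethods()]
#' @param verbose log per-method interaction counts
#' @return long-format \code{data.frame}; the computed
#'   [ClusterStats-class] is attached as attribute \code{"stats"}
#' @export
scoreMethods <- function(x, resource, methods = scoringMethods(),
                         config = methodConfig(), clusters = NULL,
                         stats = NULL, verbose = FALSE) {
    bad <- setdiff(methods, scoringMethods())
    if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
    parts <- .datasetParts(x, clusters)
    if (is.null(stats))
        stats <- .summarizeClustersImpl(parts$norm, parts$clusters)
    fun <- list(cellphonedb = scoreCellPhoneDB, connectome = scoreConnectome,
                natmi = scoreNATMI, sca = scoreSCA, logfc = scoreLogFCMean,
                crosstalk = scoreCrosstalk)
    out <- lapply(methods, function(m) {
        r <- fun[[m]](parts$norm, resource, config,
                      clusters = parts$clusters, stats = stats)
        if (verbose) message(m, ": ", nrow(r), " scored interactions")
        r
    })
    res <- do.call(rbind, out)
    attr(res, "stats") <- stats
    res
}
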