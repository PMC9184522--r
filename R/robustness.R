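#' Subsample cells within each cluster
#'
#' Independently subsamples each cluster without replacement to
#' \code{keep_fraction} of its cells (rounded), erroring if any cluster
#' would drop below 3 cells.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{cluster} column
#' @param keep_fraction in (0, 1]
#' @param seed RNG seed
#' @return the subsampled \code{SingleCellExperiment}
#' @export
subsampleCells <- function(sce, keep_fraction, seed = 1L) {
    stopifnot(keep_fraction > 0, keep_fraction <= 1)
    cl <- SummarizedExperiment::colData(sce)$cluster
    keep <- .withSeed(seed, {
        unlist(lapply(split(seq_along(cl), cl), function(idx) {
            k <- round(keep_fraction * length(idx))
            if (k < 3L) stop("cluster would fall below 3 cells")
            sort(sample(idx, k))
        }), use.names = FALSE)
    })
    sce[, sort(keep)]
}

#' Shuffle a fraction of cluster labels
#'
#' Selects \code{round(fraction n)} cells at random and permutes their
#' labels among themselves, preserving the overall label multiset (and
#' allowing permutation fixed points, so the realised mislabeled share is
#' below the nominal fraction).
#'
#' @inheritParams subsampleCells
#' @param fraction in \[0, 1\]
#' @return the relabelled \code{SingleCellExperiment}
#' @export
shuffleLabels <- function(sce, fraction, seed = 1L) {
    stopifnot(fraction >= 0, fraction <= 1)
    if (fraction == 0) return(sce)
    cl <- as.character(SummarizedExperiment::colData(sce)$cluster)
    n <- length(cl)
    .withSeed(seed, {
        idx <- sample.int(n, round(fraction * n))
        cl[idx] <- cl[idx][sample.int(length(idx))]
    })
    SummarizedExperiment::colData(sce)$cluster <- cl
    sce
}

#' Corrupt a resource with random interactions
#'
#' Replaces a proportion of the resource's records with fake interactions:
#' random ordered gene pairs drawn from the 2000 most variable genes of the
#' dataset (variance of the normalized layer), avoiding collisions with
#' existing records. In \code{"selective"} mode the records underlying a
#' baseline top set are never replaced; \code{"nonselective"} replaces
#' uniformly. Resource size is preserved.
#'
#' @param resource an [LRResource-class]
#' @param x dataset (see [scoreCellPhoneDB()]) supplying gene variances
#' @param fraction proportion to replace, in \[0, 0.40\]
#' @param mode \code{"nonselective"} or \code{"selective"}
#' @param baseline_topset a \code{TopSet} whose records are protected in
#'   selective mode
#' @param clusters cluster labels for matrix input
#' @param n_var_genes size of the variable-gene pool (default 2000; reduced
#'   with a warning when the dataset has fewer genes)
#' @param seed RNG seed
#' @return corrupted \code{LRResource}
#' @export
corruptResource <- function(resource, x, fraction,
                            mode = c("nonselective", "selective"),
                            baseline_topset = NULL, clusters = NULL,
                            n_var_genes = 2000, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(fraction >= 0, fraction <= 0.40)
    if (fraction == 0) return(resource)
    parts <- .datasetParts(x, clusters)
    v <- apply(parts$norm, 1, var)
    if (length(v) < n_var_genes) {
        warning("fewer than ", n_var_genes, " genes; using all")
        n_var_genes <- length(v)
    }
    pool <- names(sort(v, decreasing = TRUE))[seq_len(n_var_genes)]
    tab <- interactions(resource)
    nrep <- floor(fraction * nrow(tab))
    if (nrep == 0L) return(resource)
    id <- paste(tab$source_genesymbol, tab$target_genesymbol, sep = "^")
    protected <- rep(FALSE, nrow(tab))
    if (mode == "selective") {
        if (is.null(baseline_topset))
            stop("selective mode needs a baseline_topset")
        top_lr <- unique(paste(baseline_topset$table$ligand_complex,
                               baseline_topset$table$receptor_complex,
                               sep = "^"))
        protected <- id %in% top_lr
        if (sum(!protected) < nrep)
            stop("not enough unprotected records for selective replacement")
    }
    .withSeed(seed, {
        drop_idx <- sample(which(!protected), nrep)
        existing <- id
        fakes <- character(0)
        while (length(fakes) < nrep) {
            cand <- paste(sample(pool, nrep, replace = TRUE),
                          sample(pool, nrep, replace = TRUE), sep = "^")
            cand <- setdiff(unique(cand), c(existing, fakes))
            cand <- cand[!grepl("^(.*)\\^\\1$", cand)]
            fakes <- c(fakes, head(cand, nrep - length(fakes)))
        }
        gg <- strsplit(fakes, "^", fixed = TRUE)
        tab$source_genesymbol[drop_idx] <- vapply(gg, `[`, "", 1)
        tab$target_genesymbol[drop_idx] <- vapply(gg, `[`, "", 2)
    })
    rownames(tab) <- NULL
    new("LRResource", interactions = tab)
}

#' Robustness of top-ranked interactions to noise
#'
#' For each analysis, manipulation fraction and repetition, perturbs the
#' data or the resource, rescores with each method, and reports the overlap
#' of the perturbed top-250 (ties included) with the unperturbed baseline
#' top-250: \code{|top_perturbed intersect top_baseline| / |top_baseline|}.
#' A method failing on a perturbed input is recorded as \code{NA}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts},
#'   \code{logcounts} and a \code{cluster} column
#' @param resource an [LRResource-class]
#' @param analysis one of \code{"subsample_cells"}, \code{"shuffle_labels"},
#'   \code{"resource_selective"}, \code{"resource_nonselective"}
#' @param methods subset of [scoringMethods()]
#' @param grid manipulation fractions within \[0, 0.40\]
#' @param reps repetitions per non-zero fraction (default 5)
#' @param top_n baseline size (default 250)
#' @param config a [methodConfig()]
#' @param seed RNG seed; per-repetition seeds are derived from it
#' @return \code{data.frame(analysis, method, fraction, rep, overlap)}
#' @export
robustnessSweep <- function(sce, resource,
                            analysis = c("subsample_cells", "shuffle_labels",
                                         "resource_selective",
                                         "resource_nonselective"),
                            methods = scoringMethods(),
                            grid = c(0, 0.1, 0.2, 0.3, 0.4), reps = 5,
                            top_n = 250, config = methodConfig(),
                            seed = 1L) {
    analysis <- match.arg(analysis)
    stopifnot(all(grid >= 0 & grid <= 0.40))
    baseline <- scoreMethods(sce, resource, methods, config)
    base_top <- lapply(methods, function(m)
        topRanked(rankInteractions(baseline, m), k = top_n)$ids)
    names(base_top) <- methods
    rows <- list()
    for (f in grid) {
        nrep <- if (f == 0) 1L else as.integer(reps)
        for (r in seq_len(nrep)) {
            rep_seed <- (seed + 7919L * r + round(1e4 * f)) %% .Machine$integer.max
            scored <- tryCatch({
                if (f == 0) baseline
                else if (analysis == "subsample_cells")
                    scoreMethods(subsampleCells(sce, 1 - f, rep_seed),
                                 resource, methods, config)
                else if (analysis == "shuffle_labels")
                    scoreMethods(shuffleLabels(sce, f, rep_seed),
                                 resource, methods, config)
                else scoreMethods(sce, corruptResource(
                        resource, sce, f,
                        mode = sub("resource_", "", analysis),
                        baseline_topset = if (analysis == "resource_selective")
                            .unionTopSet(baseline, methods, top_n),
                        seed = rep_seed), methods, config)
            }, error = function(e) NULL)
            for (m in methods) {
                ov <- NA_real_
                if (!is.null(scored)) {
                    ids <- tryCatch(
                        topRanked(rankInteractions(scored, m), k = top_n)$ids,
                        error = function(e) NULL)
                    if (!is.null(ids))
                        ov <- length(intersect(ids, base_top[[m]])) /
                              length(base_top[[m]])
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    analysis = analysis, method = m, fraction = f, rep = r,
                    overlap = ov, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

# union of the per-method baseline top sets, as one TopSet for protection
.unionTopSet <- function(baseline, methods, top_n) {
    tabs <- lapply(methods, function(m)
        topRanked(rankInteractions(baseline, m), k = top_n)$table)
    tab <- do.call(rbind, tabs)
    structure(list(ids = unique(.comboId(tab$source, tab$target,
                                         tab$ligand_complex,
                                         tab$receptor_complex)),
                   table = tab, nominal_k = top_n, label = "baseline",
                   method = NA_character_, resource = NA_character_),
              class = "TopSet")
}
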