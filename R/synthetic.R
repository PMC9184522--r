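#' Synthetic-data scenario configuration
#'
#' Defines the conditions under which synthetic datasets with planted
#' ligand-receptor signalling are generated. Counts are negative binomial
#' with per-cell log-normal library factors; each planted pair upregulates
#' its ligand in the source cluster and its receptor (all subunits) in the
#' target cluster by \code{effect_size}.
#'
#' @param n_genes number of genes (default 2000)
#' @param n_clusters number of clusters (default 20)
#' @param cells_per_cluster cells per cluster (default 100)
#' @param baseline_mean negative binomial mean of unplanted genes (default
#'   0.5 counts)
#' @param dispersion negative binomial size parameter (default 2)
#' @param n_planted_pairs planted ligand-receptor pairs (default 20)
#' @param effect_size fold increase of planted genes in their cluster
#'   (default 8; must exceed 1)
#' @param n_decoy_interactions random non-planted resource records (default
#'   180)
#' @param complex_fraction share of planted receptors emitted as 2-subunit
#'   complexes (default 0.25)
#' @param library_size_cv coefficient of variation of per-cell library
#'   factors (default 0.3)
#' @param seed mandatory RNG seed
#' @return a list of class \code{ScenarioConfig}
#' @export
ccScenario <- function(n_genes = 2000, n_clusters = 20,
                       cells_per_cluster = 100, baseline_mean = 0.5,
                       dispersion = 2, n_planted_pairs = 20,
                       effect_size = 8, n_decoy_interactions = 180,
                       complex_fraction = 0.25, library_size_cv = 0.3,
                       seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(effect_size > 1, baseline_mean > 0, dispersion > 0,
              n_clusters >= 2, cells_per_cluster >= 3,
              complex_fraction >= 0, complex_fraction <= 1,
              library_size_cv >= 0)
    n_complex <- round(complex_fraction * n_planted_pairs)
    if (2 * n_planted_pairs + n_complex > n_genes)
        stop("more planted pairs than the gene budget allows")
    structure(list(n_genes = n_genes, n_clusters = n_clusters,
                   cells_per_cluster = cells_per_cluster,
                   baseline_mean = baseline_mean, dispersion = dispersion,
                   n_planted_pairs = n_planted_pairs,
                   effect_size = effect_size,
                   n_decoy_interactions = n_decoy_interactions,
                   complex_fraction = complex_fraction,
                   library_size_cv = library_size_cv,
                   seed = as.integer(seed)),
              class = "ScenarioConfig")
}

#' Generate a synthetic clustered expression dataset
#'
#' @param config a [ccScenario()]
#' @return list with \code{dataset} (a \code{SingleCellExperiment} with
#'   \code{counts}, \code{logcounts} and a \code{cluster} column) and
#'   \code{truth} (planted interaction tuples, colocalized cluster pairs,
#'   active cytokine x cluster pairs, specific receptor x cluster pairs)
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "ScenarioConfig"))
    P <- config$n_planted_pairs
    C <- config$n_clusters
    n_complex <- round(config$complex_fraction * P)
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    clusters <- sprintf("C%02d", seq_len(C))
    lig <- genes[seq_len(P)]
    rec <- genes[P + seq_len(P)]
    partner <- if (n_complex > 0) genes[2 * P + seq_len(n_complex)]
               else character(0)
    src <- clusters[((seq_len(P) - 1L) %% C) + 1L]
    tgt <- clusters[(seq_len(P) %% C) + 1L]
    rec_entity <- rec
    if (n_complex > 0)
        rec_entity[seq_len(n_complex)] <- vapply(seq_len(n_complex),
            function(i) canonicalEntity(paste(rec[i], partner[i], sep = "_")),
            "")
    mult <- matrix(1, config$n_genes, C, dimnames = list(genes, clusters))
    for (i in seq_len(P)) {
        mult[lig[i], src[i]] <- config$effect_size
        mult[rec[i], tgt[i]] <- config$effect_size
        if (i <= n_complex) mult[partner[i], tgt[i]] <- config$effect_size
    }
    n_cells <- C * config$cells_per_cluster
    cl_of <- rep(clusters, each = config$cells_per_cluster)
    counts <- .withSeed(config$seed, {
        sdlog <- sqrt(log(1 + config$library_size_cv^2))
        libf <- if (config$library_size_cv > 0)
            rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, n_cells)
        mu <- config$baseline_mean * sweep(mult[, cl_of, drop = FALSE],
                                           2, libf, "*")
        matrix(rnbinom(length(mu), mu = mu, size = config$dispersion),
               config$n_genes, n_cells)
    })
    dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(n_cells)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts, logcounts = normalizeCounts(counts)),
        colData = S4Vectors::DataFrame(cluster = cl_of,
                                       row.names = colnames(counts)))
    truth <- list(
        planted = data.frame(source = src, target = tgt, ligand = lig,
                             receptor = rec_entity, stringsAsFactors = FALSE),
        coloc_pairs = unique(.pairKey(src, tgt)),
        active_cytokines = paste(lig, tgt, sep = "|"),
        specific_receptors = paste(rec_entity, tgt, sep = "|"))
    list(dataset = sce, truth = truth)
}

#' Generate a synthetic ligand-receptor resource
#'
#' Planted interactions plus random decoy gene pairs drawn from genes not
#' used by any planted entity, without identity collisions or self-pairs.
#'
#' @param config a [ccScenario()]
#' @param truth the ground truth from [generateDataset()]
#' @return an [LRResource-class] of size \code{n_planted_pairs +
#'   n_decoy_interactions}
#' @export
generateResource <- function(config, truth) {
    stopifnot(inherits(config, "ScenarioConfig"))
    planted <- truth$planted
    used <- unique(unlist(lapply(c(planted$ligand, planted$receptor),
                                 entitySubunits)))
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    pool <- setdiff(genes, used)
    nd <- config$n_decoy_interactions
    decoys <- .withSeed(config$seed + 104729L, {
        out <- character(0)
        while (length(out) < nd) {
            a <- sample(pool, nd, replace = TRUE)
            b <- sample(pool, nd, replace = TRUE)
            cand <- unique(paste(a, b, sep = "^"))
            cand <- cand[!grepl("^(.*)\\^\\1$", cand)]
            out <- unique(c(out, cand))
        }
        head(out, nd)
    })
    gg <- strsplit(decoys, "^", fixed = TRUE)
    lrResource(c(planted$ligand, vapply(gg, `[`, "", 1)),
               c(planted$receptor, vapply(gg, `[`, "", 2)),
               resource = "synthetic")
}

#' Generate auxiliary modality tables with planted signal
#'
#' Produces (i) spot x cluster proportions in which planted colocalized
#' cluster pairs share a latent abundance factor, (ii) a gene x cytokine
#' signature matrix whose cytokines are named after the planted ligands and
#' weight their receptor genes (plus disjoint low-weight filler genes), with
#' the planted activity being cytokine k active in its target cluster, and
#' (iii) a receptor x cluster protein abundance matrix with planted
#' receptors elevated in their target clusters.
#'
#' @param config a [ccScenario()]
#' @param truth ground truth from [generateDataset()]
#' @param resource optional [LRResource-class]; its receiver entities define
#'   the abundance rows (default: planted receptors only)
#' @param n_spots spatial spots (default 500)
#' @param coloc_weight weight of the shared latent factor (default 3)
#' @param abundance_effect fold elevation of planted receptor abundance
#'   (default 5)
#' @return list with \code{proportions}, \code{signatures},
#'   \code{abundance}
#' @export
generateModalities <- function(config, truth, resource = NULL,
                               n_spots = 500, coloc_weight = 3,
                               abundance_effect = 5) {
    stopifnot(inherits(config, "ScenarioConfig"))
    C <- config$n_clusters
    clusters <- sprintf("C%02d", seq_len(C))
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    planted <- truth$planted
    .withSeed(config$seed + 15485863L, {
        base <- matrix(rgamma(n_spots * C, shape = 2, rate = 2), n_spots, C,
                       dimnames = list(sprintf("spot%04d", seq_len(n_spots)),
                                       clusters))
        for (pk in truth$coloc_pairs) {
            ab <- strsplit(pk, "|", fixed = TRUE)[[1]]
            f <- rgamma(n_spots, shape = 2, rate = 2)
            base[, ab[1]] <- base[, ab[1]] + coloc_weight * f
            base[, ab[2]] <- base[, ab[2]] + coloc_weight * f
        }
        proportions <- base / rowSums(base)

        cytokines <- planted$ligand
        sig <- matrix(0, config$n_genes, length(cytokines),
                      dimnames = list(genes, cytokines))
        used <- unique(unlist(lapply(c(planted$ligand, planted$receptor),
                                     entitySubunits)))
        filler_pool <- setdiff(genes, used)
        n_fill <- min(9L, length(filler_pool) %/% max(1L, length(cytokines)))
        for (k in seq_along(cytokines)) {
            rsub <- entitySubunits(planted$receptor[k])
            sig[rsub, k] <- 1
            if (n_fill > 0) {
                fill <- filler_pool[seq((k - 1) * n_fill + 1, k * n_fill)]
                sig[fill, k] <- rnorm(n_fill, 0, 0.1)
            }
        }

        receptors <- if (!is.null(resource))
            unique(interactions(resource)$target_genesymbol)
        else unique(planted$receptor)
        abundance <- matrix(rlnorm(length(receptors) * C, meanlog = log(5),
                                   sdlog = 0.3),
                            length(receptors), C,
                            dimnames = list(receptors, clusters))
        for (k in seq_len(nrow(planted))) {
            r <- planted$receptor[k]
            if (r %in% receptors)
                abundance[r, planted$target[k]] <-
                    abundance[r, planted$target[k]] * abundance_effect
        }
        list(proportions = proportions, signatures = sig,
             abundance = abundance)
    })
}
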