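# Shared fixtures, built in code.

# Tiny deterministic two-cluster dataset: 4 genes x 8 cells.
# LIG is high in cluster A, REC high in cluster B, HOUSE uniform, RARE
# expressed in few cells.
toyNorm <- function() {
    m <- rbind(
        LIG   = c(2.0, 2.2, 1.8, 2.1, 0.2, 0.1, 0.3, 0.2),
        REC   = c(0.1, 0.3, 0.2, 0.2, 2.1, 1.9, 2.0, 2.2),
        HOUSE = c(1.0, 1.1, 0.9, 1.0, 1.0, 1.1, 0.9, 1.0),
        RARE  = c(0.5, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0))
    colnames(m) <- paste0("cell", 1:8)
    m
}

toyClusters <- function() rep(c("A", "B"), each = 4)

toyResource <- function()
    lrResource(c("LIG", "HOUSE"), c("REC", "HOUSE"), resource = "toy")

toySCE <- function() {
    counts <- round(expm1(toyNorm()) * 10)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts, logcounts = toyNorm()),
        colData = S4Vectors::DataFrame(cluster = toyClusters(),
                                       row.names = colnames(counts)))
}

# Two-sided Fisher p by direct hypergeometric enumeration, for the 2x2
# table matrix(c(a, c, b, d), 2) (rows: in/out of set, cols: in/out of
# category).
fisherEnumP <- function(a, b, c_, d) {
    k <- a + c_               # category margin
    m <- a + b                # set margin
    n <- c_ + d
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    p0 <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Exhaustive CellPhoneDB-style permutation p on a tiny two-cluster dataset:
# enumerate every assignment of cells to the two cluster sizes.
enumPermP <- function(norm, clusters, lig, rec, src, tgt) {
    cl <- factor(clusters)
    stopifnot(nlevels(cl) == 2L)
    n <- ncol(norm)
    n1 <- sum(cl == levels(cl)[1])
    magOf <- function(assign1) {
        in1 <- seq_len(n) %in% assign1
        m <- cbind(rowMeans(norm[, in1, drop = FALSE]),
                   rowMeans(norm[, !in1, drop = FALSE]))
        colnames(m) <- levels(cl)
        (m[lig, src] + m[rec, tgt]) / 2
    }
    obs <- magOf(which(cl == levels(cl)[1]))
    sets <- utils::combn(n, n1)
    mags <- apply(sets, 2, magOf)
    mean(mags >= obs)
}

# Lazily computed default-scenario run, shared across acceptance tests.
.scenario_cache <- new.env(parent = emptyenv())

defaultScenarioRun <- function() {
    if (!exists("run", envir = .scenario_cache)) {
        sc <- ccScenario(seed = 1)
        gen <- generateDataset(sc)
        res <- generateResource(sc, gen$truth)
        cfg <- methodConfig(n_permutations = 1000, seed = 3)
        scored <- scoreMethods(gen$dataset, res, config = cfg)
        assign("run", list(sc = sc, gen = gen, res = res, cfg = cfg,
                           scored = scored), envir = .scenario_cache)
    }
    get("run", envir = .scenario_cache)
}
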