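cfgFast <- methodConfig(n_permutations = 200, seed = 5)

test_that("the expression-proportion filter is inclusive at the boundary", {
    # ligand expressed in exactly 10% of source cells passes; below fails
    norm <- rbind(L = c(1, rep(0, 9), rep(0.5, 10)),
                  R = c(rep(0.5, 10), rep(1, 10)))
    cl <- rep(c("S", "T"), each = 10)
    res <- lrResource("L", "R")
    out <- scoreNATMI(norm, res, clusters = cl)
    expect_true(any(out$source == "S" & out$target == "T"))  # prop = 0.10
    norm2 <- norm
    norm2["L", 1] <- 0  # prop 0.05... actually 0 now
    out2 <- scoreNATMI(norm2, res, clusters = cl)
    expect_false(any(out2$source == "S" & out2$target == "T"))
})

test_that("undetected entities are dropped from every method", {
    norm <- toyNorm()
    res <- lrResource(c("LIG", "GHOST"), c("REC", "REC"))
    for (f in list(scoreNATMI, scoreLogFCMean, scoreConnectome))
        expect_false("GHOST" %in% f(norm, res, clusters = toyClusters())$ligand_complex)
})

test_that("permutation p-values are 1 for constant expression and match enumeration", {
    flat <- matrix(1, 2, 6, dimnames = list(c("L", "R"), paste0("c", 1:6)))
    res <- lrResource("L", "R")
    out <- scoreCellPhoneDB(flat, res, cfgFast,
                            clusters = rep(c("A", "B"), each = 3))
    expect_true(all(out$p_value == 1))
    # 4 cells, 2 clusters of 2: sampled p within 3 binomial SE of the
    # exhaustive enumeration over all 6 assignments
    norm <- matrix(c(3, 0.5, 2.5, 0.4, 0.5, 3, 0.2, 2.8), 2,
                   dimnames = list(c("L", "R"), paste0("c", 1:4)))
    cl <- c("A", "A", "B", "B")
    p_enum <- enumPermP(norm, cl, "L", "R", "A", "B")
    cfg <- methodConfig(n_permutations = 1000, seed = 8, prop_threshold = 0)
    out <- scoreCellPhoneDB(norm, lrResource("L", "R"), cfg, clusters = cl)
    p_samp <- out$p_value[out$source == "A" & out$target == "B"]
    se <- sqrt(p_enum * (1 - p_enum) / 1000)
    expect_lt(abs(p_samp - p_enum), max(3 * se, 1e-9))
    expect_equal(out$score_specificity, 1 - out$p_value)
})

test_that("permutation scoring is reproducible given the seed", {
    norm <- toyNorm()
    res <- toyResource()
    a <- scoreCellPhoneDB(norm, res, cfgFast, clusters = toyClusters())
    b <- scoreCellPhoneDB(norm, res, cfgFast, clusters = toyClusters())
    expect_equal(a, b)
    expect_error(scoreCellPhoneDB(norm, res,
        methodConfig(n_permutations = 0), clusters = toyClusters()))
})

test_that("connectome weights follow the z-score and product forms", {
    norm <- toyNorm()
    res <- toyResource()
    cfg <- methodConfig(de_p_threshold = 1)  # keep all, check values
    out <- scoreConnectome(norm, res, cfg, clusters = toyClusters())
    st <- summarizeClusters(norm, toyClusters())
    row <- out[out$ligand_complex == "LIG" & out$source == "A" &
               out$target == "B", ]
    expect_equal(row$score_magnitude,
                 statMatrix(st, "mean_log")["LIG", "A"] *
                 statMatrix(st, "mean_log")["REC", "B"])
    expect_equal(row$score_specificity,
                 (statMatrix(st, "zscore")["LIG", "A"] +
                  statMatrix(st, "zscore")["REC", "B"]) / 2)
    # cluster-uniform genes have zero specificity
    hh <- out[out$ligand_complex == "HOUSE" & out$receptor_complex == "HOUSE", ]
    expect_true(all(abs(hh$score_specificity) < 1e-10))
    # default DE filter removes non-differential interactions
    strict <- scoreConnectome(norm, res, methodConfig(),
                              clusters = toyClusters())
    expect_false("HOUSE" %in% strict$ligand_complex)
})

test_that("connectome ranks a planted source-specific pair on top", {
    set.seed(31)
    n_per <- 30
    cl <- rep(c("A", "B", "C"), each = n_per)
    norm <- matrix(abs(rnorm(5 * 90, 1, 0.1)), 5, 90,
                   dimnames = list(c("L1", "R1", "L2", "R2", "X"), NULL))
    norm["L1", cl == "A"] <- norm["L1", cl == "A"] + 2
    norm["R1", cl == "B"] <- norm["R1", cl == "B"] + 2
    res <- lrResource(c("L1", "L2"), c("R1", "R2"))
    out <- scoreConnectome(norm, res,
                           methodConfig(de_p_threshold = 1), clusters = cl)
    best <- out[which.max(out$score_specificity), ]
    expect_equal(best[, c("source", "target", "ligand_complex")],
                 data.frame(source = "A", target = "B",
                            ligand_complex = "L1"),
                 ignore_attr = TRUE)
    # specificity equals the hand-computed mean of the two z-scores
    st <- summarizeClusters(norm, cl)
    m <- statMatrix(st, "mean_log")
    zL <- (m["L1", "A"] - mean(m["L1", ])) / sd(m["L1", ])
    zR <- (m["R1", "B"] - mean(m["R1", ])) / sd(m["R1", ])
    expect_equal(best$score_specificity, (zL + zR) / 2, tolerance = 1e-12)
})

test_that("NATMI specificity has its closed forms", {
    # exclusive expression: specificity 1
    excl <- rbind(L = c(1, 1, 0, 0, 0, 0), R = c(0, 0, 1, 1, 0, 0))
    cl <- rep(c("A", "B", "C"), each = 2)
    res <- lrResource("L", "R")
    out <- scoreNATMI(excl, res, clusters = cl)
    expect_equal(out$score_specificity[out$source == "A" & out$target == "B"], 1)
    # uniform expression: 1/C^2
    unif <- matrix(1, 2, 6, dimnames = list(c("L", "R"), NULL))
    ou <- scoreNATMI(unif, res, clusters = cl)
    expect_equal(ou$score_specificity, rep(1 / 9, 9), tolerance = 1e-12)
    # per-entity fractions sum to 1 over source clusters
    set.seed(3)
    rnd <- matrix(runif(12, 0.5, 2), 2, 6, dimnames = list(c("L", "R"), NULL))
    or_ <- scoreNATMI(rnd, res, methodConfig(prop_threshold = 0), clusters = cl)
    st <- summarizeClusters(rnd, cl)
    m <- statMatrix(st, "mean_log")
    expect_equal(sum(m["L", ] / sum(m["L", ])), 1)
})

test_that("LRscore has its closed forms and filters inclusively", {
    # construct means so that sqrt(l r) equals mu: score exactly 0.5, kept
    norm <- rbind(L = rep(1, 8), R = rep(1, 8),
                  PAD1 = rep(1, 8), PAD2 = rep(1, 8))
    cl <- rep(c("A", "B"), each = 4)
    expect_equal(mean(norm), 1)  # mu = 1 and l = r = 1
    res <- lrResource("L", "R")
    out <- scoreSCA(norm, res, methodConfig(sca_de_filter = FALSE),
                    clusters = cl)
    expect_true(all(out$score_magnitude == 0.5))  # kept at the boundary
    expect_equal(nrow(out), 4L)
    # zero expression on either side gives score 0 (and is filtered)
    norm0 <- norm; norm0["L", ] <- 0
    out0 <- scoreSCA(norm0, res,
                     methodConfig(sca_de_filter = FALSE,
                                  sca_lr_filter = FALSE, prop_threshold = 0),
                     clusters = cl)
    expect_true(all(out0$score_magnitude == 0))
    # monotone increasing in the ligand mean
    lr <- function(l, r, mu) sqrt(l * r) / (mu + sqrt(l * r))
    ls <- seq(0.1, 10, length.out = 50)
    expect_true(all(diff(lr(ls, 2, 1)) > 0))
    expect_error(scoreSCA(matrix(0, 2, 8,
                                 dimnames = list(c("L", "R"), NULL)),
                          res, clusters = cl),
                 "mu", ignore.case = TRUE)
})

test_that("logFC mean averages the two fold changes and flips sign on swap", {
    norm <- toyNorm()
    res <- toyResource()
    out <- scoreLogFCMean(norm, res, clusters = toyClusters())
    st <- summarizeClusters(norm, toyClusters())
    lfc <- statMatrix(st, "log2fc")
    row <- out[out$ligand_complex == "LIG" & out$source == "A" &
               out$target == "B", ]
    expect_equal(row$score_magnitude, (lfc["LIG", "A"] + lfc["REC", "B"]) / 2)
    expect_equal(row$score_magnitude, row$score_specificity)
    # swapping the two balanced clusters flips the sign
    rev_row <- out[out$ligand_complex == "LIG" & out$source == "B" &
                   out$target == "A", ]
    expect_equal(rev_row$score_magnitude, -row$score_magnitude,
                 tolerance = 1e-12)
    # uniform genes score 0
    hh <- out[out$ligand_complex == "HOUSE" & out$receptor_complex == "HOUSE", ]
    expect_true(all(abs(hh$score_magnitude) < 1e-10))
})

test_that("crosstalk scores are bounded, zero on uniform PEM, and near-zero MI for independent genes", {
    norm <- toyNorm()
    out <- scoreCrosstalk(norm, toyResource(), clusters = toyClusters())
    expect_true(all(out$score_magnitude >= 0 & out$score_magnitude <= 1))
    # perfectly uniform matrix: every PEM 0, every score 0
    unif <- matrix(1, 3, 8, dimnames = list(c("L", "R", "X"), NULL))
    ou <- scoreCrosstalk(unif, lrResource("L", "R"),
                         clusters = toyClusters())
    expect_true(all(ou$score_magnitude == 0))
    # independent genes at large n: MI below 0.05 bits
    set.seed(12)
    n <- 2000
    big <- rbind(L = rexp(2 * n), R = rexp(2 * n))
    bins_l <- CCCbench:::.efreqBin(big["L", 1:n], 4)
    bins_r <- CCCbench:::.efreqBin(big["R", 1:n], 4)
    expect_lt(CCCbench:::.mutualInfo2(bins_l, bins_r), 0.05)
    # dependent genes carry high MI
    dep <- big["L", 1:n]
    expect_gt(CCCbench:::.mutualInfo2(CCCbench:::.efreqBin(dep, 4),
                                      CCCbench:::.efreqBin(dep, 4)), 1)
})

test_that("small clusters reduce the crosstalk bin count with a warning", {
    norm <- cbind(toyNorm(), toyNorm()[, 1:2])
    cl <- c(toyClusters(), "Z", "Z")
    expect_warning(scoreCrosstalk(norm, toyResource(), clusters = cl),
                   "reducing bins")
})

test_that("deterministic methods are invariant under cell permutation", {
    norm <- toyNorm()
    set.seed(14)
    perm <- sample(ncol(norm))
    res <- toyResource()
    for (f in list(scoreConnectome, scoreNATMI, scoreLogFCMean,
                   scoreCrosstalk)) {
        a <- f(norm, res, clusters = toyClusters())
        b <- f(norm[, perm], res, clusters = toyClusters()[perm])
        expect_equal(a[order(a$source, a$target, a$ligand_complex), ],
                     b[order(b$source, b$target, b$ligand_complex), ],
                     ignore_attr = TRUE, tolerance = 1e-12)
    }
})

test_that("a complex never outscores its weakest subunit as a singleton", {
    norm <- toyNorm()
    res <- lrResource(c("LIG", "LIG"), c("HOUSE_RARE", "RARE"))
    out <- scoreNATMI(norm, res, methodConfig(prop_threshold = 0),
                      clusters = toyClusters())
    cx <- out[out$receptor_complex == "HOUSE_RARE", ]
    sg <- out[out$receptor_complex == "RARE", ]
    key <- paste(cx$source, cx$target)
    expect_true(all(cx$score_magnitude <=
                    sg$score_magnitude[match(key, paste(sg$source, sg$target))] + 1e-12))
})

test_that("scoreMethods runs all six methods on one stats pass", {
    out <- scoreMethods(toySCE(), toyResource(), config = cfgFast)
    expect_setequal(unique(out$method), scoringMethods())
    expect_true(all(c("source", "target", "ligand_complex",
                      "receptor_complex", "score_magnitude",
                      "score_specificity", "p_value") %in% colnames(out)))
    expect_error(scoreMethods(toySCE(), toyResource(), methods = "nope"),
                 "unknown methods")
})
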