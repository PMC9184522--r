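test_that("pseudobulk filters follow the strict count and inclusive proportion boundaries", {
    # one cluster of 10 cells; gene sums 5 vs 6, prop exactly 10%
    counts <- rbind(SUM5 = c(5, rep(0, 9)),
                    SUM6 = c(6, rep(0, 9)),
                    ZERO = rep(0, 10),
                    BOTH = rep(1, 10))
    counts <- cbind(counts, counts)  # second cluster identical
    cl <- rep(c("A", "B"), each = 10)
    pb <- buildPseudobulk(counts, cl)
    expect_true(is.na(pb["SUM5", "A"]))        # summed count 5 excluded
    expect_false(is.na(pb["SUM6", "A"]))       # 6 with prop 0.10 included
    expect_true(is.na(pb["ZERO", "A"]))
    expect_equal(pb["BOTH", "A"], log2(11))
    expect_error(buildPseudobulk(counts, factor(cl, levels = c("A", "B", "C"))),
                 "empty cluster")
})

test_that("mlm activities recover an orthogonal planted signal", {
    set.seed(41)
    genes <- sprintf("g%03d", 1:60)
    S <- matrix(0, 60, 3, dimnames = list(genes, c("cytA", "cytB", "cytC")))
    S[1:20, 1] <- rnorm(20); S[21:40, 2] <- rnorm(20); S[41:60, 3] <- rnorm(20)
    y <- setNames(as.numeric(2 * S[, 2]) + rnorm(60, 0, 0.1), genes)
    act <- mlmActivities(y, S)
    expect_equal(act$cytokine[which.max(act$score)], "cytB")
    expect_true(all(abs(act$score[act$cytokine != "cytB"]) < 3))
    expect_gt(act$score[act$cytokine == "cytB"], 20)
    # least-squares check: fitted coefficient of cytB is near 2
    fit <- lm(y ~ S)
    expect_equal(unname(coef(fit)["ScytB"]), 2, tolerance = 0.05)
    # gene order is irrelevant
    perm <- sample(60)
    act2 <- mlmActivities(y[perm], S)
    expect_equal(act$score, act2$score, tolerance = 1e-9)
    # profile orthogonal to every signature: no strong scores
    y0 <- setNames(rnorm(60, 0, 0.1), genes)
    expect_true(all(abs(mlmActivities(y0, S)$score) < 3))
    # collinear designs are rejected by name
    S2 <- cbind(S, cytD = S[, 1])
    expect_error(mlmActivities(y, S2), "cytD|collinear")
    expect_error(mlmActivities(y[1:3], S), "fewer than")
})

test_that("mlm t-value signs track planted coefficients", {
    set.seed(43)
    genes <- sprintf("g%03d", 1:90)
    S <- matrix(rnorm(90 * 4), 90, 4,
                dimnames = list(genes, paste0("c", 1:4)))
    hits <- 0
    for (rep_ in 1:40) {
        beta <- sample(c(-3, 3), 4, replace = TRUE)
        y <- setNames(as.numeric(S %*% beta + rnorm(90)), genes)
        act <- mlmActivities(y, S)
        hits <- hits + all(sign(act$score) == sign(beta))
    }
    expect_gte(hits / 40, 0.95)
})

test_that("active cytokine calls use positive score and inclusive FDR 0.05", {
    act <- list(
        T1 = data.frame(cytokine = c("a", "b", "c"),
                        score = c(2, -2, 1.5), p = c(0.001, 0.001, 0.2),
                        fdr = c(0.05, 0.001, 0.2)))
    calls <- callActiveCytokines(act)
    expect_setequal(calls$positive, "a|T1")       # fdr = 0.05 inclusive
    expect_setequal(calls$negative, c("b|T1", "c|T1"))
    empty <- callActiveCytokines(list())
    expect_equal(length(empty$universe), 0L)
})

test_that("proportion colocalization calls the most correlated pairs", {
    set.seed(51)
    n <- 200
    f <- rgamma(n, 2)
    base <- matrix(rgamma(n * 6, 2), n, 6,
                   dimnames = list(NULL, paste0("K", 1:6)))
    base[, 1] <- base[, 1] + 3 * f
    base[, 2] <- base[, 2] + 3 * f
    P <- base / rowSums(base)
    calls <- colocalizationFromProportions(P)
    expect_true("K1|K2" %in% calls$positive)
    z <- attr(calls, "z")
    expect_equal(z$pair[which.max(z$z)], "K1|K2")
    expect_error(colocalizationFromProportions(P[1:5, ]), ">= 10 spots")
    # constant column: affected pairs negative, with a warning
    P2 <- cbind(P * 0.9, K7 = 0.1)
    expect_warning(c2 <- colocalizationFromProportions(P2), "constant")
    expect_false(any(grepl("K7", c2$positive)))
})

test_that("independent spot proportions yield about 5 percent positives", {
    set.seed(53)
    rates <- vapply(1:20, function(i) {
        P <- matrix(rgamma(300 * 15, 2), 300, 15,
                    dimnames = list(NULL, paste0("K", 1:15)))
        P <- P / rowSums(P)
        calls <- colocalizationFromProportions(P)
        length(calls$positive) / length(calls$universe)
    }, 0)
    expect_lt(abs(mean(rates) - 0.05), 0.04)
})

test_that("z-score colocalization thresholds at 1.645 inclusive", {
    Z <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    Z["A", "B"] <- Z["B", "A"] <- 1.645
    Z["A", "C"] <- Z["C", "A"] <- 1.644
    calls <- colocalizationFromZscores(Z)
    expect_setequal(calls$positive, "A|B")
    none <- colocalizationFromZscores(matrix(0, 2, 2,
        dimnames = list(c("A", "B"), c("A", "B"))))
    expect_equal(length(none$positive), 0L)
    expect_error(colocalizationFromZscores(matrix(0, 2, 3)), "square")
})

test_that("odds-ratio curves match the Fisher oracle and flag capped ratios", {
    set.seed(61)
    n <- 60
    rk <- data.frame(rank = 1:n, key = sprintf("k%02d", 1:n))
    calls <- CCCbench:::.modalityCalls(sprintf("k%02d", 1:20),
                                       sprintf("k%02d", 21:60))
    curve <- oddsRatioCurve(rk, calls, function(row) row$key,
                            cutoffs = c(10, 30))
    for (i in seq_len(nrow(curve))) {
        N <- curve$cutoff[i]
        a <- sum(1:n <= N & 1:n <= 20); b <- sum(1:n <= N & 1:n > 20)
        c_ <- 20 - a; d <- 40 - b
        expect_equal(curve$fisher_p[i], fisherEnumP(a, b, c_, d),
                     tolerance = 1e-10)
        expect_equal(curve$odds_ratio[i],
                     if (any(c(a, b, c_, d) == 0))
                         ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
                     else (a * d) / (b * c_))
    }
    # perfect separation at the exact cutoff: infinite OR flagged
    sep <- oddsRatioCurve(rk, calls, function(row) row$key, cutoffs = 20)
    expect_true(sep$capped)
    expect_error(oddsRatioCurve(rk, calls, function(row) row$key,
                                cutoffs = c(10, 10)), "strictly increasing")
    expect_error(oddsRatioCurve(rk, calls, function(row) NA, cutoffs = 10),
                 "universe")
})

test_that("rankings independent of the calls give odds ratios near 1", {
    set.seed(63)
    n <- 2000
    keys <- sprintf("k%04d", 1:n)
    pos <- sample(keys, 400)
    calls <- CCCbench:::.modalityCalls(pos, setdiff(keys, pos))
    ors <- vapply(1:30, function(i) {
        rk <- data.frame(rank = 1:n, key = sample(keys))
        oddsRatioCurve(rk, calls, function(row) row$key,
                       cutoffs = 500)$odds_ratio
    }, 0)
    expect_lt(abs(mean(ors) - 1), 0.1)
})

test_that("receptor specificity evaluation has the expected extremes", {
    set.seed(71)
    A <- matrix(rlnorm(80, log(5), 0.2), 10, 8,
                dimnames = list(sprintf("R%02d", 1:10), paste0("K", 1:8)))
    A[1, 1] <- A[1, 1] * 20
    A[2, 2] <- A[2, 2] * 20
    A[3, 3] <- A[3, 3] * 20
    Z <- t(scale(t(clrTransform(A))))
    pos <- which(Z >= 1.645)
    # perfect separation: predictions score positives above everything
    pred <- expand.grid(receptor = rownames(A), cluster = colnames(A),
                        stringsAsFactors = FALSE)
    pred$score <- as.numeric(Z >= 1.645) * 10 + runif(nrow(pred))
    ev <- receptorSpecificityEval(pred, A, n_draws = 25, seed = 3)
    expect_equal(ev$auroc, 1)
    expect_equal(ev$auprc, 1)
    # a monotone transform of the scores leaves AUROC unchanged
    pred2 <- transform(pred, score = exp(score / 5))
    ev2 <- receptorSpecificityEval(pred2, A, n_draws = 5, seed = 3)
    expect_equal(ev2$auroc, ev$auroc)
    expect_error(receptorSpecificityEval(pred, matrix(1, 3, 3)), "fewer than 2")
})

test_that("random scores give downsampled AUPRC near one half", {
    set.seed(73)
    A <- matrix(rlnorm(150 * 8, log(5), 0.2), 150, 8,
                dimnames = list(sprintf("R%03d", 1:150), paste0("K", 1:8)))
    for (i in 1:100) A[i, (i %% 8) + 1] <- A[i, (i %% 8) + 1] * 15
    pred <- expand.grid(receptor = rownames(A), cluster = colnames(A),
                        stringsAsFactors = FALSE)
    pred$score <- runif(nrow(pred))
    ev <- receptorSpecificityEval(pred, A, n_draws = 100, seed = 9)
    expect_lt(abs(ev$auprc - 0.5), 0.05)
})
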