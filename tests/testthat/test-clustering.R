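test_that("K-means recovers separable column groups deterministically", {
    h <- cbind(matrix(0, 2, 5), matrix(10, 2, 5)) +
        matrix(runif(20, 0, 0.01), 2, 10)
    colnames(h) <- sprintf("s%02d", 1:10)
    a <- clusterEmbedding(h, k = 2, seed = 1)
    expect_identical(unname(domainLabels(a)), rep(c(1L, 2L), each = 5))
    b <- clusterEmbedding(h, k = 2, seed = 1)
    expect_identical(domainLabels(a), domainLabels(b))
    expect_named(domainLabels(a), colnames(h))

    ## two tight jittered clusters: assignment equals the obvious optimum
    set.seed(2)
    h2 <- cbind(matrix(rnorm(12, 0, 0.05), 2, 6),
                matrix(rnorm(12, 10, 0.05), 2, 6))
    a2 <- clusterEmbedding(h2, k = 2, seed = 3)
    expect_identical(unname(domainLabels(a2)), rep(c(1L, 2L), each = 6))

    expect_error(clusterEmbedding(matrix(1, 2, 5), k = 2), "distinct")
})

test_that("ARI matches hand-worked and oracle values and is label-invariant", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(adjustedRandIndex(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
    set.seed(6)
    for (i in 1:25) {
        pred <- sample(1:4, 40, replace = TRUE)
        truth <- sample(1:3, 40, replace = TRUE)
        o <- oraclePairMetrics(pred, truth)
        expect_equal(adjustedRandIndex(pred, truth), o$ari)
        ## label permutation invariance
        perm <- sample(4)
        expect_equal(adjustedRandIndex(perm[pred], truth), o$ari)
        ## cross-check against an independent implementation
        expect_equal(adjustedRandIndex(pred, truth),
                     mclust::adjustedRandIndex(pred, truth),
                     tolerance = 1e-12)
    }
})

test_that("NMI matches the contingency double-sum oracle", {
    expect_equal(normalizedMutualInfo(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
    expect_equal(normalizedMutualInfo(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
    set.seed(8)
    for (i in 1:25) {
        pred <- sample(1:5, 60, replace = TRUE)
        truth <- sample(1:4, 60, replace = TRUE)
        o <- oraclePairMetrics(pred, truth)
        expect_equal(normalizedMutualInfo(pred, truth), o$nmi,
                     tolerance = 1e-12)
    }
})

test_that("purity matches explicit intersections and refinement raises it", {
    ## clusters {1,3} and {2,4} against truth a,a,b,b: purity 0.5
    expect_equal(purityScore(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0.5)
    expect_equal(purityScore(1:6, rep(1:2, 3)), 1)  # singletons are pure
    set.seed(10)
    for (i in 1:20) {
        pred <- sample(1:3, 30, replace = TRUE)
        truth <- sample(1:3, 30, replace = TRUE)
        o <- oraclePairMetrics(pred, truth)
        expect_equal(purityScore(pred, truth), o$pur)
        ## split one cluster in two: purity cannot decrease
        split <- pred
        idx <- which(pred == 1)
        split[idx[seq_len(length(idx) %/% 2)]] <- 4L
        expect_gte(purityScore(split, truth), o$pur)
    }
})

test_that("marker screen ranks exclusive genes first and applies filters", {
    set.seed(12)
    labels <- rep(1:2, each = 15)
    x <- matrix(runif(20 * 30, 0.5, 1), 20, 30,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    x["g05", labels == 1] <- 10      # strong exclusive marker of domain 1
    x["g05", labels == 2] <- 0.01
    ## g07 expressed in only 20% of domain-1 spots: excluded at minFrac 0.25
    x["g07", ] <- 0
    x["g07", which(labels == 1)[1:3]] <- 50
    mk <- rankMarkerGenes(x, labels, minFrac = 0.25, minAbsLfc = 0.25)
    d1 <- mk[mk$domain == 1, ]
    expect_identical(d1$gene[d1$rank == 1], "g05")
    expect_false("g07" %in% d1$gene)
    expect_true(all(abs(mk$log2fc) >= 0.25))
    expect_true(all(mk$pvalue >= 0 & mk$pvalue <= 1))

    ## tiny domain is skipped with a warning
    expect_warning(rankMarkerGenes(x, c(rep(1, 2), rep(2, 28))),
                   "fewer than 3")
})

test_that("Wilcoxon p-values agree with exhaustive enumeration", {
    set.seed(14)
    for (i in 1:5) {
        a <- runif(5); b <- runif(5) + 0.3
        pEnum <- oracleWilcoxExact(a, b)
        pPkg <- wilcox.test(a, b)$p.value
        expect_equal(pPkg, pEnum, tolerance = 1e-12)
    }
})
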