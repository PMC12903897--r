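test_that("expression distances match a naive double loop", {
    expect_equal(expressionDistances(cbind(c(0, 0), c(3, 4)))[1, 2], 5)
    x <- matrix(runif(10 * 20), 10, 20)
    d <- expressionDistances(x)
    expect_equal(diag(d), rep(0, 20))
    naive <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20)
        naive[i, j] <- sqrt(sum((x[, i] - x[, j])^2))
    expect_equal(d, naive, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("adaptive row reproduces the worked closed-form cases", {
    r <- adaptiveRow(c(1, 1, 4), sigma = 0)
    expect_equal(r$probs, c(0.5, 0.5, 0))
    expect_identical(r$k, 2L)
    expect_equal(r$zeta, 4)
    expect_equal(sum(r$probs), 1)

    r2 <- adaptiveRow(c(1, 9, 9), sigma = 0)
    expect_equal(r2$probs, c(5 / 7, 1 / 7, 1 / 7))
    expect_identical(r2$k, 3L)
    expect_equal(sum(r2$probs), 1)

    ## equal distances: symmetry forces uniform probabilities
    r3 <- adaptiveRow(rep(2.5, 4), sigma = 0)
    expect_equal(r3$probs, rep(0.25, 4))
})

test_that("adaptive row probabilities are monotone and properly clipped", {
    set.seed(3)
    for (rep in 1:20) {
        d <- sort(runif(12, 0.05, 4))
        sg <- sample(c(0, 0.3, 0.5), 1)
        r <- adaptiveRow(d, sg)
        expect_true(all(diff(r$probs) <= 1e-12))
        expect_true(all(r$probs >= 0 & r$probs < 1))
        if (r$k < 12) expect_equal(r$probs[(r$k + 1):12], rep(0, 12 - r$k))
    }
    expect_error(adaptiveRow(c(1, 2), sigma = 1), "sigma")
    expect_warning(adaptiveRow(rep(0, 5), 0), "duplicate")
})

test_that("expression graph is symmetric, hollow and mutual-kNN supported", {
    set.seed(9)
    x <- matrix(runif(8 * 30), 8, 30)
    g <- buildExpressionGraph(x, k1Max = 6, sigma = 0.3)
    A <- adjacency(g)
    expect_true(Matrix::isSymmetric(A, tol = 0))
    expect_equal(max(abs(Matrix::diag(A))), 0)
    expect_true(all(A >= 0))

    ## mutual-neighbor support equals the brute-force set intersection
    d <- expressionDistances(x)
    nbr <- lapply(1:30, function(i) {
        di <- d[i, ]; di[i] <- Inf
        cand <- order(di, seq_len(30))[1:6]
        r <- adaptiveRow(di[cand], 0.3)
        cand[seq_len(r$k)]
    })
    support <- matrix(FALSE, 30, 30)
    for (i in 1:30) for (j in nbr[[i]])
        if (i %in% nbr[[j]]) support[i, j] <- TRUE
    expect_identical(unname(as.matrix(A > 0)), support | t(support))

    expect_error(buildExpressionGraph(x, k1Max = 30), "k1Max")
})

test_that("well-separated expression clusters get no cross edges", {
    x <- cbind(matrix(runif(5 * 10, 0, 0.1), 5, 10),
               matrix(runif(5 * 10, 0, 0.1) + 100, 5, 10))
    g <- buildExpressionGraph(x, k1Max = 12, sigma = 0.3)
    A <- as.matrix(adjacency(g))
    expect_equal(max(A[1:10, 11:20]), 0)
})

test_that("spatial graph implements mutual kNN with index tie-breaks", {
    ## three collinear points, k2 = 1: spot 2's NN is spot 1 by the tie rule,
    ## so only the (1,2) edge is mutual
    coords <- rbind(c(0, 1, 2), c(0, 0, 0))
    g <- buildSpatialGraph(coords, k2 = 1)
    A <- as.matrix(adjacency(g))
    expect_equal(A, rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
                 ignore_attr = TRUE)

    ## interior spots of a square lattice have degree 4 at k2 = 4
    lay <- generateLayout(7, 7, 2, "stripes")
    g2 <- buildSpatialGraph(lay$coords, k2 = 4)
    deg <- degrees(g2)
    interior <- lay$coords["array_row", ] %in% 2:6 &
        lay$coords["array_col", ] %in% 2:6
    expect_true(all(deg[interior] == 4))

    ## binary, symmetric, hollow on arbitrary input
    g3 <- randomSpatialGraph(25, 3, seed = 4)
    A3 <- adjacency(g3)
    expect_true(all(A3@x %in% 1))
    expect_true(Matrix::isSymmetric(A3, tol = 0))
    expect_equal(max(abs(Matrix::diag(A3))), 0)
})

test_that("Laplacians have zero row sums, PSD spectrum, and the trace form", {
    expect_equal(as.matrix(laplacian(spotGraph(rbind(c(0, 1), c(1, 0))))),
                 rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
    expect_error(spotGraph(rbind(c(0, 1), c(0, 0))), "symmetric")

    for (g in list(randomSpatialGraph(20, 4, seed = 2),
                   randomExpressionGraph(20, 10, 5, 0.3, seed = 2))) {
        L <- as.matrix(laplacian(g))
        expect_lt(max(abs(rowSums(L))), 1e-12)
        expect_gt(min(eigen(L, symmetric = TRUE,
                            only.values = TRUE)$values), -1e-10)
        ## Tr(H L H^T) = 1/2 sum_ij A_ij ||h_i - h_j||^2
        set.seed(1)
        H <- matrix(rnorm(3 * 20), 3, 20)
        A <- as.matrix(adjacency(g))
        quad <- sum((H %*% L) * H)
        pair <- 0
        for (i in 1:20) for (j in 1:20)
            pair <- pair + A[i, j] * sum((H[, i] - H[, j])^2)
        expect_equal(quad, pair / 2, tolerance = 1e-10)
        expect_gte(quad, -1e-10)
    }
})

test_that("sigma selection finds the community elbow on 3-domain data", {
    sim <- simulateSpatialDataset(rows = 12, cols = 12, k = 3,
                                  layout = "stripes", nGenes = 120,
                                  nMarkersPerDomain = 15, seed = 21)
    pp <- preprocessCounts(SummarizedExperiment::assay(sim), tau = 0.95,
                           mHvg = 120)
    sel <- selectSigma(pp$xFiltered, k1Max = 15, seed = 1)
    expect_true(sel$sigma %in% seq(0.1, 0.9, by = 0.1))
    g <- buildExpressionGraph(pp$xFiltered, k1Max = 15, sigma = sel$sigma)
    ig <- igraph::graph_from_adjacency_matrix(adjacency(g),
                                              mode = "undirected",
                                              weighted = TRUE)
    set.seed(1)
    nc <- length(igraph::cluster_louvain(ig))
    expect_lte(abs(nc - 3), 2)
})
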