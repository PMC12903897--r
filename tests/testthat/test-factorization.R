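test_that("objective evaluates the fit and both graph penalties", {
    set.seed(5)
    w <- matrix(runif(12), 4, 3)
    h <- matrix(runif(18), 3, 6)
    x <- w %*% h
    g1 <- randomSpatialGraph(6, 2, seed = 1)
    g2 <- randomSpatialGraph(6, 3, seed = 2)
    L1 <- laplacian(g1); L2 <- laplacian(g2)
    expect_equal(jgrnmfObjective(x, w, h, L1, L2, 0, 0), 0)

    ## constant embedding columns sit in the Laplacian null space
    hc <- matrix(rep(runif(3), 6), 3, 6)
    expect_equal(jgrnmfObjective(x, w, hc, L1, L2, 1, 1),
                 sum((x - w %*% hc)^2), tolerance = 1e-10)

    ## term-by-term naive computation
    a1 <- 0.7; a2 <- 0.25
    xr <- x + 0.1
    naive <- sum((xr - w %*% h)^2) +
        a1 * sum(diag(h %*% as.matrix(L1) %*% t(h))) +
        a2 * sum(diag(h %*% as.matrix(L2) %*% t(h)))
    expect_equal(jgrnmfObjective(xr, w, h, L1, L2, a1, a2), naive,
                 tolerance = 1e-10)
    ## penalty is linear in alpha: doubling alpha1 doubles the gap
    base <- jgrnmfObjective(xr, w, h, L1, L2, 0, 0)
    gap1 <- jgrnmfObjective(xr, w, h, L1, L2, a1, 0) - base
    gap2 <- jgrnmfObjective(xr, w, h, L1, L2, 2 * a1, 0) - base
    expect_equal(gap2, 2 * gap1, tolerance = 1e-10)

    expect_error(jgrnmfObjective(x, w[, 1:2], h, L1, L2, 0, 0), "shape")
})

test_that("W update has the exact-factorization fixed point and loop form", {
    set.seed(8)
    w <- matrix(runif(12), 4, 3)
    h <- matrix(runif(15), 3, 5)
    x <- w %*% h
    expect_equal(updateW(x, w, h), w, tolerance = 1e-9)

    w0 <- w; w0[2, 1] <- 0
    expect_equal(updateW(x, w0, h)[2, 1], 0)

    ## naive loop evaluation of one step
    xr <- matrix(runif(20), 4, 5)
    step <- oracleNMFStep(xr, w, h)
    expect_equal(updateW(xr, w, h), step$w, tolerance = 1e-12)
})

test_that("H update reduces to vanilla NMF at alpha = 0 and matches loops", {
    set.seed(13)
    w <- matrix(runif(12), 4, 3)
    h <- matrix(runif(15), 3, 5)
    x <- w %*% h
    s <- ncol(h)
    A0 <- Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                               dims = c(s, s))
    expect_equal(updateH(x, w, h, A0, A0, rep(0, s), rep(0, s), 0, 0), h,
                 tolerance = 1e-9)
    h0 <- h; h0[1, 3] <- 0
    expect_equal(updateH(x, w, h0, A0, A0, rep(0, s), rep(0, s), 0, 0)[1, 3],
                 0)

    g1 <- randomSpatialGraph(5, 2, seed = 3)
    g2 <- randomSpatialGraph(5, 2, seed = 4)
    xr <- matrix(runif(20), 4, 5)
    got <- updateH(xr, w, h, adjacency(g1), adjacency(g2),
                   degrees(g1), degrees(g2), 0.6, 0.2)
    want <- oracleUpdateH(xr, w, h, adjacency(g1), adjacency(g2),
                          degrees(g1), degrees(g2), 0.6, 0.2)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fit is deterministic under a fixed seed", {
    x <- matrix(runif(30 * 25), 30, 25)
    g1 <- randomSpatialGraph(25, 3, seed = 1)
    g2 <- randomSpatialGraph(25, 4, seed = 2)
    f1 <- jgrnmf(x, g1, g2, f = 3, maxIter = 40, seed = 11)
    f2 <- jgrnmf(x, g1, g2, f = 3, maxIter = 40, seed = 11)
    expect_identical(basisMatrix(f1), basisMatrix(f2))
    expect_identical(embeddingMatrix(f1), embeddingMatrix(f2))
    expect_identical(objectiveTrace(f1), objectiveTrace(f2))
    f3 <- jgrnmf(x, g1, g2, f = 3, maxIter = 40, seed = 12)
    expect_false(identical(embeddingMatrix(f1), embeddingMatrix(f3)))
})

test_that("objective is non-increasing and factors stay non-negative", {
    set.seed(2)
    x <- matrix(runif(40 * 30), 40, 30)
    g1 <- randomExpressionGraph(30, 15, 6, 0.3, seed = 5)
    g2 <- randomSpatialGraph(30, 4, seed = 6)
    fit <- jgrnmf(x, g1, g2, alpha1 = 0.8, alpha2 = 0.4, f = 4,
                  maxIter = 120, epsilon = 1e-300, seed = 3)
    tr <- objectiveTrace(fit)
    expect_true(all(diff(tr) <= 1e-9 * abs(tr[-length(tr)])))
    expect_gte(min(basisMatrix(fit)), 0)
    expect_gte(min(embeddingMatrix(fit)), 0)
    expect_false(isConverged(fit))
})

test_that("alpha = 0 trajectory equals the classical multiplicative NMF", {
    set.seed(17)
    m <- 8; s <- 10; f <- 3
    x <- matrix(runif(m * s), m, s)
    w <- matrix(runif(m * f), m, f)
    h <- matrix(runif(f * s), f, s)
    fit <- jgrnmf(x, NULL, NULL, alpha1 = 0, alpha2 = 0, f = f,
                  maxIter = 25, epsilon = 1e-300, seed = 1,
                  init = list(W = w, H = h))
    wo <- w; ho <- h
    for (t in 1:25) {
        stp <- oracleNMFStep(x, wo, ho)
        wo <- stp$w; ho <- stp$h
    }
    expect_equal(basisMatrix(fit), wo, tolerance = 1e-10)
    expect_equal(embeddingMatrix(fit), ho, tolerance = 1e-10)
})

test_that("exact low-rank matrices are recovered at alpha = 0", {
    set.seed(4)
    wTrue <- matrix(runif(40 * 4), 40, 4)
    hTrue <- matrix(runif(4 * 50), 4, 50)
    x <- wTrue %*% hTrue
    fit <- jgrnmf(x, NULL, NULL, alpha1 = 0, alpha2 = 0, f = 4,
                  maxIter = 10000L, epsilon = 1e-12, seed = 2)
    rel <- norm(x - basisMatrix(fit) %*% embeddingMatrix(fit), "F") /
        norm(x, "F")
    expect_lt(rel, 1e-3)
})
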