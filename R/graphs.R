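## Spot-spot graph construction: the adaptive expression-neighbor graph with
## per-spot neighborhood sizes from a KKT closed form, and the spatial mutual
## kNN graph, plus their unnormalized Laplacians.

#' Construct a SpotGraph from an adjacency matrix
#'
#' Validates the adjacency (symmetric, non-negative, zero diagonal) and
#' attaches the degree diagonal \eqn{D_{ii} = \sum_{i'} A_{ii'}} and the
#' unnormalized Laplacian \eqn{L = D - A}.
#'
#' @param adjacency symmetric non-negative spot-spot matrix with zero
#'   diagonal (dense or sparse).
#' @param kind `"expression"` or `"spatial"`.
#' @return a [SpotGraph-class] object.
#' @export
spotGraph <- function(adjacency, kind = c("expression", "spatial")) {
    kind <- match.arg(kind)
    A <- as(as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"),
            "CsparseMatrix")
    if (!Matrix::isSymmetric(A, tol = 0))
        stop("adjacency must be exactly symmetric")
    A <- Matrix::drop0(A)
    deg <- Matrix::rowSums(A)
    L <- Matrix::Diagonal(x = deg) - A
    new("SpotGraph", adjacency = A, degrees = as.numeric(deg),
        laplacian = as(as(L, "generalMatrix"), "CsparseMatrix"), kind = kind)
}

#' Pairwise expression distances between spots
#'
#' Euclidean distances between spot columns of the (spot-normalized)
#' expression matrix.
#'
#' @param x genes x spots matrix.
#' @return dense s x s symmetric distance matrix with zero diagonal.
#' @export
expressionDistances <- function(x) {
    if (is(x, "Matrix")) x <- as.matrix(x)
    if (ncol(x) < 2L) stop("at least two spots are required")
    d <- as.matrix(stats::dist(t(x)))
    dimnames(d) <- list(colnames(x), colnames(x))
    d
}

#' Adaptive neighbor probabilities for one spot
#'
#' Given the ascending distances from a spot to its `k1Max` nearest other
#' spots, computes the closed-form connection probabilities that minimize the
#' row objective \eqn{\sum_l d_l / (1 - E_l)} under the residual-adjusted sum
#' constraint: with
#' \eqn{\sqrt{\zeta} = \sum_l \sqrt{d_l} / (k_{max} - 1 - \sigma)}, the
#' probability of the l-th neighbor is
#' \eqn{E_l = \max(0, 1 - \sqrt{d_l}/\sqrt{\zeta})}, and the selected
#' neighbor count is \eqn{k = \#\{l : d_l < \zeta\}} (clamped to at least one
#' neighbor).
#'
#' @param distSorted ascending non-negative distances to the `k1Max` nearest
#'   other spots.
#' @param sigma residual parameter; must satisfy
#'   `length(distSorted) - 1 - sigma > 0`.
#' @return list with `probs` (probabilities, zero beyond the selected
#'   neighbors), `k` (selected neighbor count), and `zeta` (the adaptive
#'   radius).
#' @export
adaptiveRow <- function(distSorted, sigma = 0) {
    k1Max <- length(distSorted)
    stopifnot(k1Max >= 2L, all(distSorted >= 0),
              !is.unsorted(distSorted))
    if (k1Max - 1 - sigma <= 0)
        stop("require k1Max - 1 - sigma > 0 (k1Max = ", k1Max,
             ", sigma = ", sigma, ")")
    if (all(distSorted == 0)) {
        warning("all candidate distances are zero (duplicate spots); ",
                "using uniform connection probabilities")
        return(list(probs = rep(1 / k1Max, k1Max), k = k1Max, zeta = 0))
    }
    sqrtZeta <- sum(sqrt(distSorted)) / (k1Max - 1 - sigma)
    zeta <- sqrtZeta^2
    probs <- pmax(0, 1 - sqrt(distSorted) / sqrtZeta)
    k <- sum(distSorted < zeta)
    if (k < 1L) k <- 1L  # keep the single nearest neighbor, clipped weight
    if (k < k1Max) probs[(k + 1L):k1Max] <- 0
    list(probs = probs, k = as.integer(k), zeta = zeta)
}

## Per-spot neighbor candidates by ascending distance, self excluded,
## distance ties broken toward the smaller spot index.
.nearestNeighbors <- function(d, k) {
    s <- nrow(d)
    idx <- matrix(0L, s, k)
    dst <- matrix(0, s, k)
    for (i in seq_len(s)) {
        di <- d[i, ]
        di[i] <- Inf
        ord <- order(di, seq_len(s))[seq_len(k)]
        idx[i, ] <- ord
        dst[i, ] <- di[ord]
    }
    list(idx = idx, dist = dst)
}

#' Build the adaptive expression-neighbor graph
#'
#' For every spot, connection probabilities over its `k1Max` nearest other
#' spots (Euclidean distance between expression profiles) are computed with
#' [adaptiveRow()]; an edge is retained only when both endpoints select each
#' other (mutual membership in the adaptive neighbor sets), and the two
#' directed probabilities are averaged to give a symmetric adjacency.
#'
#' @param x genes x spots expression matrix (typically the spot-normalized
#'   matrix X').
#' @param k1Max maximum neighbors per spot; `2 <= k1Max <` number of spots.
#' @param sigma residual parameter of the closed form (see [adaptiveRow()]).
#' @return a [SpotGraph-class] of kind `"expression"`.
#' @export
buildExpressionGraph <- function(x, k1Max = 30L, sigma = 0.3) {
    s <- ncol(x)
    if (k1Max >= s) stop("k1Max must be smaller than the number of spots")
    if (k1Max < 2L) stop("k1Max must be at least 2")
    d <- expressionDistances(x)
    .expressionGraphFromDistances(d, k1Max, sigma, colnames(x))
}

.expressionGraphFromDistances <- function(d, k1Max, sigma, ids = NULL) {
    s <- nrow(d)
    nn <- .nearestNeighbors(d, k1Max)
    kSel <- integer(s)
    probRows <- matrix(0, s, k1Max)
    for (i in seq_len(s)) {
        ar <- adaptiveRow(nn$dist[i, ], sigma)
        kSel[i] <- ar$k
        probRows[i, ] <- ar$probs
    }
    ## directed adjacency restricted to each spot's selected neighbor set
    ii <- rep(seq_len(s), times = kSel)
    sel <- sequence(kSel)
    jj <- nn$idx[cbind(ii, sel)]
    pp <- probRows[cbind(ii, sel)]
    P <- Matrix::sparseMatrix(i = ii, j = jj, x = pp, dims = c(s, s))
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(s, s))
    mutual <- S * Matrix::t(S)      # 1 iff i' in N_i and i in N_i'
    Ahat <- P * mutual
    A <- (Ahat + Matrix::t(Ahat)) / 2
    A <- Matrix::drop0(A)
    dimnames(A) <- list(ids, ids)
    spotGraph(A, kind = "expression")
}

#' Build the spatial mutual k-nearest-neighbor graph
#'
#' Binary adjacency over spot coordinates: \eqn{A_{ii'} = 1} iff spots i and
#' i' each list the other among their `k2` nearest neighbors by Euclidean
#' distance (ties broken toward the smaller spot index).
#'
#' @param coords 2 x spots coordinate matrix (or spots x 2, auto-detected
#'   when unambiguous).
#' @param k2 neighbors per spot; default 6, the hexagonal Visium neighborhood.
#' @return a [SpotGraph-class] of kind `"spatial"`.
#' @export
buildSpatialGraph <- function(coords, k2 = 6L) {
    coords <- as.matrix(coords)
    if (nrow(coords) != 2L && ncol(coords) == 2L) coords <- t(coords)
    s <- ncol(coords)
    if (k2 < 1L || k2 >= s) stop("require 1 <= k2 < number of spots")
    d <- as.matrix(stats::dist(t(coords)))
    nn <- .nearestNeighbors(d, k2)
    ii <- rep(seq_len(s), each = k2)
    jj <- as.integer(t(nn$idx))
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(s, s))
    A <- Matrix::drop0(S * Matrix::t(S))
    dimnames(A) <- list(colnames(coords), colnames(coords))
    spotGraph(A, kind = "spatial")
}

#' Select sigma by the Louvain community elbow
#'
#' Builds the adaptive expression graph for each value of `grid`, runs
#' Louvain community detection on the weighted graph, and returns the sigma
#' immediately preceding the sharpest relative increase in community count.
#' If no consecutive increase exceeds 1.5x, the grid median is returned.
#' Ties are broken toward the smaller sigma.
#'
#' @param x genes x spots expression matrix.
#' @param k1Max maximum neighbors per spot.
#' @param grid candidate sigma values, default `seq(0.1, 0.9, by = 0.1)`.
#' @param seed seed for the Louvain runs.
#' @return list with `sigma` (the chosen value) and `communities` (the
#'   community count per grid value; `NA` where the graph was degenerate).
#' @export
selectSigma <- function(x, k1Max = 30L, grid = seq(0.1, 0.9, by = 0.1),
                        seed = 1L) {
    stopifnot(length(grid) >= 1L)
    grid <- sort(grid)
    d <- expressionDistances(x)
    counts <- rep(NA_real_, length(grid))
    for (t in seq_along(grid)) {
        g <- .expressionGraphFromDistances(d, k1Max, grid[t])
        A <- adjacency(g)
        if (Matrix::nnzero(A) == 0L) {
            warning("no edges at sigma = ", grid[t], "; skipping")
            next
        }
        ig <- igraph::graph_from_adjacency_matrix(
            A, mode = "undirected", weighted = TRUE)
        set.seed(seed)
        counts[t] <- length(igraph::cluster_louvain(ig))
    }
    ok <- which(!is.na(counts))
    if (length(ok) < 2L)
        return(list(sigma = stats::median(grid), communities = counts))
    ratios <- counts[ok[-1]] / counts[ok[-length(ok)]]
    if (max(ratios) <= 1.5)
        return(list(sigma = stats::median(grid), communities = counts))
    best <- which.max(ratios)  # which.max returns the first (smallest sigma)
    list(sigma = grid[ok[best]], communities = counts)
}
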