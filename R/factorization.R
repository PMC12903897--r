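## Joint graph-regularized NMF: minimize
##   ||X - WH||_F^2 + alpha1 Tr(H L1 H') + alpha2 Tr(H L2 H')
## over W >= 0, H >= 0 by alternating multiplicative updates. The graph
## matrices enter the H update split as L = D - A so both the numerator and
## the denominator stay non-negative.

.DELTA <- 1e-12  # denominator floor guarding 0/0 in the multiplicative ratios

#' Joint graph-regularized NMF objective
#'
#' Evaluates
#' \eqn{\|X - WH\|_F^2 + \alpha_1 Tr(H L^1 H^T) + \alpha_2 Tr(H L^2 H^T)}.
#'
#' @param x genes x spots matrix (the HVG-standardized matrix).
#' @param w genes x factors basis matrix.
#' @param h factors x spots coefficient matrix.
#' @param L1,L2 spot-spot graph Laplacians (expression and spatial).
#' @param alpha1,alpha2 non-negative regularization weights.
#' @return the scalar objective value.
#' @export
jgrnmfObjective <- function(x, w, h, L1, L2, alpha1, alpha2) {
    if (nrow(w) != nrow(x) || ncol(h) != ncol(x) || ncol(w) != nrow(h))
        stop("incompatible shapes for x, w, h")
    if (nrow(L1) != ncol(x) || nrow(L2) != ncol(x))
        stop("Laplacian dimensions must match the number of spots")
    r <- x - w %*% h
    fit <- sum(r * r)
    pen1 <- if (alpha1 > 0) alpha1 * sum(as.matrix(h %*% L1) * h) else 0
    pen2 <- if (alpha2 > 0) alpha2 * sum(as.matrix(h %*% L2) * h) else 0
    fit + pen1 + pen2
}

#' One multiplicative update of the basis matrix W
#'
#' \eqn{W \leftarrow W \odot (X H^T) \oslash (W H H^T)}, with a small floor
#' on the denominator.
#'
#' @inheritParams jgrnmfObjective
#' @return the updated W.
#' @export
updateW <- function(x, w, h) {
    num <- x %*% t(h)
    den <- w %*% (h %*% t(h))
    w * as.matrix(num) / (as.matrix(den) + .DELTA)
}

#' One multiplicative update of the coefficient matrix H
#'
#' \eqn{H \leftarrow H \odot (W^T X + \alpha_1 H A^1 + \alpha_2 H A^2)
#' \oslash (W^T W H + \alpha_1 H D^1 + \alpha_2 H D^2)}, with a small floor
#' on the denominator. `A1`, `A2` are adjacency matrices and `D1`, `D2` the
#' corresponding degree vectors or diagonal matrices.
#'
#' @inheritParams jgrnmfObjective
#' @param A1,A2 spot-spot adjacency matrices.
#' @param D1,D2 degree vectors (or diagonal matrices) of `A1`, `A2`.
#' @return the updated H.
#' @export
updateH <- function(x, w, h, A1, A2, D1, D2, alpha1, alpha2) {
    if (is(D1, "Matrix") || is.matrix(D1)) D1 <- Matrix::diag(D1)
    if (is(D2, "Matrix") || is.matrix(D2)) D2 <- Matrix::diag(D2)
    num <- as.matrix(crossprod(w, x))
    den <- crossprod(w) %*% h
    if (alpha1 > 0) {
        num <- num + alpha1 * as.matrix(h %*% A1)
        den <- den + alpha1 * h * rep(D1, each = nrow(h))
    }
    if (alpha2 > 0) {
        num <- num + alpha2 * as.matrix(h %*% A2)
        den <- den + alpha2 * h * rep(D2, each = nrow(h))
    }
    h * num / (as.matrix(den) + .DELTA)
}

#' Fit the joint graph-regularized NMF model
#'
#' Alternates [updateW()] and [updateH()] from a seeded uniform(0, 1) random
#' initialization until the max-norm change of H falls below `epsilon` or
#' `maxIter` iterations are reached. The objective is recorded after every
#' iteration and is non-increasing.
#'
#' @param x genes x spots non-negative matrix (the HVG-standardized matrix).
#' @param graph1 expression [SpotGraph-class] (or `NULL` when `alpha1 = 0`).
#' @param graph2 spatial [SpotGraph-class] (or `NULL` when `alpha2 = 0`).
#' @param alpha1,alpha2 non-negative regularization weights; defaults 0.8
#'   and 0.1.
#' @param f number of factors (latent domains).
#' @param epsilon convergence threshold on \eqn{\|H_t - H_{t-1}\|_\infty};
#'   default 1e-4.
#' @param maxIter iteration cap; default 500.
#' @param seed RNG seed for the initialization.
#' @param init optional list with dense non-negative matrices `W` (genes x f)
#'   and `H` (f x spots) overriding the random initialization.
#' @return a [JGRNMFFit-class] object.
#' @export
jgrnmf <- function(x, graph1 = NULL, graph2 = NULL, alpha1 = 0.8,
                   alpha2 = 0.1, f, epsilon = 1e-4, maxIter = 500L,
                   seed = 1L, init = NULL) {
    stopifnot(f >= 1L, epsilon > 0, maxIter >= 1L,
              alpha1 >= 0, alpha2 >= 0)
    if (is(x, "Matrix")) x <- as.matrix(x)
    if (min(x) < 0) stop("x must be non-negative")
    m <- nrow(x); s <- ncol(x)
    zeroGraph <- function() {
        spotGraph(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(s, s)),
                  kind = "spatial")
    }
    if (is.null(graph1)) {
        if (alpha1 > 0) stop("graph1 is required when alpha1 > 0")
        graph1 <- zeroGraph()
    }
    if (is.null(graph2)) {
        if (alpha2 > 0) stop("graph2 is required when alpha2 > 0")
        graph2 <- zeroGraph()
    }
    A1 <- adjacency(graph1); D1 <- degrees(graph1); L1 <- laplacian(graph1)
    A2 <- adjacency(graph2); D2 <- degrees(graph2); L2 <- laplacian(graph2)
    if (nrow(A1) != s || nrow(A2) != s)
        stop("graph dimensions must match the number of spots")

    if (is.null(init)) {
        set.seed(seed)
        w <- matrix(runif(m * f), m, f)
        h <- matrix(runif(f * s), f, s)
    } else {
        w <- init$W; h <- init$H
        stopifnot(is.matrix(w), is.matrix(h), nrow(w) == m, ncol(w) == f,
                  nrow(h) == f, ncol(h) == s, min(w) >= 0, min(h) >= 0)
    }

    objTrace <- numeric(maxIter)
    errTrace <- numeric(maxIter)
    converged <- FALSE
    iter <- 0L
    for (t in seq_len(maxIter)) {
        w <- updateW(x, w, h)
        hNew <- updateH(x, w, h, A1, A2, D1, D2, alpha1, alpha2)
        errH <- max(abs(hNew - h))
        h <- hNew
        obj <- jgrnmfObjective(x, w, h, L1, L2, alpha1, alpha2)
        if (!is.finite(obj) || !is.finite(errH))
            stop("non-finite value encountered at iteration ", t)
        objTrace[t] <- obj
        errTrace[t] <- errH
        iter <- t
        if (errH < epsilon) {
            converged <- TRUE
            break
        }
    }
    new("JGRNMFFit",
        W = w, H = h, alpha1 = alpha1, alpha2 = alpha2,
        objectiveTrace = objTrace[seq_len(iter)],
        errTrace = errTrace[seq_len(iter)],
        iterations = iter, converged = converged,
        seed = as.integer(seed), epsilon = epsilon,
        maxIter = as.integer(maxIter))
}
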