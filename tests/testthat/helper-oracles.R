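## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the adaptive-graph oracle is a generic
## constrained optimizer, the NMF oracles are literal loop evaluations, and
## the metric oracles enumerate pairs / contingency cells directly.

## Numeric minimizer of the per-spot neighbor-probability problem:
##   min sum_l d_l / (1 - E_l)  s.t.  sum_l E_l = 1 + sigma,  E_l < 1,
## solved by an augmented-Lagrangian L-BFGS-B scheme, then clipped at zero.
oracleAdaptiveProbs <- function(d, sigma) {
    k <- length(d)
    target <- 1 + sigma
    lambda <- 0
    mu <- 10
    E <- rep(target / k, k)
    fn <- function(E) {
        r <- sum(E) - target
        sum(d / (1 - E)) + lambda * r + mu / 2 * r^2
    }
    gr <- function(E) {
        r <- sum(E) - target
        d / (1 - E)^2 + lambda + mu * r
    }
    for (it in 1:60) {
        opt <- stats::optim(E, fn, gr, method = "L-BFGS-B",
                            lower = rep(-1e3, k), upper = rep(1 - 1e-9, k),
                            control = list(factr = 10, maxit = 1000))
        E <- opt$par
        r <- sum(E) - target
        if (abs(r) < 1e-11) break
        lambda <- lambda + mu * r
        mu <- mu * 2
    }
    pmax(0, E)
}

## Classical two-factor multiplicative NMF (Lee-Seung, Frobenius loss),
## written as explicit elementwise loops over small matrices.
oracleNMFStep <- function(x, w, h) {
    m <- nrow(w); f <- ncol(w); s <- ncol(h)
    wNew <- w
    for (p in seq_len(m)) for (q in seq_len(f)) {
        num <- 0; den <- 0
        for (j in seq_len(s)) {
            num <- num + x[p, j] * h[q, j]
            pred <- 0
            for (r in seq_len(f)) pred <- pred + w[p, r] * h[r, j]
            den <- den + pred * h[q, j]
        }
        wNew[p, q] <- w[p, q] * num / (den + 1e-12)
    }
    hNew <- h
    for (q in seq_len(f)) for (j in seq_len(s)) {
        num <- 0; den <- 0
        for (p in seq_len(m)) {
            num <- num + wNew[p, q] * x[p, j]
            pred <- 0
            for (r in seq_len(f)) pred <- pred + wNew[p, r] * h[r, j]
            den <- den + wNew[p, q] * pred
        }
        hNew[q, j] <- h[q, j] * num / (den + 1e-12)
    }
    list(w = wNew, h = hNew)
}

## Loop evaluation of the graph-regularized H update for one step.
oracleUpdateH <- function(x, w, h, A1, A2, D1, D2, a1, a2) {
    A1 <- as.matrix(A1); A2 <- as.matrix(A2)
    f <- nrow(h); s <- ncol(h)
    hNew <- h
    wtx <- t(w) %*% x; wtw <- t(w) %*% w
    for (q in seq_len(f)) for (j in seq_len(s)) {
        num <- wtx[q, j]
        den <- sum(wtw[q, ] * h[, j])
        for (jp in seq_len(s)) {
            num <- num + a1 * h[q, jp] * A1[jp, j] +
                a2 * h[q, jp] * A2[jp, j]
        }
        den <- den + a1 * h[q, j] * D1[j] + a2 * h[q, j] * D2[j]
        hNew[q, j] <- h[q, j] * num / (den + 1e-12)
    }
    hNew
}

## Pair-counting metrics by explicit enumeration over all spot pairs.
oraclePairMetrics <- function(pred, truth) {
    n <- length(pred)
    sameP <- outer(pred, pred, "==")
    sameT <- outer(truth, truth, "==")
    up <- upper.tri(sameP)
    a <- sum(sameP[up] & sameT[up])
    b <- sum(!sameP[up] & sameT[up])
    cc <- sum(sameP[up] & !sameT[up])
    d <- sum(!sameP[up] & !sameT[up])
    ari <- if ((a + b) * (b + d) + (a + cc) * (cc + d) == 0) 1 else
        2 * (a * d - b * cc) / ((a + b) * (b + d) + (a + cc) * (cc + d))

    ## NMI by literal double sum over contingency cells
    pu <- table(pred) / n
    pv <- table(truth) / n
    mi <- 0
    for (u in names(pu)) for (v in names(pv)) {
        puv <- sum(pred == u & truth == v) / n
        if (puv > 0) mi <- mi + puv * log(puv / (pu[[u]] * pv[[v]]))
    }
    hu <- -sum(pu * log(pu))
    hv <- -sum(pv * log(pv))
    nmi <- if (mi <= 0) 0 else 2 * mi / (hu + hv)

    pur <- 0
    for (u in unique(pred)) {
        best <- 0
        for (v in unique(truth)) {
            inter <- sum(pred == u & truth == v)
            if (inter > best) best <- inter
        }
        pur <- pur + best
    }
    list(ari = ari, nmi = as.numeric(nmi), pur = pur / n)
}

## Exact two-sample Wilcoxon rank-sum p-value by enumerating every split of
## the pooled values into the two groups (small samples, no ties assumed).
oracleWilcoxExact <- function(x, y) {
    pooled <- c(x, y)
    n <- length(pooled)
    nx <- length(x)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    splits <- utils::combn(n, nx)
    wAll <- apply(splits, 2L, function(idx) {
        sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
    })
    mu <- nx * (n - nx) / 2
    mean(abs(wAll - mu) >= abs(wObs - mu))
}
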