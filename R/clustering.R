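## Clustering of the NMF embedding into spatial domains and external
## agreement metrics (ARI / NMI / purity), plus the one-vs-rest Wilcoxon
## marker-gene screen.

#' Cluster the embedding into spatial domains
#'
#' K-means (Euclidean) on the spot columns of the embedding H, with seeded
#' multiple restarts. Labels are relabeled to first-appearance order along
#' the spot sequence so the same partition always gets the same ids.
#'
#' @param h factors x spots embedding matrix (or a [JGRNMFFit-class]).
#' @param k number of domains, `2 <= k <=` number of spots.
#' @param seed RNG seed for the restarts.
#' @param nstart number of K-means restarts (default 10).
#' @return a [DomainAssignment-class].
#' @export
clusterEmbedding <- function(h, k, seed = 1L, nstart = 10L) {
    if (is(h, "JGRNMFFit")) h <- embeddingMatrix(h)
    if (is(h, "Matrix")) h <- as.matrix(h)
    s <- ncol(h)
    stopifnot(k >= 2L, k <= s)
    pts <- t(h)
    if (nrow(unique(pts)) < k)
        stop("fewer distinct embedding columns (",
             nrow(unique(pts)), ") than requested clusters (", k, ")")
    set.seed(seed)
    km <- stats::kmeans(pts, centers = k, nstart = nstart, iter.max = 100L)
    lab <- as.integer(match(km$cluster, unique(km$cluster)))
    names(lab) <- colnames(h)
    new("DomainAssignment", labels = lab, k = as.integer(k),
        seed = as.integer(seed))
}

.checkLabelPair <- function(pred, truth) {
    if (is(pred, "DomainAssignment")) pred <- domainLabels(pred)
    if (is(truth, "DomainAssignment")) truth <- domainLabels(truth)
    if (length(pred) != length(truth))
        stop("pred and truth must have the same length")
    if (length(pred) < 2L)
        stop("at least two observations are required")
    list(pred = as.integer(factor(pred)), truth = as.integer(factor(truth)))
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement,
#' \eqn{ARI = (RI - E(RI)) / (\max(RI) - E(RI))}, computed from the
#' contingency table of the two labelings. 1 means identical partitions; 0 is
#' the expectation under random labeling.
#'
#' @param pred,truth label vectors (or [DomainAssignment-class] objects) of
#'   equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjustedRandIndex <- function(pred, truth) {
    lp <- .checkLabelPair(pred, truth)
    tab <- table(lp$pred, lp$truth)
    n <- length(lp$pred)
    sumij <- sum(choose(tab, 2))
    sumA <- sum(choose(rowSums(tab), 2))
    sumB <- sum(choose(colSums(tab), 2))
    nPairs <- choose(n, 2)
    expected <- sumA * sumB / nPairs
    maxIndex <- (sumA + sumB) / 2
    if (maxIndex == expected) return(1)  # both partitions trivial
    (sumij - expected) / (maxIndex - expected)
}

#' Normalized mutual information
#'
#' \eqn{NMI = 2 I(\hat O, O) / (H(\hat O) + H(O))} with plug-in probabilities
#' from the contingency table (0 log 0 taken as 0); returns 0 when the mutual
#' information is 0 (e.g. a constant labeling).
#'
#' @inheritParams adjustedRandIndex
#' @return scalar in \[0, 1\].
#' @export
normalizedMutualInfo <- function(pred, truth) {
    lp <- .checkLabelPair(pred, truth)
    n <- length(lp$pred)
    tab <- table(lp$pred, lp$truth) / n
    pu <- rowSums(tab)
    pv <- colSums(tab)
    nz <- tab > 0
    mi <- sum(tab[nz] * log(tab[nz] / outer(pu, pv)[nz]))
    if (mi <= 0) return(0)
    hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
    hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
    2 * mi / (hu + hv)
}

#' Cluster purity
#'
#' \eqn{PUR = (1/s) \sum_v \max_u |\hat O_v \cap O_u|}: the fraction of spots
#' belonging to the majority truth class of their predicted cluster.
#'
#' @inheritParams adjustedRandIndex
#' @return scalar in (0, 1\].
#' @export
purityScore <- function(pred, truth) {
    lp <- .checkLabelPair(pred, truth)
    tab <- table(lp$pred, lp$truth)
    sum(apply(tab, 1L, max)) / length(lp$pred)
}

#' All three agreement scores at once
#'
#' @inheritParams adjustedRandIndex
#' @return named list with `ari`, `nmi` and `pur`.
#' @export
clusteringScores <- function(pred, truth) {
    list(ari = adjustedRandIndex(pred, truth),
         nmi = normalizedMutualInfo(pred, truth),
         pur = purityScore(pred, truth))
}

#' Rank marker genes per domain
#'
#' One-vs-rest Wilcoxon rank-sum screen on the spot-normalized expression
#' matrix. For each domain, genes expressed (count > 0) in at least
#' `minFrac` of the domain's spots and with
#' \eqn{|log2((mean_{in}+c)/(mean_{out}+c))| \ge} `minAbsLfc`
#' (pseudocount c = 1e-9) are kept and ranked by absolute log2 fold change;
#' the top `topN` per domain are returned with raw two-sided p-values.
#' Domains with fewer than 3 spots are skipped with a warning.
#'
#' @param x genes x spots expression matrix (spot-normalized).
#' @param labels per-spot domain labels (vector or
#'   [DomainAssignment-class]).
#' @param minFrac minimum in-domain expression fraction (default 0.25).
#' @param minAbsLfc minimum absolute log2 fold change (default 0.25).
#' @param topN markers reported per domain (default 20).
#' @return data.frame with columns `domain`, `gene`, `log2fc`, `pvalue`,
#'   `rank`.
#' @export
rankMarkerGenes <- function(x, labels, minFrac = 0.25, minAbsLfc = 0.25,
                            topN = 20L) {
    stopifnot(minFrac >= 0, minFrac <= 1)
    if (is(labels, "DomainAssignment")) labels <- domainLabels(labels)
    if (is(x, "Matrix")) x <- as.matrix(x)
    if (length(labels) != ncol(x))
        stop("labels length must equal the number of spots")
    doms <- sort(unique(labels))
    if (length(doms) < 2L) stop("at least 2 domains are required")
    genes <- rownames(x)
    if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(x)))
    pseudo <- 1e-9
    out <- list()
    for (d in doms) {
        inD <- labels == d
        if (sum(inD) < 3L) {
            warning("domain ", d, " has fewer than 3 spots; skipped")
            next
        }
        xin <- x[, inD, drop = FALSE]
        xout <- x[, !inD, drop = FALSE]
        frac <- rowMeans(xin > 0)
        lfc <- log2((rowMeans(xin) + pseudo) / (rowMeans(xout) + pseudo))
        keep <- which(frac >= minFrac & abs(lfc) >= minAbsLfc)
        if (length(keep) == 0L) next
        keep <- keep[order(-abs(lfc[keep]), keep)][seq_len(min(topN,
                                                               length(keep)))]
        pv <- vapply(keep, function(g) {
            ## ties are expected in sparse counts; the normal approximation
            ## with tie correction is used automatically in that case
            suppressWarnings(stats::wilcox.test(xin[g, ], xout[g, ])$p.value)
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
            domain = d, gene = genes[keep], log2fc = lfc[keep], pvalue = pv,
            rank = seq_along(keep), row.names = NULL)
    }
    if (length(out) == 0L)
        return(data.frame(domain = integer(0), gene = character(0),
                          log2fc = numeric(0), pvalue = numeric(0),
                          rank = integer(0)))
    do.call(rbind, out)
}
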