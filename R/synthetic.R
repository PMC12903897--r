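## Synthetic spatial-transcriptomics generator: a spot lattice partitioned
## into K domains, domain-specific marker programs, Poisson or negative
## binomial count noise, and independent dropout. Produces a
## SingleCellExperiment so the whole pipeline is testable without downloads.

#' Generate a spot layout with domain labels
#'
#' Places spots on an integer `rows` x `cols` grid and partitions them into
#' `k` domains: `"stripes"` cuts the grid into k vertical bands of
#' near-equal width, `"blocks"` into k rectangular tiles, and `"voronoi"`
#' labels each spot by its nearest of k seeded centers (ties toward the
#' smaller center index).
#'
#' @param rows,cols grid dimensions; `rows * cols >= k`.
#' @param k number of domains, at least 2.
#' @param layout `"stripes"`, `"blocks"` or `"voronoi"`.
#' @param seed RNG seed (used by the voronoi layout).
#' @return list with `coords` (2 x spots matrix, rows `array_row`,
#'   `array_col`), `truth` (a [DomainAssignment-class]) and `spotIds`.
#' @export
generateLayout <- function(rows, cols, k,
                           layout = c("stripes", "blocks", "voronoi"),
                           seed = 1L) {
    layout <- match.arg(layout)
    s <- rows * cols
    if (k < 2L || k > s) stop("require 2 <= k <= rows * cols")
    spotRow <- rep(seq_len(rows), times = cols)
    spotCol <- rep(seq_len(cols), each = rows)
    spotIds <- sprintf("spot_%04d", seq_len(s))
    lab <- switch(layout,
        stripes = {
            as.integer(cut(spotCol, breaks = k, labels = FALSE))
        },
        blocks = {
            kr <- floor(sqrt(k))
            while (k %% kr != 0L) kr <- kr - 1L
            kc <- k %/% kr
            rb <- as.integer(cut(spotRow, breaks = kr, labels = FALSE))
            cb <- as.integer(cut(spotCol, breaks = kc, labels = FALSE))
            (rb - 1L) * kc + cb
        },
        voronoi = {
            set.seed(seed)
            centers <- sample.int(s, k)
            d2 <- outer(spotRow, spotRow[centers], "-")^2 +
                  outer(spotCol, spotCol[centers], "-")^2
            max.col(-d2, ties.method = "first")
        })
    if (length(unique(lab)) < k)
        stop("layout produced fewer than k distinct domains")
    coords <- rbind(array_row = spotRow, array_col = spotCol)
    colnames(coords) <- spotIds
    truth <- new("DomainAssignment", labels = stats::setNames(
        as.integer(lab), spotIds), k = as.integer(k), seed = as.integer(seed))
    list(coords = coords, truth = truth, spotIds = spotIds)
}

#' Generate counts with domain-specific expression programs
#'
#' Each domain receives `nMarkersPerDomain` marker genes whose mean is
#' `baselineMean * effectSize` inside the domain and `baselineMean` outside;
#' all remaining genes are flat at `baselineMean`. Counts are drawn from the
#' chosen noise model and independently zeroed with probability
#' `dropoutRate` (zero inflation). Marker genes occupy the first
#' `k * nMarkersPerDomain` rows, in domain order.
#'
#' @param truth a [DomainAssignment-class] with per-spot domain labels.
#' @param nGenes total genes; at least `k * nMarkersPerDomain`.
#' @param nMarkersPerDomain marker genes per domain (default 10).
#' @param baselineMean background mean count (default 1).
#' @param effectSize fold elevation of markers inside their domain
#'   (default 5).
#' @param dropoutRate independent zeroing probability (default 0.3).
#' @param noise `"poisson"` or `"nb"` (negative binomial with size
#'   `nbDispersion`).
#' @param nbDispersion NB size parameter theta (variance
#'   \eqn{\mu + \mu^2/\theta}); default 10.
#' @param seed RNG seed.
#' @return sparse genes x spots count matrix with gene/spot dimnames.
#' @export
generateCounts <- function(truth, nGenes = 300L, nMarkersPerDomain = 10L,
                           baselineMean = 1, effectSize = 5,
                           dropoutRate = 0.3,
                           noise = c("poisson", "nb"), nbDispersion = 10,
                           seed = 1L) {
    noise <- match.arg(noise)
    labels <- domainLabels(truth)
    k <- nDomains(truth)
    s <- length(labels)
    if (nGenes < k * nMarkersPerDomain)
        stop("nGenes must be at least k * nMarkersPerDomain")
    stopifnot(dropoutRate >= 0, dropoutRate <= 1, baselineMean > 0,
              effectSize > 0)
    set.seed(seed)
    mu <- matrix(baselineMean, nGenes, s)
    for (d in seq_len(k)) {
        gidx <- (d - 1L) * nMarkersPerDomain + seq_len(nMarkersPerDomain)
        mu[gidx, labels == d] <- baselineMean * effectSize
    }
    counts <- switch(noise,
        poisson = matrix(stats::rpois(nGenes * s, mu), nGenes, s),
        nb = matrix(stats::rnbinom(nGenes * s, mu = mu, size = nbDispersion),
                    nGenes, s))
    if (dropoutRate > 0) {
        keepMask <- matrix(stats::rbinom(nGenes * s, 1L, 1 - dropoutRate),
                           nGenes, s)
        counts <- counts * keepMask
    }
    dimnames(counts) <- list(sprintf("gene_%04d", seq_len(nGenes)),
                             names(labels))
    Matrix::Matrix(counts, sparse = TRUE)
}

#' Simulate a complete spatial dataset
#'
#' Combines [generateLayout()] and [generateCounts()] into a
#' [SingleCellExperiment::SingleCellExperiment] with a `"counts"` assay and
#' colData columns `array_row`, `array_col` and `domain` (the ground truth).
#' Generator settings are stored in `metadata(sce)$params`.
#'
#' @inheritParams generateLayout
#' @inheritParams generateCounts
#' @return a `SingleCellExperiment`.
#' @export
simulateSpatialDataset <- function(rows = 20L, cols = 20L, k = 4L,
                                   layout = "stripes", nGenes = 300L,
                                   nMarkersPerDomain = 10L, baselineMean = 1,
                                   effectSize = 5, dropoutRate = 0.3,
                                   noise = "poisson", nbDispersion = 10,
                                   seed = 1L) {
    lay <- generateLayout(rows, cols, k, layout, seed)
    counts <- generateCounts(lay$truth, nGenes, nMarkersPerDomain,
                             baselineMean, effectSize, dropoutRate, noise,
                             nbDispersion, seed)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            array_row = lay$coords["array_row", ],
            array_col = lay$coords["array_col", ],
            domain = as.integer(domainLabels(lay$truth)),
            row.names = lay$spotIds))
    S4Vectors::metadata(sce)$params <- list(
        rows = rows, cols = cols, k = k, layout = layout, nGenes = nGenes,
        nMarkersPerDomain = nMarkersPerDomain, baselineMean = baselineMean,
        effectSize = effectSize, dropoutRate = dropoutRate, noise = noise,
        nbDispersion = nbDispersion, seed = seed)
    sce
}
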