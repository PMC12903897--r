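## End-to-end orchestration: read -> preprocess -> expression graph (with
## optional sigma grid search) -> spatial graph -> JGR-NMF -> K-means ->
## scores -> results on disk.

#' Run the full spatial-domain identification pipeline
#'
#' Executes preprocessing, graph construction, joint graph-regularized NMF
#' and K-means clustering on a dataset, optionally scoring against ground
#' truth and writing all artifacts to disk.
#'
#' @param input a `SingleCellExperiment` (e.g. from [readVisium()],
#'   [readCsvMatrix()] or [simulateSpatialDataset()]) with a `"counts"`
#'   assay and colData `array_row`, `array_col`; alternatively a list with
#'   `counts` (genes x spots) and `coords` (2 x spots).
#' @param nDomains number of spatial domains K (and default factor count).
#' @param tau gene-filter zero-fraction threshold (default 0.8).
#' @param mHvg number of highly variable genes (default 2000).
#' @param k1Max maximum neighbors of the adaptive expression graph
#'   (default 30).
#' @param sigma residual parameter of the adaptive graph (default 0.3);
#'   ignored when `sigmaGrid` is given.
#' @param sigmaGrid optional grid of sigma values; when supplied, sigma is
#'   chosen by the Louvain community elbow ([selectSigma()]).
#' @param k2 spatial mutual-kNN neighbor count (default 6).
#' @param alpha1,alpha2 regularization weights (defaults 0.8 and 0.1).
#' @param factors number of NMF factors; defaults to `nDomains`.
#' @param epsilon,maxIter convergence threshold and iteration cap of the
#'   factorization.
#' @param seed RNG seed used for initialization, sigma selection and
#'   clustering.
#' @param truth optional per-spot ground-truth labels (vector aligned with
#'   the spots, or `TRUE` to use a `domain` colData column).
#' @param outDir optional output directory for [writeResults()].
#' @param graphDistanceSource matrix feeding the expression distances:
#'   `"x_filtered"` (spot-normalized, all kept genes; default) or `"x_hvg"`.
#' @param dropEmptySpots drop spots with zero totals after gene filtering
#'   instead of raising an error.
#' @param verbose log per-stage progress to stderr.
#' @return list with `assignment` ([DomainAssignment-class]), `fit`
#'   ([JGRNMFFit-class]), `scores` (or `NULL`), `sigma` (the value used),
#'   `graphs` (list of the two [SpotGraph-class] objects), `preprocessed`
#'   (the [preprocessCounts()] output) and `metadata`.
#' @export
runPipeline <- function(input, nDomains, tau = 0.8, mHvg = 2000L,
                        k1Max = 30L, sigma = 0.3, sigmaGrid = NULL,
                        k2 = 6L, alpha1 = 0.8, alpha2 = 0.1,
                        factors = NULL, epsilon = 1e-4, maxIter = 500L,
                        seed = 1L,
                        truth = NULL, outDir = NULL,
                        graphDistanceSource = c("x_filtered", "x_hvg"),
                        dropEmptySpots = FALSE, verbose = FALSE) {
    graphDistanceSource <- match.arg(graphDistanceSource)
    stopifnot(nDomains >= 2L)
    say <- function(...) if (verbose) message(sprintf(...))
    t0 <- proc.time()[["elapsed"]]
    stage <- function(lab) {
        say("[%s] %.1fs", lab, proc.time()[["elapsed"]] - t0)
    }

    if (is(input, "SummarizedExperiment")) {
        counts <- SummarizedExperiment::assay(input, "counts")
        cd <- SummarizedExperiment::colData(input)
        coords <- rbind(array_row = cd$array_row, array_col = cd$array_col)
        colnames(coords) <- colnames(counts)
        if (isTRUE(truth)) truth <- cd$domain
    } else {
        counts <- input$counts
        coords <- input$coords
    }
    if (is.null(counts) || is.null(coords))
        stop("input must provide counts and coordinates")

    pp <- preprocessCounts(counts, tau = tau, mHvg = mHvg,
                           dropEmptySpots = dropEmptySpots)
    coords <- coords[, pp$keptSpots, drop = FALSE]
    if (!is.null(truth) && !isFALSE(truth))
        truth <- truth[pp$keptSpots]
    stage("preprocess")

    xGraph <- switch(graphDistanceSource, x_filtered = pp$xFiltered,
                     x_hvg = pp$xHvg)
    sigmaUsed <- sigma
    if (!is.null(sigmaGrid)) {
        sel <- selectSigma(xGraph, k1Max = k1Max, grid = sigmaGrid,
                           seed = seed)
        sigmaUsed <- sel$sigma
        say("selected sigma = %g", sigmaUsed)
    }
    g1 <- buildExpressionGraph(xGraph, k1Max = k1Max, sigma = sigmaUsed)
    stage("expression graph")
    g2 <- buildSpatialGraph(coords, k2 = k2)
    stage("spatial graph")

    f <- if (is.null(factors)) as.integer(nDomains) else as.integer(factors)
    fit <- jgrnmf(pp$xHvg, g1, g2, alpha1 = alpha1, alpha2 = alpha2, f = f,
                  epsilon = epsilon, maxIter = maxIter, seed = seed)
    stage("factorization")

    assignment <- clusterEmbedding(embeddingMatrix(fit), k = nDomains,
                                   seed = seed)
    stage("clustering")

    scores <- NULL
    if (!is.null(truth) && !isFALSE(truth))
        scores <- clusteringScores(domainLabels(assignment), truth)

    metadata <- list(
        tau = tau, m_hvg = mHvg, k1_max = k1Max, sigma = sigmaUsed,
        sigma_grid = sigmaGrid, k2 = k2, alpha1 = alpha1, alpha2 = alpha2,
        factors = f, n_domains = nDomains, epsilon = epsilon,
        max_iter = maxIter, seed = seed,
        graph_distance_source = graphDistanceSource,
        n_genes_kept = length(pp$keptGenes), n_hvg = length(pp$hvgGenes),
        n_spots = ncol(pp$xFiltered))

    if (!is.null(outDir))
        writeResults(outDir, assignment, fit, scores, metadata = metadata)

    list(assignment = assignment, fit = fit, scores = scores,
         sigma = sigmaUsed, graphs = list(expression = g1, spatial = g2),
         preprocessed = pp, metadata = metadata)
}
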