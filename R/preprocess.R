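## Preprocessing: raw counts -> filtered/normalized X' -> HVG-selected,
## max-scaled X~ in [0,1]. All functions take genes x spots matrices (dense or
## Matrix sparse) and preserve dimnames.

.asMat <- function(x) {
    if (is(x, "Matrix")) x else Matrix::Matrix(x, sparse = TRUE)
}

#' Filter genes by zero-expression fraction
#'
#' Removes gene j when its zero-expression ratio
#' \eqn{zex_j = \#\{spots: X_{ij} = 0\}/s} is at least `tau` (boundary
#' included). The surviving gene order is preserved.
#'
#' @param counts genes x spots matrix of non-negative counts.
#' @param tau zero-fraction threshold in (0, 1]; default 0.8, i.e. genes not
#'   expressed in more than 80% of spots are dropped.
#' @return list with `x` (filtered matrix) and `kept` (integer indices into
#'   the original gene order).
#' @export
filterGenes <- function(counts, tau = 0.8) {
    stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau <= 1)
    counts <- .asMat(counts)
    s <- ncol(counts)
    cs <- as(Matrix::drop0(counts), "CsparseMatrix")
    zex <- 1 - tabulate(cs@i + 1L, nrow(cs)) / s
    kept <- which(zex < tau)
    if (length(kept) == 0L)
        stop("all genes removed at tau = ", tau,
             "; increase tau or check the input counts")
    list(x = counts[kept, , drop = FALSE], kept = kept)
}

#' Normalize each spot to unit total
#'
#' Divides every column (spot) by its total so gene expression values in each
#' spot sum to one.
#'
#' @param x genes x spots matrix with strictly positive column totals.
#' @return matrix with unit column sums.
#' @export
normalizeSpots <- function(x) {
    x <- .asMat(x)
    tot <- Matrix::colSums(x)
    if (any(tot <= 0)) {
        bad <- which(tot <= 0)
        stop("spot(s) with zero total counts after gene filtering: ",
             paste(utils::head(colnames(x)[bad], 5L), collapse = ", "),
             " (n = ", length(bad), "); per-spot normalization is undefined. ",
             "Use dropEmptySpots = TRUE upstream to discard them.")
    }
    x %*% Matrix::Diagonal(x = 1 / tot)
}

#' Select highly variable genes
#'
#' Ranks genes by population variance across spots,
#' \eqn{\sigma_j^2 = (1/s)\sum_i (x_{ij} - \mu_j)^2} (divisor s, not s - 1),
#' computed on the spot-normalized matrix, and keeps the top `mHvg` rows in
#' their original order. Ties are broken toward the smaller gene index.
#'
#' @param x genes x spots spot-normalized matrix.
#' @param mHvg number of genes to retain (default 2000).
#' @return list with `x` (HVG matrix) and `kept` (row indices into `x`).
#' @export
selectHvg <- function(x, mHvg = 2000L) {
    stopifnot(mHvg >= 1L)
    x <- .asMat(x)
    m <- nrow(x)
    if (m <= mHvg) {
        if (m < mHvg)
            warning("only ", m, " genes available; keeping all (mHvg = ",
                    mHvg, ")")
        return(list(x = x, kept = seq_len(m)))
    }
    s <- ncol(x)
    mu <- Matrix::rowSums(x) / s
    v <- Matrix::rowSums(x^2) / s - mu^2
    ## stable sort: equal variances resolved toward the smaller gene index
    ord <- order(-v, seq_len(m))
    kept <- sort(ord[seq_len(mHvg)])
    list(x = x[kept, , drop = FALSE], kept = kept)
}

#' Scale each gene to the unit interval
#'
#' Divides every gene row by its maximum across spots so entries lie in
#' \[0, 1\]; all-zero rows are left untouched.
#'
#' @param x genes x spots non-negative matrix.
#' @return matrix with per-row maxima equal to 1 (all-zero rows excepted).
#' @export
scaleGenes <- function(x) {
    x <- .asMat(x)
    mx <- apply(x, 1L, max)
    mx[mx == 0] <- 1
    Matrix::Diagonal(x = 1 / mx) %*% x
}

#' Full preprocessing pipeline
#'
#' Runs gene filtering, per-spot sum-to-one normalization, highly variable
#' gene selection and per-gene max scaling, producing the filtered normalized
#' matrix X' (all surviving genes) and the HVG-standardized matrix X~ that
#' the factorization consumes.
#'
#' @param counts genes x spots count matrix, or a
#'   [SingleCellExperiment::SingleCellExperiment] carrying a `"counts"` assay.
#' @param tau zero-fraction gene filter threshold (default 0.8).
#' @param mHvg number of highly variable genes (default 2000).
#' @param dropEmptySpots if `TRUE`, spots whose totals are zero after gene
#'   filtering are dropped instead of raising an error.
#' @return list with `xFiltered` (spot-normalized, all kept genes), `xHvg`
#'   (HVG rows, max-scaled to \[0, 1\]), `keptGenes` (filter survivors, indices
#'   into the input), `hvgGenes` (HVG subset, indices into the input), and
#'   `keptSpots` (indices into the input spots).
#' @export
preprocessCounts <- function(counts, tau = 0.8, mHvg = 2000L,
                             dropEmptySpots = FALSE) {
    if (is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- .asMat(counts)
    fl <- filterGenes(counts, tau)
    keptSpots <- seq_len(ncol(fl$x))
    if (dropEmptySpots) {
        tot <- Matrix::colSums(fl$x)
        if (any(tot == 0)) {
            keptSpots <- unname(which(tot > 0))
            fl$x <- fl$x[, keptSpots, drop = FALSE]
        }
    }
    xf <- normalizeSpots(fl$x)
    hv <- selectHvg(xf, mHvg)
    xh <- scaleGenes(hv$x)
    list(
        xFiltered = xf,
        xHvg = xh,
        keptGenes = fl$kept,
        hvgGenes = fl$kept[hv$kept],
        keptSpots = keptSpots
    )
}
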