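## Readers for 10x Visium bundles and generic CSV/TSV matrices, the results
## writer, and a Visium-style bundle writer for synthetic datasets. Counts
## are kept sparse throughout.

.findFile <- function(dir, candidates) {
    for (f in candidates) {
        p <- file.path(dir, f)
        if (file.exists(p)) return(p)
    }
    NULL
}

.readTsvCol <- function(path, col = 1L) {
    read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[col]]
}

.readMtx <- function(path) {
    if (grepl("\\.gz$", path)) {
        con <- gzfile(path)
        on.exit(close(con))
        Matrix::readMM(con)
    } else {
        Matrix::readMM(path)
    }
}

#' Read a 10x Visium bundle
#'
#' Reads Matrix-Market counts with their feature and barcode annotations and
#' the tissue-positions table (both the headerless `tissue_positions_list.csv`
#' and the headered `tissue_positions.csv` dialects). Only in-tissue spots
#' (tissue flag 1) are retained, and counts and coordinates are aligned by
#' barcode to the counts order.
#'
#' @param bundlePath directory containing `matrix.mtx[.gz]`,
#'   `features.tsv[.gz]`, `barcodes.tsv[.gz]` and
#'   `spatial/tissue_positions[_list].csv` (the positions file may also sit
#'   in the bundle root).
#' @param useArrayCoords if `TRUE` (default) coordinates are
#'   (`array_row`, `array_col`) grid units; otherwise pixel coordinates.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `"counts"`
#'   assay (genes x spots, sparse) and colData `array_row`, `array_col` (or
#'   pixel coordinates).
#' @export
readVisium <- function(bundlePath, useArrayCoords = TRUE) {
    if (!dir.exists(bundlePath))
        stop("bundle directory not found: ", bundlePath)
    mtx <- .findFile(bundlePath, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stop("missing counts file matrix.mtx[.gz] in ",
                           bundlePath)
    feat <- .findFile(bundlePath, c("features.tsv", "features.tsv.gz",
                                    "genes.tsv", "genes.tsv.gz"))
    if (is.null(feat)) stop("missing features.tsv[.gz] in ", bundlePath)
    bc <- .findFile(bundlePath, c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.null(bc)) stop("missing barcodes.tsv[.gz] in ", bundlePath)
    pos <- .findFile(bundlePath, c(
        file.path("spatial", "tissue_positions.csv"),
        file.path("spatial", "tissue_positions_list.csv"),
        "tissue_positions.csv", "tissue_positions_list.csv"))
    if (is.null(pos)) stop("missing spatial/tissue_positions[_list].csv in ",
                           bundlePath)

    counts <- as(.readMtx(mtx), "CsparseMatrix")
    geneIds <- .readTsvCol(feat)
    barcodes <- .readTsvCol(bc)
    if (nrow(counts) != length(geneIds))
        stop("features.tsv has ", length(geneIds), " genes but the matrix ",
             "has ", nrow(counts), " rows")
    if (ncol(counts) != length(barcodes))
        stop("barcodes.tsv has ", length(barcodes), " barcodes but the ",
             "matrix has ", ncol(counts), " columns")
    if (anyDuplicated(geneIds) || anyDuplicated(barcodes))
        stop("duplicate gene ids or barcodes in the bundle")
    dimnames(counts) <- list(geneIds, barcodes)

    firstLine <- readLines(pos, n = 1L)
    hasHeader <- grepl("barcode", firstLine, ignore.case = TRUE)
    posTab <- read.csv(pos, header = hasHeader, stringsAsFactors = FALSE)
    if (ncol(posTab) < 6L)
        stop("tissue positions file must have 6 columns (barcode, ",
             "in_tissue, array_row, array_col, pixel_row, pixel_col)")
    colnames(posTab) <- c("barcode", "in_tissue", "array_row", "array_col",
                          "pxl_row", "pxl_col")
    unmatched <- sum(!barcodes %in% posTab$barcode)
    if (unmatched > 0L)
        stop("barcode alignment failed: ", unmatched, " of ",
             length(barcodes), " count barcodes are absent from the ",
             "positions file")
    posTab <- posTab[posTab$in_tissue == 1, , drop = FALSE]
    keep <- barcodes[barcodes %in% posTab$barcode]
    if (length(keep) == 0L)
        stop("no in-tissue spots remain after filtering")
    counts <- counts[, keep, drop = FALSE]
    posTab <- posTab[match(keep, posTab$barcode), , drop = FALSE]
    if (useArrayCoords) {
        cd <- S4Vectors::DataFrame(array_row = posTab$array_row,
                                   array_col = posTab$array_col,
                                   row.names = keep)
    } else {
        cd <- S4Vectors::DataFrame(array_row = posTab$pxl_row,
                                   array_col = posTab$pxl_col,
                                   row.names = keep)
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    S4Vectors::metadata(sce)$n_out_of_tissue <-
        length(barcodes) - length(keep)
    sce
}

#' Read a dense CSV/TSV expression matrix with coordinates
#'
#' Counts: gene rows and spot columns, header row of spot ids, first column
#' gene ids. Coordinates: three columns (spot id, x, y). Delimiters are
#' auto-detected from the file extensions (`.tsv`/`.txt`: tab; otherwise
#' comma).
#'
#' @param countsPath path to the counts table.
#' @param coordsPath path to the coordinates table.
#' @return a [SingleCellExperiment::SingleCellExperiment] as in
#'   [readVisium()].
#' @export
readCsvMatrix <- function(countsPath, coordsPath) {
    for (p in c(countsPath, coordsPath))
        if (!file.exists(p)) stop("missing file: ", p)
    delim <- function(p) if (grepl("\\.(tsv|txt)(\\.gz)?$", p)) "\t" else ","
    ## read.table uniquifies duplicate header names, so check the raw header
    hdr <- strsplit(readLines(countsPath, n = 1L), delim(countsPath),
                    fixed = TRUE)[[1L]][-1L]
    if (anyDuplicated(hdr)) stop("duplicate spot ids in counts")
    tab <- read.delim(countsPath, sep = delim(countsPath), header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    geneIds <- as.character(tab[[1L]])
    vals <- tab[, -1L, drop = FALSE]
    nonNum <- !vapply(vals, is.numeric, logical(1))
    if (any(nonNum)) {
        j <- which(nonNum)[1L]
        bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
        stop("non-numeric value in counts at row ", bad, ", column ",
             colnames(vals)[j])
    }
    spotIds <- colnames(vals)
    if (anyDuplicated(geneIds)) stop("duplicate gene ids in counts")
    if (anyDuplicated(spotIds)) stop("duplicate spot ids in counts")
    counts <- Matrix::Matrix(as.matrix(vals), sparse = TRUE)
    dimnames(counts) <- list(geneIds, spotIds)

    co <- read.delim(coordsPath, sep = delim(coordsPath), header = TRUE,
                     stringsAsFactors = FALSE)
    if (ncol(co) < 3L) stop("coords file must have columns: spot id, x, y")
    if (anyDuplicated(co[[1L]])) stop("duplicate spot ids in coords")
    missing <- setdiff(spotIds, as.character(co[[1L]]))
    if (length(missing) > 0L)
        stop("coords file is missing ", length(missing), " spot(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    co <- co[match(spotIds, as.character(co[[1L]])), , drop = FALSE]
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(array_row = as.numeric(co[[2L]]),
                                       array_col = as.numeric(co[[3L]]),
                                       row.names = spotIds))
}

#' Write pipeline results
#'
#' Emits `labels.csv` (spot_id, domain), `embedding.csv` (factors x spots,
#' spot columns), `objective_trace.csv`, `run_metadata.json` (hyperparameters,
#' seed, iteration count, convergence flag) and, when scores are supplied,
#' `metrics.json` with keys `ari`, `nmi`, `pur`.
#'
#' @param outDir output directory (created if needed).
#' @param assignment a [DomainAssignment-class].
#' @param fit a [JGRNMFFit-class].
#' @param scores optional list with `ari`, `nmi`, `pur`
#'   (see [clusteringScores()]).
#' @param metadata optional named list merged into the run metadata.
#' @return invisibly, the vector of files written.
#' @export
writeResults <- function(outDir, assignment, fit, scores = NULL,
                         metadata = list()) {
    if (!dir.exists(outDir)) {
        ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!ok || !dir.exists(outDir))
            stop("cannot create output directory: ", outDir)
    }
    labels <- domainLabels(assignment)
    spotIds <- names(labels)
    if (is.null(spotIds)) spotIds <- paste0("spot_", seq_along(labels))
    files <- character(0)

    p <- file.path(outDir, "labels.csv")
    write.csv(data.frame(spot_id = spotIds, domain = as.integer(labels)),
              p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)

    h <- embeddingMatrix(fit)
    colnames(h) <- spotIds
    rownames(h) <- paste0("factor_", seq_len(nrow(h)))
    p <- file.path(outDir, "embedding.csv")
    write.csv(as.data.frame(as.matrix(h)), p, row.names = TRUE, quote = FALSE)
    files <- c(files, p)

    p <- file.path(outDir, "objective_trace.csv")
    write.csv(data.frame(iteration = seq_along(objectiveTrace(fit)),
                         objective = objectiveTrace(fit),
                         err_h = errTrace(fit)),
              p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)

    meta <- c(list(
        alpha1 = fit@alpha1, alpha2 = fit@alpha2,
        factors = ncol(basisMatrix(fit)), epsilon = fit@epsilon,
        max_iter = fit@maxIter, seed = fit@seed,
        iterations = fit@iterations, converged = fit@converged,
        n_domains = nDomains(assignment),
        clustering_seed = assignment@seed), metadata)
    p <- file.path(outDir, "run_metadata.json")
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, p)

    if (!is.null(scores)) {
        p <- file.path(outDir, "metrics.json")
        jsonlite::write_json(scores[c("ari", "nmi", "pur")], p,
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        files <- c(files, p)
    }
    invisible(files)
}

#' Write a Visium-style bundle from a dataset
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and
#' `spatial/tissue_positions.csv` so that [readVisium()] round-trips the
#' dataset. Intended for synthetic fixtures.
#'
#' @param sce a `SingleCellExperiment` with a `"counts"` assay and colData
#'   `array_row`, `array_col`.
#' @param dir target directory (created if needed).
#' @param inTissue integer vector of tissue flags (default all 1).
#' @return invisibly, `dir`.
#' @export
writeVisiumBundle <- function(sce, dir, inTissue = NULL) {
    dir.create(file.path(dir, "spatial"), recursive = TRUE,
               showWarnings = FALSE)
    counts <- SummarizedExperiment::assay(sce, "counts")
    Matrix::writeMM(as(as(counts, "dMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    cd <- SummarizedExperiment::colData(sce)
    if (is.null(inTissue)) inTissue <- rep(1L, ncol(counts))
    pos <- data.frame(
        barcode = colnames(counts), in_tissue = as.integer(inTissue),
        array_row = cd$array_row, array_col = cd$array_col,
        pxl_row_in_fullres = cd$array_row * 100L,
        pxl_col_in_fullres = cd$array_col * 100L)
    write.csv(pos, file.path(dir, "spatial", "tissue_positions.csv"),
              row.names = FALSE, quote = FALSE)
    invisible(dir)
}
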