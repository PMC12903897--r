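## Small fixture builders shared across tests.

randomCounts <- function(m = 30, s = 20, seed = 1, lambda = 2) {
    set.seed(seed)
    matrix(rpois(m * s, lambda), m, s,
           dimnames = list(sprintf("g%03d", seq_len(m)),
                           sprintf("s%03d", seq_len(s))))
}

## Random mutual-kNN spatial graph on random coordinates.
randomSpatialGraph <- function(s = 40, k2 = 4, seed = 1) {
    set.seed(seed)
    coords <- rbind(runif(s) * 10, runif(s) * 10)
    colnames(coords) <- sprintf("s%03d", seq_len(s))
    buildSpatialGraph(coords, k2 = k2)
}

randomExpressionGraph <- function(s = 40, m = 20, k1Max = 8, sigma = 0.3,
                                  seed = 1) {
    set.seed(seed)
    x <- matrix(runif(m * s), m, s)
    buildExpressionGraph(x, k1Max = k1Max, sigma = sigma)
}

## A tiny SCE bundle on disk for the Visium reader tests.
writeTinyBundle <- function(dir, permutePositions = FALSE,
                            outOfTissue = integer(0),
                            dropFromPositions = integer(0)) {
    counts <- Matrix::Matrix(matrix(c(0, 1, 2,
                                      3, 4, 5,
                                      6, 0, 8,
                                      9, 10, 0), nrow = 3, ncol = 4,
                                    dimnames = list(
                                        c("gA", "gB", "gC"),
                                        c("bc1", "bc2", "bc3", "bc4"))),
                             sparse = TRUE)
    dir.create(file.path(dir, "spatial"), recursive = TRUE,
               showWarnings = FALSE)
    Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    flags <- rep(1L, 4)
    flags[outOfTissue] <- 0L
    pos <- data.frame(barcode = colnames(counts), in_tissue = flags,
                      array_row = c(1L, 1L, 2L, 2L),
                      array_col = c(1L, 2L, 1L, 2L),
                      pxl_row_in_fullres = c(100L, 100L, 200L, 200L),
                      pxl_col_in_fullres = c(100L, 200L, 100L, 200L))
    if (length(dropFromPositions))
        pos <- pos[-dropFromPositions, , drop = FALSE]
    if (permutePositions) pos <- pos[c(3, 1, 4, 2), , drop = FALSE]
    write.csv(pos, file.path(dir, "spatial", "tissue_positions.csv"),
              row.names = FALSE, quote = FALSE)
    counts
}
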