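#' @importFrom methods new validObject is as setClass setGeneric setMethod
#'   setValidity show slot
#' @importFrom Matrix Matrix sparseMatrix Diagonal rowSums colSums t drop0
#' @importFrom stats dist kmeans median runif rpois rnbinom rbinom var
#'   wilcox.test
#' @importFrom utils read.delim write.csv read.csv
NULL

#' SpotGraph: a spot-spot affinity graph with degree and Laplacian matrices
#'
#' Holds a symmetric non-negative spot adjacency matrix together with its
#' degree diagonal and unnormalized graph Laplacian \eqn{L = D - A}. Two kinds
#' are used in the model: the adaptive expression-neighbor graph (continuous
#' weights in \[0, 1\]) and the spatial mutual k-nearest-neighbor graph
#' (binary weights).
#'
#' @slot adjacency symmetric, non-negative, zero-diagonal sparse matrix.
#' @slot degrees numeric vector of row sums of the adjacency.
#' @slot laplacian sparse matrix \eqn{D - A}; rows sum to zero.
#' @slot kind `"expression"` or `"spatial"`.
#'
#' @seealso [spotGraph()], [buildExpressionGraph()], [buildSpatialGraph()]
#' @export
setClass("SpotGraph",
    representation(
        adjacency = "Matrix",
        degrees = "numeric",
        laplacian = "Matrix",
        kind = "character"
    )
)

setValidity("SpotGraph", function(object) {
    A <- object@adjacency
    msg <- character()
    if (nrow(A) != ncol(A))
        msg <- c(msg, "adjacency must be square")
    if (length(object@degrees) != nrow(A))
        msg <- c(msg, "degrees length must equal adjacency dimension")
    if (Matrix::nnzero(A) > 0 && min(A) < 0)
        msg <- c(msg, "adjacency entries must be non-negative")
    if (max(abs(Matrix::diag(A))) > 0)
        msg <- c(msg, "adjacency diagonal must be zero")
    if (!Matrix::isSymmetric(A, tol = 0))
        msg <- c(msg, "adjacency must be exactly symmetric")
    if (!object@kind %in% c("expression", "spatial"))
        msg <- c(msg, "kind must be 'expression' or 'spatial'")
    if (length(msg)) msg else TRUE
})

#' JGRNMFFit: result of the joint graph-regularized NMF optimization
#'
#' Stores the non-negative basis matrix W (genes x factors), the spot
#' embedding H (factors x spots), the regularization weights, and per-iteration
#' diagnostics of the multiplicative-update optimization.
#'
#' @slot W non-negative basis matrix, genes x factors.
#' @slot H non-negative coefficient (embedding) matrix, factors x spots.
#' @slot alpha1,alpha2 regularization weights of the expression and spatial
#'   graph penalties.
#' @slot objectiveTrace objective value after each iteration.
#' @slot errTrace per-iteration max-norm change of H.
#' @slot iterations number of iterations performed.
#' @slot converged `TRUE` iff the H-change dropped below `epsilon` before the
#'   iteration cap.
#' @slot seed RNG seed used for initialization.
#' @slot epsilon convergence threshold on the max-norm change of H.
#' @slot maxIter iteration cap.
#'
#' @seealso [jgrnmf()]
#' @export
setClass("JGRNMFFit",
    representation(
        W = "matrix",
        H = "matrix",
        alpha1 = "numeric",
        alpha2 = "numeric",
        objectiveTrace = "numeric",
        errTrace = "numeric",
        iterations = "integer",
        converged = "logical",
        seed = "integer",
        epsilon = "numeric",
        maxIter = "integer"
    )
)

setValidity("JGRNMFFit", function(object) {
    msg <- character()
    if (ncol(object@W) != nrow(object@H))
        msg <- c(msg, "W and H have incompatible factor dimensions")
    if (min(object@W) < 0 || min(object@H) < 0)
        msg <- c(msg, "W and H must be non-negative")
    if (object@alpha1 < 0 || object@alpha2 < 0)
        msg <- c(msg, "alpha1 and alpha2 must be non-negative")
    if (length(msg)) msg else TRUE
})

#' DomainAssignment: per-spot spatial domain labels
#'
#' @slot labels named integer vector, one 1-based domain id per spot.
#' @slot k number of domains.
#' @slot seed clustering seed.
#'
#' @seealso [clusterEmbedding()]
#' @export
setClass("DomainAssignment",
    representation(
        labels = "integer",
        k = "integer",
        seed = "integer"
    )
)

setValidity("DomainAssignment", function(object) {
    msg <- character()
    if (any(object@labels < 1L) || any(object@labels > object@k))
        msg <- c(msg, "labels must lie in 1..k")
    if (length(msg)) msg else TRUE
})

#' @describeIn SpotGraph-class number of spots
#' @param x,object a `SpotGraph`
#' @export
setMethod("dim", "SpotGraph", function(x) dim(x@adjacency))

setMethod("show", "SpotGraph", function(object) {
    A <- object@adjacency
    cat(sprintf(
        "SpotGraph (%s): %d spots, %d undirected edges, mean weighted degree %.3f\n",
        object@kind, nrow(A), Matrix::nnzero(A) %/% 2L,
        mean(object@degrees)
    ))
})

setMethod("show", "JGRNMFFit", function(object) {
    cat(sprintf(
        paste0(
            "JGRNMFFit: %d genes x %d factors x %d spots\n",
            "  alpha1 = %g, alpha2 = %g\n",
            "  %d iterations, converged = %s, final objective = %.6g\n"
        ),
        nrow(object@W), ncol(object@W), ncol(object@H),
        object@alpha1, object@alpha2, object@iterations,
        object@converged,
        object@objectiveTrace[length(object@objectiveTrace)]
    ))
})

setMethod("show", "DomainAssignment", function(object) {
    cat(sprintf(
        "DomainAssignment: %d spots in %d domains (sizes: %s)\n",
        length(object@labels), object@k,
        paste(tabulate(object@labels, object@k), collapse = ", ")
    ))
})

#' Accessors for SpotGraph, JGRNMFFit and DomainAssignment
#'
#' @param object a `SpotGraph`, `JGRNMFFit` or `DomainAssignment`.
#' @return `adjacency`, `laplacian`: sparse matrices; `degrees`: numeric
#'   vector; `basisMatrix`, `embeddingMatrix`: dense matrices;
#'   `objectiveTrace`, `errTrace`: numeric vectors; `isConverged`: logical;
#'   `domainLabels`: named integer vector; `nDomains`: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "SpotGraph", function(object) object@adjacency)

#' @rdname accessors
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))
#' @rdname accessors
#' @export
setMethod("degrees", "SpotGraph", function(object) object@degrees)

#' @rdname accessors
#' @export
setGeneric("laplacian", function(object) standardGeneric("laplacian"))
#' @rdname accessors
#' @export
setMethod("laplacian", "SpotGraph", function(object) object@laplacian)

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setMethod("basisMatrix", "JGRNMFFit", function(object) object@W)

#' @rdname accessors
#' @export
setGeneric("embeddingMatrix",
    function(object) standardGeneric("embeddingMatrix"))
#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "JGRNMFFit", function(object) object@H)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "JGRNMFFit", function(object) object@objectiveTrace)

#' @rdname accessors
#' @export
setGeneric("errTrace", function(object) standardGeneric("errTrace"))
#' @rdname accessors
#' @export
setMethod("errTrace", "JGRNMFFit", function(object) object@errTrace)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "JGRNMFFit", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("domainLabels", function(object) standardGeneric("domainLabels"))
#' @rdname accessors
#' @export
setMethod("domainLabels", "DomainAssignment", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("nDomains", function(object) standardGeneric("nDomains"))
#' @rdname accessors
#' @export
setMethod("nDomains", "DomainAssignment", function(object) object@k)
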