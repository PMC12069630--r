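#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix rowSums colSums t crossprod
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Triangular surface mesh
#'
#' Holds the native cortical geometry: an \code{N x 3} matrix of vertex
#' coordinates (millimetres) and an \code{M x 3} integer matrix of triangle
#' faces.  Faces are stored 1-based (R convention); the FreeSurfer readers
#' and writers convert from/to the 0-based on-disk indices.
#'
#' @slot vertices numeric \code{N x 3} matrix of coordinates.
#' @slot faces integer \code{M x 3} matrix of vertex indices in \code{1..N},
#'   pairwise distinct within each face.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be an N x 3 numeric matrix")
    if (ncol(f) != 3L) return("faces must be an M x 3 integer matrix")
    if (nrow(v) < 3L) return("a mesh needs at least 3 vertices")
    if (nrow(f) < 1L) return("a mesh needs at least 1 face")
    if (!all(is.finite(v))) return("non-finite vertex coordinate")
    if (any(f < 1L) || any(f > nrow(v))) return("face index out of range")
    if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
      return("face with repeated vertex index")
    TRUE
  })

#' Construct a SurfaceMesh
#'
#' @param vertices numeric \code{N x 3} matrix.
#' @param faces integer \code{M x 3} matrix of 1-based vertex indices.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  new("SurfaceMesh", vertices = vertices, faces = as.matrix(faces))
}

#' Brain graph of a cortical surface
#'
#' The sparse graph machinery for one subject: the binary adjacency
#' \code{A} derived from mesh edges (no self-loops), the self-looped
#' \code{A + I}, its degree vector, and the renormalized propagation
#' operator \code{D^-1/2 (A + I) D^-1/2} used by every GCN layer.
#'
#' @slot adjacency sparse symmetric binary adjacency, zero diagonal.
#' @slot selfloopAdjacency \code{adjacency + I}.
#' @slot degrees row sums of \code{selfloopAdjacency}.
#' @slot normOperator the renormalized operator; symmetric, spectrum in
#'   \code{[-1, 1]}.
#' @export
setClass("BrainGraph",
  representation(adjacency = "Matrix", selfloopAdjacency = "Matrix",
                 degrees = "numeric", normOperator = "Matrix"),
  validity = function(object) {
    n <- nrow(object@adjacency)
    if (ncol(object@adjacency) != n) return("adjacency must be square")
    if (length(object@degrees) != n) return("degree vector length mismatch")
    if (any(Matrix::diag(object@adjacency) != 0)) return("adjacency must have a zero diagonal")
    if (any(Matrix::diag(object@selfloopAdjacency) != 1)) return("self-looped adjacency must have a unit diagonal")
    TRUE
  })

#' Cortical parcellation (per-vertex labels)
#'
#' Per-vertex integer class labels in \code{0..K-1} with an ignore
#' sentinel for unlabeled vertices, plus the label table mapping each
#' class to its region name, RGB colour and original structure id (as in
#' FreeSurfer annot colortables).
#'
#' @slot labels integer vector, entries in \code{0..K-1} or \code{ignoreIndex}.
#' @slot ignoreIndex sentinel for unlabeled vertices (default \code{-1}).
#' @slot labelTable data.frame with columns \code{class}, \code{name},
#'   \code{red}, \code{green}, \code{blue}, \code{structureId}.
#' @export
setClass("Parcellation",
  representation(labels = "integer", ignoreIndex = "integer", labelTable = "data.frame"),
  validity = function(object) {
    tab <- object@labelTable
    need <- c("class", "name", "red", "green", "blue", "structureId")
    if (!all(need %in% names(tab))) return("labelTable lacks required columns")
    k <- nrow(tab)
    if (k > 0L && !identical(sort(tab$class), 0:(k - 1L)))
      return("labelTable classes must be contiguous 0..K-1")
    lab <- object@labels
    keep <- lab != object@ignoreIndex
    if (any(keep) && (any(lab[keep] < 0L) || any(lab[keep] >= k)))
      return("label outside the label table")
    TRUE
  })

#' Construct a Parcellation
#'
#' @param labels integer vector of class indices (\code{0..K-1}) with
#'   \code{ignoreIndex} marking unlabeled vertices.
#' @param labelTable data.frame mapping classes to names and colours; built
#'   automatically (distinct colours, generic names) when omitted.
#' @param ignoreIndex unlabeled sentinel, default \code{-1L}.
#' @return A \linkS4class{Parcellation}.
#' @export
Parcellation <- function(labels, labelTable = NULL, ignoreIndex = -1L) {
  labels <- as.integer(labels)
  if (is.null(labelTable)) {
    k <- if (any(labels != ignoreIndex)) max(labels[labels != ignoreIndex]) + 1L else 0L
    labelTable <- defaultLabelTable(k)
  }
  new("Parcellation", labels = labels, ignoreIndex = as.integer(ignoreIndex),
      labelTable = labelTable)
}

## Distinct, never-black colours so the packed RGB of every class is unique
## and nonzero (0 is reserved for unlabeled vertices in annot files).
defaultLabelTable <- function(k, names = NULL) {
  if (is.null(names)) names <- sprintf("parcel_%02d", seq_len(k) - 1L)
  packed <- seq_len(k)          # 1..k, nonzero and distinct
  data.frame(class = seq_len(k) - 1L,
             name = names,
             red = packed %% 256L,
             green = (packed %/% 256L) %% 256L,
             blue = (packed %/% 65536L) %% 256L,
             structureId = seq_len(k) - 1L,
             stringsAsFactors = FALSE)
}

#' One subject: mesh, graph, features, labels
#'
#' @slot id subject identifier.
#' @slot mesh the \linkS4class{SurfaceMesh}.
#' @slot graph the \linkS4class{BrainGraph} built from the mesh.
#' @slot features \code{N x C} per-vertex feature matrix.
#' @slot labels integer ground-truth labels (\code{0..K-1}, \code{-1} ignored).
#' @export
setClass("CortexSubject",
  representation(id = "character", mesh = "SurfaceMesh", graph = "BrainGraph",
                 features = "matrix", labels = "integer"),
  validity = function(object) {
    n <- nrow(object@graph@adjacency)
    if (nrow(object@features) != n) return("feature rows must match graph size")
    if (length(object@labels) != n) return("label length must match graph size")
    TRUE
  })

#' Eigendecomposition of a normalized graph Laplacian
#'
#' @slot vectors orthonormal eigenvector matrix \code{U}.
#' @slot values eigenvalues (all in \code{[0, 2]} for a normalized Laplacian).
#' @slot lambdaMax the largest eigenvalue.
#' @export
setClass("SpectralDecomposition",
  representation(vectors = "matrix", values = "numeric", lambdaMax = "numeric"),
  validity = function(object) {
    if (nrow(object@vectors) != length(object@values))
      return("eigenvector/eigenvalue dimension mismatch")
    TRUE
  })

## ---- generics & accessors -------------------------------------------------

#' Number of vertices
#' @param x a SurfaceMesh, BrainGraph, Parcellation or CortexSubject.
#' @return integer vertex count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
#' @rdname nVertices
#' @export
setMethod("nVertices", "BrainGraph", function(x) nrow(x@adjacency))
#' @rdname nVertices
#' @export
setMethod("nVertices", "Parcellation", function(x) length(x@labels))
#' @rdname nVertices
#' @export
setMethod("nVertices", "CortexSubject", function(x) nrow(x@features))

#' Mesh accessors
#' @param x a \linkS4class{SurfaceMesh}.
#' @return the coordinate or face matrix.
#' @export
meshVertices <- function(x) x@vertices

#' @rdname meshVertices
#' @export
meshFaces <- function(x) x@faces

#' Number of faces
#' @param x a \linkS4class{SurfaceMesh}.
#' @export
nFaces <- function(x) nrow(x@faces)

#' Graph accessors
#'
#' \code{adjacencyMatrix} returns the binary adjacency without self-loops,
#' \code{selfloopAdjacency} returns \code{A + I}, \code{graphDegrees} the
#' self-looped degree vector, and \code{normOperator} the renormalized
#' propagation operator.
#'
#' @param x a \linkS4class{BrainGraph}.
#' @export
adjacencyMatrix <- function(x) x@adjacency

#' @rdname adjacencyMatrix
#' @export
selfloopAdjacency <- function(x) x@selfloopAdjacency

#' @rdname adjacencyMatrix
#' @export
graphDegrees <- function(x) x@degrees

#' @rdname adjacencyMatrix
#' @export
normOperator <- function(x) x@normOperator

#' Parcellation accessors
#' @param x a \linkS4class{Parcellation}.
#' @export
parcLabels <- function(x) x@labels

#' @rdname parcLabels
#' @export
labelTable <- function(x) x@labelTable

#' @rdname parcLabels
#' @export
ignoreIndex <- function(x) x@ignoreIndex

#' @rdname parcLabels
#' @export
nClasses <- function(x) nrow(x@labelTable)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
})
setMethod("show", "BrainGraph", function(object) {
  cat(sprintf("BrainGraph: %d vertices, %d undirected edges (+ self-loops)\n",
              nVertices(object), as.integer(Matrix::nnzero(object@adjacency) / 2)))
})
setMethod("show", "Parcellation", function(object) {
  k <- nClasses(object)
  nIgn <- sum(object@labels == object@ignoreIndex)
  cat(sprintf("Parcellation: %d vertices, %d regions, %d unlabeled\n",
              nVertices(object), k, nIgn))
})
setMethod("show", "CortexSubject", function(object) {
  cat(sprintf("CortexSubject '%s': %d vertices, %d feature channels\n",
              object@id, nVertices(object), ncol(object@features)))
})
setMethod("show", "SpectralDecomposition", function(object) {
  cat(sprintf("SpectralDecomposition: n = %d, lambda_max = %.6f\n",
              length(object@values), object@lambdaMax))
})
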