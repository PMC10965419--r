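#' OntologyDAG: one namespace of an ontology as a rooted DAG
#'
#' Terms of a single namespace with their hierarchical (child-to-parent)
#' edges, a precomputed children-first topological order and the root set.
#' Term indices (1..m, in lexicographic id order) are the column index used
#' by every annotation and score matrix aligned to this graph.
#'
#' @slot namespace single namespace tag (\code{"default"} when the OBO file
#'   carries none).
#' @slot terms character vector of term accessions, sorted; defines the
#'   term index.
#' @slot termNames human-readable labels, parallel to \code{terms}.
#' @slot parents list, parallel to \code{terms}; integer indices of each
#'   term's direct parents.
#' @slot children list, parallel to \code{terms}; integer indices of each
#'   term's direct children (inverse of \code{parents}).
#' @slot topoOrder integer permutation of 1..m placing every term before
#'   all of its ancestors (children first, roots last).
#' @slot roots integer indices of terms with no parents (never empty).
#' @slot altIds named character vector mapping secondary ids to canonical
#'   term accessions.
#'
#' @export
setClass("OntologyDAG",
  representation(
    namespace = "character",
    terms     = "character",
    termNames = "character",
    parents   = "list",
    children  = "list",
    topoOrder = "integer",
    roots     = "integer",
    altIds    = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  m <- length(object@terms)
  msg <- character()
  if (length(object@namespace) != 1L)
    msg <- c(msg, "namespace must be a single string")
  if (m == 0L)
    msg <- c(msg, "ontology namespace has no terms")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term ids must be unique")
  if (length(object@termNames) != m || length(object@parents) != m ||
      length(object@children) != m)
    msg <- c(msg, "termNames/parents/children must parallel terms")
  if (length(object@topoOrder) != m ||
      !identical(sort(object@topoOrder), seq_len(m)))
    msg <- c(msg, "topoOrder must be a permutation of 1..m")
  if (m > 0L && length(object@roots) == 0L)
    msg <- c(msg, "a valid DAG has at least one root")
  if (length(msg) == 0L) {
    # every child must precede each of its parents
    pos <- integer(m)
    pos[object@topoOrder] <- seq_len(m)
    for (i in seq_len(m)) {
      p <- object@parents[[i]]
      if (length(p) && any(pos[p] <= pos[i]))
        return(sprintf("topoOrder violated at term '%s'", object@terms[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationMatrix: boolean targets-by-terms ground truth
#'
#' Sparse boolean matrix with one row per annotated target and one column
#' per term of a single ontology namespace, column-aligned to the
#' \linkS4class{OntologyDAG} term index.
#'
#' @slot namespace namespace tag matching the graph it is aligned to.
#' @slot targets character vector of target identifiers (row order).
#' @slot annotations \code{lgCMatrix}, n x m, TRUE where the target carries
#'   the term.
#' @slot propagated TRUE once annotations have been extended to all
#'   ancestors.
#'
#' @export
setClass("AnnotationMatrix",
  representation(
    namespace   = "character",
    targets     = "character",
    annotations = "lgCMatrix",
    propagated  = "logical"
  )
)

setValidity("AnnotationMatrix", function(object) {
  msg <- character()
  if (nrow(object@annotations) != length(object@targets))
    msg <- c(msg, "one matrix row per target required")
  if (anyDuplicated(object@targets))
    msg <- c(msg, "target identifiers must be unique")
  if (length(object@propagated) != 1L)
    msg <- c(msg, "propagated must be a single logical")
  if (length(msg)) msg else TRUE
})

#' ScoreMatrix: real-valued targets-by-terms prediction scores
#'
#' Sparse numeric matrix of prediction scores in (0, 1]; a structural zero
#' means "not predicted". Rows are the subset of ground-truth targets the
#' method made predictions for, columns align to the
#' \linkS4class{OntologyDAG} term index.
#'
#' @slot namespace namespace tag matching the graph it is aligned to.
#' @slot targets character vector of predicted target identifiers.
#' @slot scores \code{dgCMatrix}, n' x m, entries in (0, 1].
#' @slot propagated \code{"none"}, \code{"fill"} or \code{"max"} depending
#'   on which propagation has been applied.
#'
#' @export
setClass("ScoreMatrix",
  representation(
    namespace  = "character",
    targets    = "character",
    scores     = "dgCMatrix",
    propagated = "character"
  )
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@targets))
    msg <- c(msg, "one matrix row per target required")
  if (anyDuplicated(object@targets))
    msg <- c(msg, "target identifiers must be unique")
  x <- object@scores@x
  if (length(x) && (min(x) <= 0 || max(x) > 1))
    msg <- c(msg, "stored scores must lie in (0, 1]")
  if (!object@propagated %in% c("none", "fill", "max"))
    msg <- c(msg, "propagated must be one of 'none', 'fill', 'max'")
  if (length(msg)) msg else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("termIds", "OntologyDAG", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("nTerms", "OntologyDAG", function(x) length(x@terms))

#' @rdname accessors
#' @export
setMethod("termParents", "OntologyDAG", function(x) {
  stats::setNames(lapply(x@parents, function(p) x@terms[p]), x@terms)
})

#' @rdname accessors
#' @export
setMethod("topoOrder", "OntologyDAG", function(x) x@topoOrder)

#' @rdname accessors
#' @export
setMethod("rootTerms", "OntologyDAG", function(x) x@roots)

#' @rdname accessors
#' @export
setMethod("ontNamespace", "OntologyDAG", function(x) x@namespace)

#' @rdname accessors
#' @export
setMethod("ontNamespace", "AnnotationMatrix", function(x) x@namespace)

#' @rdname accessors
#' @export
setMethod("ontNamespace", "ScoreMatrix", function(x) x@namespace)

#' @rdname accessors
#' @export
setMethod("targetIds", "AnnotationMatrix", function(x) x@targets)

#' @rdname accessors
#' @export
setMethod("targetIds", "ScoreMatrix", function(x) x@targets)

#' @rdname accessors
#' @export
setMethod("nTargets", "AnnotationMatrix", function(x) length(x@targets))

#' @rdname accessors
#' @export
setMethod("nTargets", "ScoreMatrix", function(x) length(x@targets))

#' @rdname accessors
#' @export
setMethod("isPropagated", "AnnotationMatrix", function(x) x@propagated)

#' @rdname accessors
#' @export
setMethod("isPropagated", "ScoreMatrix", function(x) x@propagated != "none")

#' Extract the underlying sparse matrix
#'
#' @param x an \code{AnnotationMatrix} or \code{ScoreMatrix}.
#' @return The sparse matrix held by \code{x} (\code{lgCMatrix} for
#'   annotations, \code{dgCMatrix} for scores), with target row names and
#'   term column names.
#' @export
annotationMatrix <- function(x) {
  stopifnot(is(x, "AnnotationMatrix"))
  x@annotations
}

#' @rdname annotationMatrix
#' @export
scoreMatrix <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  x@scores
}

## ---- show ----------------------------------------------------------------

setMethod("show", "OntologyDAG", function(object) {
  nEdges <- sum(lengths(object@parents))
  cat(sprintf(
    "OntologyDAG '%s': %d terms, %d edges, %d root(s)\n",
    object@namespace, length(object@terms), nEdges, length(object@roots)))
  invisible(NULL)
})

setMethod("show", "AnnotationMatrix", function(object) {
  cat(sprintf(
    "AnnotationMatrix '%s': %d targets x %d terms, %d annotations (%s)\n",
    object@namespace, nrow(object@annotations), ncol(object@annotations),
    sum(object@annotations),
    if (object@propagated) "propagated" else "direct"))
  invisible(NULL)
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf(
    "ScoreMatrix '%s': %d targets x %d terms, %d scored cells (propagation: %s)\n",
    object@namespace, nrow(object@scores), ncol(object@scores),
    length(object@scores@x), object@propagated))
  invisible(NULL)
})
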