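#' @title Accessor generics
#' @description Generics for the core evaluation containers: ontology DAGs,
#'   ground-truth annotation matrices and prediction score matrices.
#' @param x an \code{OntologyDAG}, \code{AnnotationMatrix} or
#'   \code{ScoreMatrix} object.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname accessors
#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))

#' @rdname accessors
#' @export
setGeneric("termParents", function(x) standardGeneric("termParents"))

#' @rdname accessors
#' @export
setGeneric("topoOrder", function(x) standardGeneric("topoOrder"))

#' @rdname accessors
#' @export
setGeneric("rootTerms", function(x) standardGeneric("rootTerms"))

#' @rdname accessors
#' @export
setGeneric("ontNamespace", function(x) standardGeneric("ontNamespace"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))

#' @rdname accessors
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' Propagate annotations or scores towards the ontology root(s)
#'
#' @param x an \code{AnnotationMatrix} or \code{ScoreMatrix}.
#' @param graph the \code{OntologyDAG} the columns of \code{x} are aligned to.
#' @param ... further arguments passed to methods (\code{mode} for score
#'   propagation).
#' @return An object of the same class as \code{x} with annotations/scores
#'   extended to all ancestors.
#' @export
setGeneric("propagate", function(x, graph, ...) standardGeneric("propagate"))
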