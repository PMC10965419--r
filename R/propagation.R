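#' @describeIn propagate Extend every target's annotation set to its full
#'   ancestor closure: after propagation a cell (target, term) is TRUE iff
#'   the term is an ancestor-or-self of a directly annotated term. One
#'   linear pass over the topological order; idempotent, so re-propagating
#'   an already closed matrix is a no-op.
#' @export
setMethod("propagate", signature(x = "AnnotationMatrix", graph = "OntologyDAG"),
  function(x, graph, ...) {
    .checkAligned(x, graph)
    M <- .propagateTruth(x@annotations, graph)
    methods::initialize(x, annotations = M, propagated = TRUE)
  })

#' @describeIn propagate Push prediction scores towards the root(s), one
#'   linear pass over the topological order (children before parents). In
#'   \code{mode = "fill"} (the CAFA default) a parent's own score is never
#'   overwritten: only unscored parents receive the maximum over their
#'   children's (already processed) scores, and that kept-or-filled value
#'   is what cascades further up. In \code{mode = "max"} every parent
#'   receives the maximum of its own score and its children's, so scores
#'   are monotone non-increasing from root to leaf and every thresholded
#'   prediction is a consistent subgraph.
#' @param mode \code{"fill"} or \code{"max"}.
#' @export
setMethod("propagate", signature(x = "ScoreMatrix", graph = "OntologyDAG"),
  function(x, graph, mode = c("fill", "max"), ...) {
    mode <- match.arg(mode)
    .checkAligned(x, graph)
    S <- .propagateScores(x@scores, graph, mode)
    methods::initialize(x, scores = S, propagated = mode)
  })

.checkAligned <- function(x, graph) {
  mat <- if (is(x, "AnnotationMatrix")) x@annotations else x@scores
  if (ncol(mat) != nTerms(graph) || !identical(x@namespace, graph@namespace))
    stop("matrix is not aligned to this ontology namespace")
  invisible(TRUE)
}

## Truth propagation as a boolean matrix product with the ancestor
## reachability matrix R (R[i, a] = TRUE iff a is an ancestor-or-self of
## i). R is built in one pass over the reverse topological order (roots
## first), so each term's row is the union of its parents' finished rows.
.propagateTruth <- function(M, graph) {
  R <- .reachability(graph)
  out <- methods::as(Matrix::drop0((M %*% R) > 0), "CsparseMatrix")
  dimnames(out) <- dimnames(M)
  methods::as(out, "lMatrix")
}

.reachability <- function(graph) {
  m <- nTerms(graph)
  rows <- vector("list", m)  # ancestor-or-self index sets
  for (i in rev(graph@topoOrder)) {
    anc <- i
    for (p in graph@parents[[i]]) anc <- c(anc, rows[[p]])
    rows[[i]] <- unique(anc)
  }
  j <- unlist(rows)
  i <- rep.int(seq_len(m), lengths(rows))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(m, m))
}

## Score propagation: one pass over the topological order. cand[, p]
## accumulates the maximum over p's already-processed children; when p
## itself is reached all its children have contributed.
## `dense` switches the working representation: dense arrays are faster
## for the column updates but unaffordable for challenge-scale n x m, so
## the default falls back to sparse column assignment on large inputs.
.propagateScores <- function(S, graph, mode, dense = NULL) {
  n <- nrow(S)
  m <- ncol(S)
  if (n == 0L || sum(lengths(graph@parents)) == 0L) return(S)
  if (is.null(dense)) dense <- as.double(n) * m <= 2e7
  X <- if (dense) as.matrix(S) else S
  cand <- if (dense) matrix(0, n, m) else
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(n, m))
  for (i in graph@topoOrder) {
    own <- X[, i]
    ci <- cand[, i]
    v <- if (mode == "max") pmax(own, ci) else ifelse(own > 0, own, ci)
    if (!identical(v, own)) X[, i] <- v
    for (p in graph@parents[[i]]) {
      cp <- cand[, p]
      up <- v > cp
      if (any(up)) cand[, p] <- pmax(cp, v)
    }
  }
  out <- methods::as(Matrix::drop0(X), "CsparseMatrix")
  dimnames(out) <- dimnames(S)
  out
}
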