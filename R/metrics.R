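#' Precision, recall and F-measure from confusion masses
#'
#' Degenerate denominators are defined as 0 (nothing predicted gives
#' precision 0; empty truth gives recall 0), so every record is total.
#' Inputs may be counts or information-accretion mass sums; all arguments
#' are vectorized.
#'
#' @param tp,fp,fn non-negative true-positive / false-positive /
#'   false-negative masses.
#' @return data.frame with columns \code{pr}, \code{rc}, \code{f}.
#' @examples
#' prRcF(2, 1, 1)  # pr = rc = f = 2/3
#' @export
prRcF <- function(tp, fp, fn) {
  pr <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rc <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  data.frame(pr = pr, rc = rc, f = f)
}

#' Remaining uncertainty, misinformation and semantic distance
#'
#' \code{ru} is the information-accretion mass of the false negatives,
#' \code{mi} that of the false positives, and
#' \code{s = sqrt(ru^2 + mi^2)} their Euclidean combination (the semantic
#' distance between prediction and truth). Vectorized.
#'
#' @param fnIA,fpIA non-negative information-accretion masses of false
#'   negatives and false positives.
#' @return data.frame with columns \code{ru}, \code{mi}, \code{s}.
#' @examples
#' ruMiS(3, 4)  # s = 5
#' @export
ruMiS <- function(fnIA, fpIA) {
  data.frame(ru = fnIA, mi = fpIA, s = sqrt(fnIA^2 + fpIA^2))
}

#' Per-target confusion masses at one threshold
#'
#' For each target, the predicted set P is the set of terms with score
#' >= \code{tau} (structural zeros are never predicted, including at
#' \code{tau = 0}) and the true set T is the annotated set. With
#' \code{excludeRoots}, namespace roots are removed from both sets before
#' counting, so a root-only prediction counts as no prediction at all.
#' Unweighted masses are set cardinalities; weighted masses sum the
#' information-accretion weights over the same sets.
#'
#' @param truth logical matrix (targets x terms); a single target may be
#'   given as a vector.
#' @param scores numeric matrix of the same shape, entries in [0, 1].
#' @param tau threshold in [0, 1).
#' @param weights optional per-term information-accretion weights.
#' @param excludeRoots remove root terms before counting?
#' @param roots integer indices of the root terms (required when
#'   \code{excludeRoots}).
#' @return List with per-target vectors \code{tp}, \code{fp}, \code{fn},
#'   logical \code{predicted}, and — when \code{weights} is supplied —
#'   \code{tpW}, \code{fpW}, \code{fnW}.
#' @export
confusionCounts <- function(truth, scores, tau, weights = NULL,
                            excludeRoots = FALSE, roots = integer()) {
  stopifnot(tau >= 0, tau < 1)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1L)
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1L)
  if (excludeRoots && length(roots)) {
    keep <- setdiff(seq_len(ncol(scores)), roots)
    truth <- truth[, keep, drop = FALSE]
    scores <- scores[, keep, drop = FALSE]
    weights <- weights[keep]
  }
  P <- scores > 0
  if (tau > 0) P <- P & (scores >= tau)
  hits <- P & truth
  tp <- Matrix::rowSums(hits)
  fp <- Matrix::rowSums(P) - tp
  fn <- Matrix::rowSums(truth) - tp
  out <- list(tp = as.numeric(tp), fp = as.numeric(fp),
              fn = as.numeric(fn),
              predicted = as.numeric(Matrix::rowSums(P)) > 0)
  if (!is.null(weights)) {
    w <- as.numeric(weights)
    tpW <- as.numeric(hits %*% w)
    out$tpW <- tpW
    out$fpW <- as.numeric(P %*% w) - tpW
    out$fnW <- as.numeric(truth %*% w) - tpW
  }
  out
}

#' Aggregate per-target confusions into one evaluation record
#'
#' Macro-averaging computes precision/recall per target and then averages:
#' recall always over all ground-truth targets, precision over the targets
#' with at least one prediction at the threshold (\code{norm = "cafa"},
#' the CAFA convention) or over all ground-truth targets
#' (\code{norm = "full"}, penalizing low coverage). Micro-averaging sums
#' the confusion masses over targets first and computes the metrics once
#' (dividing the summed masses by the number of targets first changes
#' nothing, as the factor cancels in every ratio). Remaining uncertainty
#' and misinformation are always averaged over all ground-truth targets.
#'
#' @param conf list from \code{\link{confusionCounts}} over all
#'   ground-truth targets of a namespace.
#' @param averaging \code{"macro"} or \code{"micro"}.
#' @param norm \code{"cafa"} or \code{"full"}.
#' @return One-row data.frame: \code{n}, \code{cov}, \code{pr}, \code{rc},
#'   \code{f}, plus \code{wpr}, \code{wrc}, \code{wf}, \code{ru},
#'   \code{mi}, \code{s} when weighted masses are present.
#' @export
aggregateConfusion <- function(conf, averaging = c("macro", "micro"),
                               norm = c("cafa", "full")) {
  averaging <- match.arg(averaging)
  norm <- match.arg(norm)
  n <- length(conf$tp)
  stopifnot(n >= 1L)
  flag <- conf$predicted
  rec <- data.frame(n = n, cov = mean(flag))
  rec <- cbind(rec, .avgPrRcF(conf$tp, conf$fp, conf$fn, flag,
                              averaging, norm))
  if (!is.null(conf$tpW)) {
    w <- .avgPrRcF(conf$tpW, conf$fpW, conf$fnW, flag, averaging, norm)
    names(w) <- c("wpr", "wrc", "wf")
    rec <- cbind(rec, w, ruMiS(mean(conf$fnW), mean(conf$fpW)))
  }
  rec
}

.avgPrRcF <- function(tp, fp, fn, flag, averaging, norm) {
  if (averaging == "micro")
    return(prRcF(sum(tp), sum(fp), sum(fn)))
  per <- prRcF(tp, fp, fn)
  pr <- if (norm == "cafa") {
    if (any(flag)) sum(per$pr[flag]) / sum(flag) else 0
  } else {
    mean(per$pr)
  }
  rc <- mean(per$rc)
  f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  data.frame(pr = pr, rc = rc, f = f)
}

#' Evenly spaced score thresholds
#'
#' The default grid: \code{n} evenly spaced cutoffs covering [0, 1),
#' i.e. 0, 1/n, ..., (n-1)/n; with the default \code{n = 100} that is
#' 0.00, 0.01, ..., 0.99.
#'
#' @param n number of cutoffs.
#' @return Numeric vector of thresholds.
#' @export
defaultThresholds <- function(n = 100L) {
  stopifnot(n >= 1L)
  seq(0, by = 1 / n, length.out = n)
}

#' Threshold sweep: one evaluation record per cutoff
#'
#' Computes per-target confusions at every threshold of the grid and
#' aggregates them into one record per threshold (see
#' \code{\link{aggregateConfusion}}). Ground-truth targets missing from
#' the score matrix participate with an empty prediction, so coverage and
#' all-target averages are taken over the full ground truth. The grid can
#' be partitioned into blocks evaluated independently (optionally on
#' several worker processes); the result is identical to sequential
#' evaluation and ordered by threshold.
#'
#' Both matrices must already be propagated; pass them through
#' \code{\link{propagate}} first.
#'
#' @param gt propagated \linkS4class{AnnotationMatrix}.
#' @param pred propagated \linkS4class{ScoreMatrix} of the same namespace.
#' @param graph the \linkS4class{OntologyDAG} both are aligned to.
#' @param weights optional information-accretion weights from
#'   \code{\link{readIA}}; triggers the weighted metrics.
#' @param thresholds ordered numeric vector of cutoffs in [0, 1).
#' @param averaging,norm see \code{\link{aggregateConfusion}}.
#' @param excludeRoots drop namespace roots from every predicted and true
#'   set.
#' @param nBlocks number of threshold blocks.
#' @param workers number of worker processes (forked; results are
#'   identical for any value).
#' @return data.frame with one row per threshold: \code{ns}, \code{tau},
#'   \code{n}, \code{cov}, \code{pr}, \code{rc}, \code{f} and, with
#'   weights, \code{wpr}, \code{wrc}, \code{wf}, \code{ru}, \code{mi},
#'   \code{s}.
#' @export
sweepThresholds <- function(gt, pred, graph, weights = NULL,
                            thresholds = defaultThresholds(),
                            averaging = c("macro", "micro"),
                            norm = c("cafa", "full"),
                            excludeRoots = FALSE,
                            nBlocks = 1L, workers = 1L) {
  averaging <- match.arg(averaging)
  norm <- match.arg(norm)
  stopifnot(is(gt, "AnnotationMatrix"), is(pred, "ScoreMatrix"))
  .checkAligned(gt, graph)
  .checkAligned(pred, graph)
  if (length(thresholds) == 0L)
    stop("empty threshold grid")
  stopifnot(all(thresholds >= 0), all(thresholds < 1))
  thresholds <- sort(thresholds)

  truth <- gt@annotations
  scores <- .alignScores(pred, targetIds(gt), nTerms(graph))
  roots <- rootTerms(graph)

  blocks <- .splitBlocks(seq_along(thresholds), max(1L, as.integer(nBlocks)))
  evalBlock <- function(idx) {
    do.call(rbind, lapply(thresholds[idx], function(tau) {
      conf <- confusionCounts(truth, scores, tau, weights = weights,
                              excludeRoots = excludeRoots, roots = roots)
      cbind(data.frame(ns = ontNamespace(graph), tau = tau),
            aggregateConfusion(conf, averaging, norm))
    }))
  }
  parts <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, evalBlock, mc.cores = workers)
  } else {
    lapply(blocks, evalBlock)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

## Rows of the score matrix reindexed to the full ground-truth target
## list; targets without predictions become all-zero rows.
.alignScores <- function(pred, gtTargets, m) {
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(gtTargets), m),
                            dimnames = list(gtTargets, colnames(pred@scores)))
  hit <- match(targetIds(pred), gtTargets)
  present <- !is.na(hit)
  if (any(present))
    S[hit[present], ] <- pred@scores[present, , drop = FALSE]
  methods::as(S, "CsparseMatrix")
}

.splitBlocks <- function(idx, nBlocks) {
  nBlocks <- min(nBlocks, length(idx))
  split(idx, ceiling(seq_along(idx) / (length(idx) / nBlocks)))
}

#' Best-performance summaries over a threshold sweep
#'
#' Extracts, per prediction file and namespace, the record achieving the
#' maximum F-measure (Fmax), the minimum semantic distance (Smin) and the
#' maximum weighted F-measure (wFmax), with ties broken by the lowest
#' threshold. The Smin and wFmax tables are present only when the sweep
#' carried information-accretion weights.
#'
#' @param records data.frame from \code{\link{sweepThresholds}} (or rows
#'   of several sweeps bound together, with a \code{filename} column).
#' @return Named list of data.frames: \code{fmax}, and with weights
#'   \code{smin} and \code{wfmax}.
#' @export
bestScores <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (is.null(records$filename)) records$filename <- "prediction"
  pick <- function(metric, decreasing) {
    do.call(rbind, lapply(
      split(records, list(records$filename, records$ns), drop = TRUE),
      function(d) {
        v <- d[[metric]]
        best <- if (decreasing) max(v) else min(v)
        cand <- d[v == best, , drop = FALSE]
        cand[which.min(cand$tau), , drop = FALSE]
      }))
  }
  out <- list(fmax = pick("f", TRUE))
  if (!is.null(records$s)) {
    out$smin <- pick("s", FALSE)
    out$wfmax <- pick("wf", TRUE)
  }
  for (i in seq_along(out)) rownames(out[[i]]) <- NULL
  out
}
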