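#' Reference evaluation by explicit set operations
#'
#' An independent re-derivation of the whole evaluation semantics using
#' nothing but named sets and loops: ancestor closures by recursion,
#' propagation by fixpoint iteration of the per-edge rule, confusions by
#' set intersection, and averaging by explicit per-target arithmetic. It
#' deliberately shares no code with the matrix engine (no sparse
#' matrices, no topological order) and exists as its comparison standard
#' on small instances.
#'
#' @param gtPairs data.frame with columns \code{target}, \code{term}:
#'   direct ground-truth annotations.
#' @param predPairs data.frame with columns \code{target}, \code{term},
#'   \code{score}: one method's predictions.
#' @param graph the \linkS4class{OntologyDAG} of one namespace.
#' @param thresholds numeric cutoffs in [0, 1).
#' @param averaging \code{"macro"} or \code{"micro"}.
#' @param norm \code{"cafa"} or \code{"full"}.
#' @param excludeRoots drop root terms from predicted and true sets.
#' @param ia optional named numeric vector of information-accretion
#'   weights (by term id; missing terms weigh 0).
#' @param propMode \code{"fill"} or \code{"max"}.
#' @param maxTerms optional cap on predicted terms per target (ties at
#'   the cut kept for the lexicographically smaller term id).
#' @return data.frame with the same columns as
#'   \code{\link{sweepThresholds}}.
#' @export
oracleEvaluate <- function(gtPairs, predPairs, graph,
                           thresholds = defaultThresholds(),
                           averaging = c("macro", "micro"),
                           norm = c("cafa", "full"),
                           excludeRoots = FALSE, ia = NULL,
                           propMode = c("fill", "max"),
                           maxTerms = NULL) {
  averaging <- match.arg(averaging)
  norm <- match.arg(norm)
  propMode <- match.arg(propMode)
  ids <- termIds(graph)
  parentsOf <- stats::setNames(lapply(graph@parents, function(p) ids[p]), ids)
  childrenOf <- stats::setNames(rep(list(character()), length(ids)), ids)
  for (child in ids)
    for (p in parentsOf[[child]])
      childrenOf[[p]] <- c(childrenOf[[p]], child)
  rootIds <- ids[vapply(parentsOf, length, integer(1)) == 0L]

  memo <- new.env(parent = emptyenv())
  ancestors <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- id
    for (p in parentsOf[[id]]) res <- union(res, ancestors(p))
    memo[[id]] <- res
    res
  }

  ## ground truth: per-target closed sets
  gtPairs$target <- trimws(as.character(gtPairs$target))
  gtPairs$term <- trimws(as.character(gtPairs$term))
  gtPairs <- gtPairs[gtPairs$term %in% ids, , drop = FALSE]
  truthSets <- lapply(split(gtPairs$term, gtPairs$target),
                      function(tt) unique(unlist(lapply(unique(tt),
                                                        ancestors))))
  truthSets <- truthSets[order(names(truthSets))]
  n <- length(truthSets)
  if (n == 0L) stop("oracle: no usable ground truth")

  ## predictions: filter, dedupe by max, optional cap, fixpoint propagation
  predSets <- .oracleScores(predPairs, names(truthSets), ids, maxTerms,
                            childrenOf, propMode)

  iaOf <- function(tt) {
    if (length(tt) == 0L) return(0)
    w <- ia[tt]
    w[is.na(w)] <- 0
    sum(w)
  }

  recs <- lapply(sort(thresholds), function(tau) {
    tp <- fp <- fn <- numeric(n)
    tpW <- fpW <- fnW <- numeric(n)
    flag <- logical(n)
    for (k in seq_len(n)) {
      tg <- names(truthSets)[k]
      T <- truthSets[[k]]
      s <- predSets[[tg]]
      P <- if (is.null(s)) character() else
        names(s)[s > 0 & s >= tau]
      if (excludeRoots) {
        T <- setdiff(T, rootIds)
        P <- setdiff(P, rootIds)
      }
      flag[k] <- length(P) > 0L
      tp[k] <- length(intersect(P, T))
      fp[k] <- length(setdiff(P, T))
      fn[k] <- length(setdiff(T, P))
      if (!is.null(ia)) {
        tpW[k] <- iaOf(intersect(P, T))
        fpW[k] <- iaOf(setdiff(P, T))
        fnW[k] <- iaOf(setdiff(T, P))
      }
    }
    ratio <- function(a, b) if (b > 0) a / b else 0
    avg <- function(tp, fp, fn) {
      if (averaging == "micro") {
        pr <- ratio(sum(tp), sum(tp) + sum(fp))
        rc <- ratio(sum(tp), sum(tp) + sum(fn))
      } else {
        prt <- mapply(function(a, b) ratio(a, a + b), tp, fp)
        rct <- mapply(function(a, b) ratio(a, a + b), tp, fn)
        pr <- if (norm == "cafa") {
          if (any(flag)) sum(prt[flag]) / sum(flag) else 0
        } else sum(prt) / n
        rc <- sum(rct) / n
      }
      f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
      c(pr = pr, rc = rc, f = f)
    }
    rec <- data.frame(ns = ontNamespace(graph), tau = tau, n = n,
                      cov = sum(flag) / n)
    rec <- cbind(rec, as.data.frame(as.list(avg(tp, fp, fn))))
    if (!is.null(ia)) {
      wv <- avg(tpW, fpW, fnW)
      ru <- sum(fnW) / n
      mi <- sum(fpW) / n
      rec <- cbind(rec,
                   data.frame(wpr = wv[["pr"]], wrc = wv[["rc"]],
                              wf = wv[["f"]], ru = ru, mi = mi,
                              s = sqrt(ru^2 + mi^2)))
    }
    rec
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

.oracleScores <- function(predPairs, gtTargets, ids, maxTerms,
                          childrenOf, propMode) {
  predPairs$target <- trimws(as.character(predPairs$target))
  predPairs$term <- trimws(as.character(predPairs$term))
  predPairs$score <- suppressWarnings(as.numeric(predPairs$score))
  predPairs <- predPairs[!is.na(predPairs$score) &
                           predPairs$score > 0 &
                           predPairs$term %in% ids &
                           predPairs$target %in% gtTargets, , drop = FALSE]
  predPairs$score <- pmin(predPairs$score, 1)
  out <- lapply(split(predPairs, predPairs$target), function(d) {
    s <- vapply(split(d$score, d$term), max, numeric(1))
    if (!is.null(maxTerms) && length(s) > maxTerms) {
      o <- order(-s, names(s))
      s <- s[o[seq_len(maxTerms)]]
    }
    full <- stats::setNames(numeric(length(ids)), ids)
    full[names(s)] <- s
    scoredAtInput <- full > 0
    ## fixpoint of the per-edge propagation rule: in fill mode a term
    ## scored in the input always keeps its own score, while an unscored
    ## term tracks the maximum over its children until nothing changes
    repeat {
      changed <- FALSE
      for (t in ids) {
        ch <- childrenOf[[t]]
        if (length(ch) == 0L) next
        top <- max(full[ch])
        newVal <- if (propMode == "max") max(full[t], top)
                  else if (scoredAtInput[[t]]) full[[t]] else top
        if (newVal != full[[t]]) {
          full[t] <- newVal
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    full
  })
  out
}
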