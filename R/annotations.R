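#' Parse a ground-truth annotation file
#'
#' Reads a headerless two-column TSV (target id, term id) and builds one
#' \linkS4class{AnnotationMatrix} per namespace, column-aligned to the
#' corresponding \linkS4class{OntologyDAG}. Identifiers are
#' whitespace-stripped and matched case-sensitively; secondary term ids
#' resolve to their canonical term. Rows naming terms absent from every
#' graph are dropped with a logged count; duplicated pairs collapse to a
#' single annotation. Targets end up in a namespace's matrix only if they
#' carry at least one annotation within that namespace. Zero usable rows
#' overall is a fatal error.
#'
#' The returned matrices hold the direct (unpropagated) annotations; see
#' \code{\link{propagate}}.
#'
#' @param file path to the ground-truth TSV.
#' @param graphs named list of \linkS4class{OntologyDAG} from
#'   \code{\link{readOBO}}.
#' @param text alternatively, the file content as a character vector of
#'   lines (overrides \code{file}).
#' @return Named list of \linkS4class{AnnotationMatrix}, one per namespace
#'   with at least one usable annotation.
#' @export
readGroundTruth <- function(file = NULL, graphs, text = NULL) {
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  fields <- strsplit(text, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok & nzchar(trimws(text))))
    warning(sum(!ok & nzchar(trimws(text))),
            " malformed ground-truth line(s) skipped")
  target <- vapply(fields[ok], function(f) trimws(f[1]), character(1))
  term <- vapply(fields[ok], function(f) trimws(f[2]), character(1))
  keep <- nzchar(target) & nzchar(term)
  target <- target[keep]; term <- term[keep]

  lookup <- .termLookup(graphs)
  hit <- match(term, lookup$id)
  dropped <- sum(is.na(hit))
  if (dropped > 0L)
    warning(dropped, " ground-truth row(s) referencing unknown term(s) dropped")
  if (all(is.na(hit)))
    stop("ground truth contains no usable annotations")
  target <- target[!is.na(hit)]
  ns <- lookup$ns[hit[!is.na(hit)]]
  col <- lookup$col[hit[!is.na(hit)]]

  out <- list()
  for (nsTag in names(graphs)) {
    sel <- ns == nsTag
    if (!any(sel)) next
    g <- graphs[[nsTag]]
    tg <- sort(unique(target[sel]))
    i <- match(target[sel], tg)
    j <- col[sel]
    mat <- Matrix::sparseMatrix(i = i, j = j,
                                dims = c(length(tg), nTerms(g)),
                                dimnames = list(tg, termIds(g)))
    out[[nsTag]] <- methods::new("AnnotationMatrix",
      namespace = nsTag, targets = tg,
      annotations = methods::as(mat, "lMatrix"),
      propagated = FALSE)
  }
  if (length(out) == 0L)
    stop("ground truth contains no usable annotations")
  out
}

## Flat (term id -> namespace, column) lookup across all namespace graphs,
## including secondary ids.
.termLookup <- function(graphs) {
  id <- character(); ns <- character(); col <- integer()
  for (g in graphs) {
    id <- c(id, termIds(g), names(g@altIds))
    ns <- c(ns, rep(ontNamespace(g), nTerms(g) + length(g@altIds)))
    col <- c(col, seq_len(nTerms(g)), match(g@altIds, termIds(g)))
  }
  list(id = id, ns = ns, col = col)
}

#' Parse a prediction file
#'
#' Reads a headerless three-column TSV (target id, term id, score) for one
#' prediction method and builds one \linkS4class{ScoreMatrix} per
#' namespace. Filtering follows the benchmark contract: only targets
#' present in the ground truth and terms present in the ontology are kept
#' (dropped counts are logged); lines that do not have exactly three
#' fields — such as CAFA submission headers — are skipped with a warning;
#' non-numeric scores drop the row; scores above 1 are clamped to 1 with a
#' warning and scores of 0 or below are treated as "not predicted".
#' Duplicate (target, term) pairs keep the maximum score. With
#' \code{maxTerms} set, only the \code{maxTerms} highest-scoring terms per
#' target and namespace are retained (ties at the cut kept for the lower
#' term index).
#'
#' A file with zero usable rows yields empty score matrices — the method
#' is scored, with all-zero metrics, rather than rejected.
#'
#' @param file path to the prediction TSV.
#' @param graphs named list of \linkS4class{OntologyDAG}.
#' @param groundTruth named list of \linkS4class{AnnotationMatrix} from
#'   \code{\link{readGroundTruth}}.
#' @param maxTerms optional positive integer cap on predicted terms per
#'   target per namespace (applied before propagation).
#' @param text alternatively, the file content as a character vector of
#'   lines (overrides \code{file}).
#' @return Named list of \linkS4class{ScoreMatrix}, one per namespace in
#'   \code{groundTruth}.
#' @export
readPredictions <- function(file = NULL, graphs, groundTruth,
                            maxTerms = NULL, text = NULL) {
  if (!is.null(maxTerms))
    stopifnot(is.numeric(maxTerms), length(maxTerms) == 1L, maxTerms >= 1)
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  fields <- strsplit(text, "\t", fixed = TRUE)
  ok <- lengths(fields) == 3L
  skipped <- sum(!ok & nzchar(trimws(text)))
  if (skipped > 0L)
    warning(skipped, " non-3-column prediction line(s) skipped")
  fields <- fields[ok]
  target <- vapply(fields, function(f) trimws(f[1]), character(1))
  term <- vapply(fields, function(f) trimws(f[2]), character(1))
  score <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(score)) {
    warning(sum(is.na(score)), " prediction row(s) with non-numeric ",
            "score dropped")
    keep <- !is.na(score)
    target <- target[keep]; term <- term[keep]; score <- score[keep]
  }
  if (any(score > 1)) {
    warning(sum(score > 1), " prediction score(s) above 1 clamped to 1")
    score <- pmin(score, 1)
  }
  keep <- score > 0
  target <- target[keep]; term <- term[keep]; score <- score[keep]

  lookup <- .termLookup(graphs)
  hit <- match(term, lookup$id)
  gtTargets <- unique(unlist(lapply(groundTruth, targetIds)))
  knownTarget <- target %in% gtTargets
  usable <- !is.na(hit) & knownTarget
  nBadTerm <- sum(is.na(hit))
  nBadTarget <- sum(!knownTarget & !is.na(hit))
  if (nBadTerm > 0L)
    warning(nBadTerm, " prediction row(s) referencing unknown term(s) dropped")
  if (nBadTarget > 0L)
    warning(nBadTarget, " prediction row(s) for target(s) absent from the ",
            "ground truth dropped")
  target <- target[usable]; score <- score[usable]
  ns <- lookup$ns[hit[usable]]
  col <- lookup$col[hit[usable]]

  out <- list()
  for (nsTag in names(groundTruth)) {
    g <- graphs[[nsTag]]
    gtT <- targetIds(groundTruth[[nsTag]])
    sel <- which(ns == nsTag & target %in% gtT)
    t <- target[sel]; j <- col[sel]; s <- score[sel]
    # duplicate (target, term): keep the maximum score
    if (length(sel)) {
      key <- paste(t, j, sep = "\r")
      o <- order(key, -s)
      first <- !duplicated(key[o])
      t <- t[o][first]; j <- j[o][first]; s <- s[o][first]
    }
    if (!is.null(maxTerms) && length(t)) {
      # top maxTerms per target; ties at the boundary keep the lower index
      o <- order(t, -s, j)
      t <- t[o]; j <- j[o]; s <- s[o]
      rank <- stats::ave(s, t, FUN = seq_along)
      keep <- rank <= maxTerms
      t <- t[keep]; j <- j[keep]; s <- s[keep]
    }
    tg <- sort(unique(t))
    mat <- Matrix::sparseMatrix(i = match(t, tg), j = j, x = s,
                                dims = c(length(tg), nTerms(g)),
                                dimnames = list(tg, termIds(g)))
    out[[nsTag]] <- methods::new("ScoreMatrix",
      namespace = nsTag, targets = tg,
      scores = methods::as(mat, "CsparseMatrix"),
      propagated = "none")
  }
  out
}

#' Read a team-mapping file
#'
#' Headerless three-column TSV: prediction filename, team name, display
#' name. A filename listed twice is a fatal error.
#'
#' @param file path to the team map.
#' @param text alternatively, the file content as lines.
#' @return data.frame with columns \code{filename}, \code{team},
#'   \code{display}.
#' @export
readTeamMap <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  text <- text[nzchar(trimws(text))]
  fields <- strsplit(text, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("team map: every line needs at least filename and team")
  df <- data.frame(
    filename = vapply(fields, function(f) trimws(f[1]), character(1)),
    team     = vapply(fields, function(f) trimws(f[2]), character(1)),
    display  = vapply(fields, function(f)
      trimws(if (length(f) >= 3L) f[3] else f[1]), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$filename))
    stop("team map: duplicate filename '",
         df$filename[duplicated(df$filename)][1], "'")
  df
}
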