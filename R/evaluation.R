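#' Run a full benchmark over a directory of prediction files
#'
#' End-to-end evaluation: parses the ontology, the ground truth and the
#' optional information-accretion file once, then processes each
#' prediction file in turn — parse, filter, propagate, threshold sweep —
#' so that only one method's score matrices are in memory at a time.
#' Produces the full evaluation table (one row per file, namespace and
#' threshold) and the best-score tables (Fmax; Smin and wFmax when
#' information accretion is supplied), optionally deduplicated to one
#' prediction per team. Progress, timestamps and target/term statistics
#' are streamed via \code{message()}.
#'
#' An unreadable or unparsable prediction file is skipped with an error
#' logged and the run continues; if no file yields usable predictions the
#' run is fatal. Every output row is a pure function of the inputs and
#' the configuration: reruns are byte-identical regardless of file order,
#' block count or worker count.
#'
#' @param oboFile path to the ontology OBO file.
#' @param predDir directory containing prediction TSVs (or a character
#'   vector of file paths).
#' @param gtFile path to the ground-truth TSV.
#' @param iaFile optional information-accretion TSV; enables the weighted
#'   metrics and the Smin/wFmax tables.
#' @param outDir optional output directory; when given, writes
#'   \code{evaluation_all.tsv}, \code{fmax.tsv} and (with IA)
#'   \code{smin.tsv}, \code{wfmax.tsv}. Created if absent; existing files
#'   are only overwritten with \code{overwrite = TRUE}.
#' @param teamMapFile optional team map (see \code{\link{readTeamMap}});
#'   deduplicates the best tables to one file per team and namespace.
#' @param thresholds explicit threshold vector; default \code{NULL} uses
#'   \code{\link{defaultThresholds}(nThresholds)}.
#' @param nThresholds size of the default evenly spaced grid.
#' @param averaging,norm,excludeRoots,maxTerms see
#'   \code{\link{sweepThresholds}} and \code{\link{readPredictions}}.
#' @param propMode score propagation mode, \code{"fill"} or \code{"max"}.
#' @param includePartOf treat \code{part_of} relationships as
#'   hierarchical edges.
#' @param nBlocks,workers threshold-block partitioning (identical results
#'   for any value).
#' @param overwrite allow replacing existing output files.
#' @return (Invisibly) a list: \code{table} (full evaluation data.frame),
#'   \code{best} (list of best-score tables, team-deduplicated when a team
#'   map was given), \code{skipped} (character vector of skipped files).
#' @export
runEvaluation <- function(oboFile, predDir, gtFile,
                          iaFile = NULL, outDir = NULL, teamMapFile = NULL,
                          thresholds = NULL, nThresholds = 100L,
                          averaging = c("macro", "micro"),
                          norm = c("cafa", "full"),
                          excludeRoots = FALSE, maxTerms = NULL,
                          propMode = c("fill", "max"),
                          includePartOf = FALSE,
                          nBlocks = 1L, workers = 1L,
                          overwrite = FALSE) {
  averaging <- match.arg(averaging)
  norm <- match.arg(norm)
  propMode <- match.arg(propMode)
  if (is.null(thresholds)) thresholds <- defaultThresholds(nThresholds)

  predFiles <- if (length(predDir) == 1L && dir.exists(predDir)) {
    sort(list.files(predDir, full.names = TRUE))
  } else {
    predDir
  }
  predFiles <- predFiles[file.exists(predFiles)]
  if (length(predFiles) == 0L)
    stop("no prediction files found")

  .log("parsing ontology: ", oboFile)
  graphs <- readOBO(oboFile, includePartOf = includePartOf)
  .log(length(graphs), " namespace(s): ",
       paste(vapply(graphs, function(g)
         sprintf("%s (%d terms)", ontNamespace(g), nTerms(g)), character(1)),
         collapse = ", "))

  .log("parsing ground truth: ", gtFile)
  gt <- readGroundTruth(gtFile, graphs)
  gt <- lapply(names(gt), function(nsTag)
    propagate(gt[[nsTag]], graphs[[nsTag]]))
  names(gt) <- vapply(gt, ontNamespace, character(1))
  for (nsTag in names(gt))
    .log("ground truth '", nsTag, "': ", nTargets(gt[[nsTag]]),
         " targets, ", sum(gt[[nsTag]]@annotations),
         " propagated annotations")

  weights <- NULL
  if (!is.null(iaFile)) {
    .log("parsing information accretion: ", iaFile)
    # per-graph "unknown term" warnings are expected noise with several
    # namespaces; report terms unknown to *every* namespace instead
    lookup <- .termLookup(graphs)
    iaIds <- vapply(strsplit(readLines(iaFile, warn = FALSE), "\t",
                             fixed = TRUE),
                    function(f) trimws(f[1]), character(1))
    orphan <- sum(!iaIds[nzchar(iaIds)] %in% lookup$id)
    if (orphan > 0L)
      warning(orphan, " information-accretion entr(y/ies) for term(s) ",
              "absent from the ontology ignored")
    weights <- lapply(graphs, function(g)
      withCallingHandlers(readIA(iaFile, g), warning = function(w) {
        if (grepl("unknown", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
  }

  tables <- list()
  skipped <- character()
  for (pf in predFiles) {
    .log("evaluating ", basename(pf))
    rows <- tryCatch({
      preds <- readPredictions(pf, graphs, gt, maxTerms = maxTerms)
      nsRows <- lapply(names(gt), function(nsTag) {
        p <- propagate(preds[[nsTag]], graphs[[nsTag]], mode = propMode)
        .log("  ", nsTag, ": ", nTargets(p), "/", nTargets(gt[[nsTag]]),
             " targets with predictions")
        sweepThresholds(gt[[nsTag]], p, graphs[[nsTag]],
                        weights = weights[[nsTag]],
                        thresholds = thresholds,
                        averaging = averaging, norm = norm,
                        excludeRoots = excludeRoots,
                        nBlocks = nBlocks, workers = workers)
      })
      do.call(rbind, nsRows)
    }, error = function(e) {
      .log("  ERROR, file skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(rows)) {
      skipped <- c(skipped, pf)
      next
    }
    tables[[basename(pf)]] <- cbind(filename = basename(pf), rows)
  }
  if (length(tables) == 0L)
    stop("no prediction file could be evaluated")

  table <- do.call(rbind, tables[sort(names(tables))])
  rownames(table) <- NULL
  best <- bestScores(table)
  if (!is.null(teamMapFile))
    best <- dedupeTeams(best, readTeamMap(teamMapFile))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTsv(table, file.path(outDir, "evaluation_all.tsv"), overwrite)
    .writeTsv(best$fmax, file.path(outDir, "fmax.tsv"), overwrite)
    if (!is.null(best$smin)) {
      .writeTsv(best$smin, file.path(outDir, "smin.tsv"), overwrite)
      .writeTsv(best$wfmax, file.path(outDir, "wfmax.tsv"), overwrite)
    }
    .log("outputs written to ", outDir)
  }
  invisible(list(table = table, best = best, skipped = skipped))
}

.log <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
}

.writeTsv <- function(df, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep one prediction per team in the best-score tables
#'
#' Per (team, namespace), retains the file achieving the best value of
#' each table's own ranking metric: highest \code{f} for the Fmax table,
#' lowest \code{s} for Smin, highest \code{wf} for wFmax (ties broken by
#' filename for reproducibility). Files without a team-map entry form
#' singleton teams and are always retained. Display names from the map
#' are attached as a \code{display} column.
#'
#' @param best list of best-score tables from \code{\link{bestScores}}.
#' @param teamMap data.frame from \code{\link{readTeamMap}}.
#' @return The list of tables, filtered and with \code{team} and
#'   \code{display} columns.
#' @export
dedupeTeams <- function(best, teamMap) {
  stopifnot(is.list(best), is.data.frame(teamMap))
  if (anyDuplicated(teamMap$filename))
    stop("team map: duplicate filename")
  metricFor <- c(fmax = "f", smin = "s", wfmax = "wf")
  decreasingFor <- c(fmax = TRUE, smin = FALSE, wfmax = TRUE)
  out <- lapply(names(best), function(tab) {
    d <- best[[tab]]
    hit <- match(d$filename, teamMap$filename)
    d$team <- ifelse(is.na(hit), d$filename, teamMap$team[hit])
    d$display <- ifelse(is.na(hit), d$filename, teamMap$display[hit])
    metric <- metricFor[[tab]]
    keep <- unlist(lapply(
      split(seq_len(nrow(d)), list(d$team, d$ns), drop = TRUE),
      function(ix) {
        v <- d[[metric]][ix]
        best <- if (decreasingFor[[tab]]) max(v) else min(v)
        cand <- ix[v == best]
        cand[order(d$filename[cand])][1]
      }))
    res <- d[sort(keep), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  names(out) <- names(best)
  out
}
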