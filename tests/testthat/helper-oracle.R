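# Randomized engine-vs-oracle comparison used by the property and
# acceptance tests. Builds a small synthetic benchmark on disk, runs the
# full parsing/propagation/sweep pipeline, runs the independent set-based
# reference evaluator on the same raw tables, and returns the largest
# absolute metric deviation.

randomCase <- function(seed, maxTermCount = 30L, maxTargetCount = 10L) {
  set.seed(seed)
  nTerms <- sample(5:maxTermCount, 1)
  nTargets <- sample(2:maxTargetCount, 1)
  edgeProb <- runif(1, 0, 0.5)
  quality <- runif(1)
  noise <- runif(1, 0, 0.25)

  dir <- tempfile("case")
  dir.create(dir)
  obo <- file.path(dir, "ontology.obo")
  writeLines(genOntology(nTerms, 1L, edgeProb, seed = seed), obo)
  graph <- readOBO(obo)[[1]]

  ann <- genAnnotations(graph, nTargets, termsPerTarget = sample(1:3, 1),
                        seed = seed + 1L)
  pred <- genPredictions(graph, ann, quality, noise, seed = seed + 2L)

  set.seed(seed + 3L)
  ia <- data.frame(term = termIds(graph),
                   w = round(runif(nTerms(graph), 0, 4), 4))
  gtFile <- file.path(dir, "gt.tsv")
  predFile <- file.path(dir, "pred.tsv")
  iaFile <- file.path(dir, "ia.tsv")
  writeLines(paste(ann$target, ann$term, sep = "\t"), gtFile)
  writeLines(paste(pred$target, pred$term, pred$score, sep = "\t"),
             predFile)
  writeLines(paste(ia$term, ia$w, sep = "\t"), iaFile)
  list(dir = dir, obo = obo, gt = gtFile, pred = predFile, ia = iaFile,
       graph = graph, ann = ann, predDf = pred, iaDf = ia)
}

engineRecords <- function(case, thresholds, averaging, norm, propMode,
                          excludeRoots, useIA, maxTerms = NULL) {
  graphs <- readOBO(case$obo)
  gt <- readGroundTruth(case$gt, graphs)[[1]]
  gt <- propagate(gt, graphs[[1]])
  pred <- readPredictions(case$pred, graphs,
                          stats::setNames(list(gt), ontNamespace(gt)),
                          maxTerms = maxTerms)[[1]]
  pred <- propagate(pred, graphs[[1]], mode = propMode)
  weights <- if (useIA) readIA(case$ia, graphs[[1]]) else NULL
  sweepThresholds(gt, pred, graphs[[1]], weights = weights,
                  thresholds = thresholds, averaging = averaging,
                  norm = norm, excludeRoots = excludeRoots)
}

oracleRecords <- function(case, thresholds, averaging, norm, propMode,
                          excludeRoots, useIA, maxTerms = NULL) {
  gtDf <- read.delim(case$gt, header = FALSE,
                     col.names = c("target", "term"))
  predDf <- read.delim(case$pred, header = FALSE,
                       col.names = c("target", "term", "score"),
                       colClasses = c("character", "character", "numeric"))
  ia <- NULL
  if (useIA) {
    iaDf <- read.delim(case$ia, header = FALSE)
    ia <- stats::setNames(iaDf[[2]], iaDf[[1]])
  }
  oracleEvaluate(gtDf, predDf, case$graph, thresholds = thresholds,
                 averaging = averaging, norm = norm,
                 excludeRoots = excludeRoots, ia = ia,
                 propMode = propMode, maxTerms = maxTerms)
}

# largest absolute deviation between engine and oracle over all metrics
engineOracleGap <- function(seed, averaging, norm, propMode, excludeRoots,
                            useIA, thresholds = seq(0, 0.99, length.out = 11),
                            maxTerms = NULL) {
  case <- randomCase(seed)
  on.exit(unlink(case$dir, recursive = TRUE))
  e <- suppressWarnings(engineRecords(case, thresholds, averaging, norm,
                                      propMode, excludeRoots, useIA,
                                      maxTerms))
  o <- oracleRecords(case, thresholds, averaging, norm, propMode,
                     excludeRoots, useIA, maxTerms)
  cols <- intersect(c("cov", "pr", "rc", "f", "wpr", "wrc", "wf",
                      "ru", "mi", "s"), names(e))
  stopifnot(nrow(e) == nrow(o), all(cols %in% names(o)),
            identical(e$n, o$n))
  max(abs(as.matrix(e[, cols]) - as.matrix(o[, cols])))
}

optionGrid <- function() {
  expand.grid(averaging = c("macro", "micro"),
              norm = c("cafa", "full"),
              propMode = c("fill", "max"),
              excludeRoots = c(FALSE, TRUE),
              useIA = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}
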