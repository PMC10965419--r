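benchmark <- function(dir = tempfile("bench"), qualities = c(m1 = 0.85,
                                                             m2 = 0.45),
                      seed = 11L, ...) {
  genBenchmark(dir, nTerms = 15L, nNamespaces = 2L, nTargets = 8L,
               qualities = qualities, seed = seed, ...)
}

quietRun <- function(...) suppressMessages(runEvaluation(...))

test_that("a full run yields one row per file, namespace and threshold", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  res <- quietRun(p$obo, p$predDir, p$gt)
  expect_identical(nrow(res$table), 2L * 2L * 100L)
  expect_identical(sort(unique(res$table$filename)),
                   c("m1.tsv", "m2.tsv"))
  expect_identical(sort(unique(res$table$ns)), c("ns1", "ns2"))
  # without IA: no weighted columns, no Smin/wFmax tables
  expect_null(res$table$s)
  expect_null(res$best$smin)
  expect_identical(nrow(res$best$fmax), 4L)
})

test_that("information accretion enables weighted columns and tables", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  res <- quietRun(p$obo, p$predDir, p$gt, iaFile = p$ia)
  expect_true(all(c("wpr", "wrc", "wf", "ru", "mi", "s") %in%
                    names(res$table)))
  expect_identical(names(res$best), c("fmax", "smin", "wfmax"))
})

test_that("an empty prediction directory is fatal", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  empty <- tempfile("nopreds")
  dir.create(empty)
  expect_error(quietRun(p$obo, empty, p$gt), "no prediction files")
})

test_that("an unparsable prediction file is skipped and the run continues", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  junk <- file.path(p$predDir, "broken.tsv")
  writeLines(c("no", "usable\tcontent"), junk)
  dir.create(file.path(p$predDir, "unreadable.tsv"))  # readLines will fail
  res <- suppressWarnings(quietRun(p$obo, p$predDir, p$gt))
  # an all-junk file still evaluates as an empty (all-zero) prediction
  expect_true("broken.tsv" %in% res$table$filename)
  expect_equal(max(res$table$f[res$table$filename == "broken.tsv"]), 0)
  # a genuinely unreadable entry is skipped and the run continues
  expect_match(res$skipped, "unreadable", all = FALSE)
  expect_true(all(c("m1.tsv", "m2.tsv") %in% res$table$filename))
})

test_that("outputs are written once and protected against overwriting", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  out <- file.path(dirname(p$obo), "out")
  quietRun(p$obo, p$predDir, p$gt, iaFile = p$ia, outDir = out)
  expect_true(all(file.exists(file.path(
    out, c("evaluation_all.tsv", "fmax.tsv", "smin.tsv", "wfmax.tsv")))))
  expect_error(quietRun(p$obo, p$predDir, p$gt, iaFile = p$ia,
                        outDir = out),
               "exists")
  expect_silent(suppressMessages(
    runEvaluation(p$obo, p$predDir, p$gt, iaFile = p$ia, outDir = out,
                  overwrite = TRUE)))
})

test_that("two identical runs write byte-identical tables", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  out1 <- file.path(dirname(p$obo), "out1")
  out2 <- file.path(dirname(p$obo), "out2")
  quietRun(p$obo, p$predDir, p$gt, iaFile = p$ia, outDir = out1)
  quietRun(p$obo, p$predDir, p$gt, iaFile = p$ia, outDir = out2)
  for (f in c("evaluation_all.tsv", "fmax.tsv", "smin.tsv", "wfmax.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("results do not depend on prediction file order or block count", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  r1 <- quietRun(p$obo, p$pred, p$gt, iaFile = p$ia)
  r2 <- quietRun(p$obo, rev(p$pred), p$gt, iaFile = p$ia)
  r3 <- quietRun(p$obo, p$pred, p$gt, iaFile = p$ia, nBlocks = 5L)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$table, r3$table)
})

test_that("team deduplication keeps each table's best file per team and namespace", {
  best <- list(
    fmax = data.frame(filename = c("f1.tsv", "f2.tsv", "f3.tsv"),
                      ns = "ns1", tau = 0.5, n = 5, cov = 1,
                      pr = 1, rc = 1, f = c(0.7, 0.8, 0.6)),
    smin = data.frame(filename = c("f1.tsv", "f2.tsv", "f3.tsv"),
                      ns = "ns1", tau = 0.5, n = 5, cov = 1,
                      pr = 1, rc = 1, f = 0.5,
                      ru = 1, mi = 1, s = c(1.1, 2.0, 0.4)),
    wfmax = data.frame(filename = c("f1.tsv", "f2.tsv", "f3.tsv"),
                       ns = "ns1", tau = 0.5, n = 5, cov = 1,
                       pr = 1, rc = 1, wf = c(0.4, 0.5, 0.6)))
  tm <- data.frame(filename = c("f1.tsv", "f2.tsv"),
                   team = "alpha", display = c("Alpha 1", "Alpha 2"))
  d <- dedupeTeams(best, tm)
  # fmax: within team alpha f2 wins; unmapped f3 is its own team
  expect_setequal(d$fmax$filename, c("f2.tsv", "f3.tsv"))
  expect_identical(d$fmax$display[d$fmax$filename == "f2.tsv"], "Alpha 2")
  # smin ranks by lowest s: f1 wins within the team
  expect_setequal(d$smin$filename, c("f1.tsv", "f3.tsv"))
  # wfmax ranks by its own metric
  expect_setequal(d$wfmax$filename, c("f2.tsv", "f3.tsv"))
  expect_error(dedupeTeams(best, rbind(tm, tm[1, ])), "duplicate")
})

test_that("the grouping bound holds: at most teams x namespaces rows remain", {
  p <- benchmark()
  on.exit(unlink(dirname(p$obo), recursive = TRUE))
  tmFile <- file.path(dirname(p$obo), "teams.tsv")
  writeLines(c("m1.tsv\tteamA\tMethod One", "m2.tsv\tteamA\tMethod Two"),
             tmFile)
  res <- quietRun(p$obo, p$predDir, p$gt, teamMapFile = tmFile)
  expect_lte(nrow(res$best$fmax), 1L * 2L)  # one team, two namespaces
  expect_true(all(res$best$fmax$team == "teamA"))
})
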