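test_that("precision/recall/F handle perfect, empty and mixed confusions", {
  expect_equal(prRcF(3, 0, 0), data.frame(pr = 1, rc = 1, f = 1))
  expect_equal(prRcF(0, 0, 5), data.frame(pr = 0, rc = 0, f = 0))
  expect_equal(prRcF(2, 1, 1), data.frame(pr = 2/3, rc = 2/3, f = 2/3))
  expect_equal(prRcF(0, 0, 0), data.frame(pr = 0, rc = 0, f = 0))
})

test_that("semantic distance combines ru and mi euclideanly", {
  expect_equal(ruMiS(0, 0)$s, 0)
  expect_equal(ruMiS(3, 4), data.frame(ru = 3, mi = 4, s = 5))
  expect_equal(ruMiS(5, 0)$s, 5)
})

# diamond with T = {A,B,D}, P = {A,B,C}: the worked confusion example
diamondVectors <- function() {
  g <- parseOBOText(diamondOBO())$default
  truth <- setNames(c(TRUE, TRUE, FALSE, TRUE), termIds(g))
  scores <- setNames(c(0.9, 0.8, 0.7, 0), termIds(g))
  list(g = g, truth = truth, scores = scores)
}

test_that("per-target confusion counts follow direct set arithmetic", {
  d <- diamondVectors()
  perfect <- confusionCounts(d$truth, ifelse(d$truth, 0.9, 0), tau = 0.5)
  expect_equal(c(perfect$tp, perfect$fp, perfect$fn), c(3, 0, 0))
  expect_true(perfect$predicted)

  c1 <- confusionCounts(d$truth, d$scores, tau = 0.5)
  expect_equal(c(c1$tp, c1$fp, c1$fn), c(2, 1, 1))
})

test_that("weighted confusion sums information accretion over the same sets", {
  d <- diamondVectors()
  ia <- setNames(c(0, 1, 4, 3), termIds(d$g))
  cw <- confusionCounts(d$truth, d$scores, tau = 0.5, weights = ia)
  expect_equal(c(cw$tpW, cw$fpW, cw$fnW), c(1, 4, 3))
  sm <- ruMiS(cw$fnW, cw$fpW)
  expect_equal(c(sm$ru, sm$mi, sm$s), c(3, 4, 5))
})

test_that("root exclusion removes roots from both sets and from coverage", {
  d <- diamondVectors()
  rootOnly <- setNames(c(0.9, 0, 0, 0), termIds(d$g))
  cc <- confusionCounts(d$truth, rootOnly, tau = 0.1,
                        excludeRoots = TRUE, roots = rootTerms(d$g))
  expect_false(cc$predicted)
  expect_equal(cc$tp, 0)
  expect_equal(cc$fn, 2)  # B and D remain in the truth set
})

test_that("macro aggregation averages per-target metrics under both norms", {
  # two targets: (pr, rc) = (1, 1) and (0.5, 0.5), both predicted
  conf <- list(tp = c(2, 1), fp = c(0, 1), fn = c(0, 1),
               predicted = c(TRUE, TRUE))
  r <- aggregateConfusion(conf, "macro", "cafa")
  expect_equal(c(r$pr, r$rc), c(0.75, 0.75))

  # target 2 unpredicted: cafa averages pr over 1 target, rc over 2
  conf2 <- list(tp = c(2, 0), fp = c(0, 0), fn = c(0, 2),
                predicted = c(TRUE, FALSE))
  r2 <- aggregateConfusion(conf2, "macro", "cafa")
  expect_equal(r2$pr, 1)
  expect_equal(r2$rc, 0.5)
  expect_equal(r2$cov, 0.5)
  r2full <- aggregateConfusion(conf2, "macro", "full")
  expect_equal(r2full$pr, 0.5)

  # nothing predicted at all: everything defined, all zero
  conf3 <- list(tp = c(0, 0), fp = c(0, 0), fn = c(1, 2),
                predicted = c(FALSE, FALSE))
  r3 <- aggregateConfusion(conf3, "macro", "cafa")
  expect_equal(c(r3$pr, r3$rc, r3$f, r3$cov), c(0, 0, 0, 0))
})

test_that("micro aggregation equals metrics of summed confusions and macro at n = 1", {
  conf <- list(tp = c(2, 1), fp = c(0, 1), fn = c(0, 1),
               predicted = c(TRUE, TRUE))
  r <- aggregateConfusion(conf, "micro", "cafa")
  expect_equal(r$pr, 3 / 4)
  expect_equal(r$rc, 3 / 4)

  one <- list(tp = 2, fp = 1, fn = 1, predicted = TRUE,
              tpW = 1.5, fpW = 0.5, fnW = 2)
  expect_equal(aggregateConfusion(one, "macro", "cafa"),
               aggregateConfusion(one, "micro", "cafa"))
})

sweepFixture <- function(predLines, iaLines = NULL, ...) {
  graphs <- parseOBOText(diamondOBO())
  gt <- readGroundTruth(text = c(tsv("t1", "D"), tsv("t2", "B")),
                        graphs = graphs)
  gtp <- propagate(gt$default, graphs$default)
  pred <- readPredictions(text = predLines, graphs = graphs,
                          groundTruth = gt)$default
  predp <- propagate(pred, graphs$default)
  w <- if (!is.null(iaLines)) readIA(text = iaLines, graph = graphs$default)
  sweepThresholds(gtp, predp, graphs$default, weights = w, ...)
}

test_that("the default grid produces 100 records at tau = 0.00 .. 0.99", {
  recs <- sweepFixture(tsv("t1", "D", "0.8"))
  expect_identical(nrow(recs), 100L)
  expect_equal(recs$tau, seq(0, 0.99, by = 0.01))
  expect_false(is.unsorted(recs$tau))
  expect_error(sweepFixture(tsv("t1", "D", "0.8"), thresholds = numeric()),
               "empty threshold grid")
})

test_that("coverage at tau = 0 is the fraction of targets with any prediction", {
  recs <- sweepFixture(tsv("t1", "D", "0.8"), thresholds = 0)
  expect_equal(recs$cov, 0.5)  # t2 has no predictions
})

test_that("threshold blocks and workers leave the records bit-identical", {
  base <- sweepFixture(c(tsv("t1", "D", "0.8"), tsv("t2", "B", "0.4")))
  for (nb in c(2L, 7L))
    expect_identical(sweepFixture(c(tsv("t1", "D", "0.8"),
                                    tsv("t2", "B", "0.4")),
                                  nBlocks = nb), base)
  expect_identical(sweepFixture(c(tsv("t1", "D", "0.8"),
                                  tsv("t2", "B", "0.4")),
                                nBlocks = 3L, workers = 2L), base)
})

test_that("recall and coverage are monotone non-increasing in the threshold", {
  for (seed in 41:46) {
    case <- randomCase(seed)
    on.exit(unlink(case$dir, recursive = TRUE), add = TRUE)
    recs <- engineRecords(case, thresholds = seq(0, 0.99, length.out = 25),
                          averaging = "macro", norm = "cafa",
                          propMode = "fill", excludeRoots = FALSE,
                          useIA = TRUE)
    expect_true(all(diff(recs$rc) <= 1e-12))
    expect_true(all(diff(recs$cov) <= 1e-12))
    expect_true(all(recs$f >= 0 & recs$f <= 1))
    expect_true(all(recs$s >= pmax(recs$ru, recs$mi) - 1e-12))
    expect_true(all(recs$s <= recs$ru + recs$mi + 1e-12))
  }
})

test_that("unit information accretion reduces weighted metrics to unweighted", {
  graphs <- parseOBOText(diamondOBO())
  gt <- readGroundTruth(text = c(tsv("t1", "D"), tsv("t2", "B")),
                        graphs = graphs)
  gtp <- propagate(gt$default, graphs$default)
  pred <- propagate(readPredictions(
    text = c(tsv("t1", "D", "0.8"), tsv("t1", "C", "0.4"),
             tsv("t2", "A", "0.6")),
    graphs = graphs, groundTruth = gt)$default, graphs$default)
  ones <- setNames(rep(1, 4), termIds(graphs$default))
  recs <- sweepThresholds(gtp, pred, graphs$default, weights = ones)
  expect_equal(recs$wpr, recs$pr)
  expect_equal(recs$wrc, recs$rc)
  expect_equal(recs$wf, recs$f)
  # with unit weights ru / mi are the per-target-averaged fn / fp counts
  conf0 <- confusionCounts(annotationMatrix(gtp),
                           ontoeval:::.alignScores(pred, targetIds(gtp), 4L),
                           tau = 0.5, weights = ones)
  expect_equal(recs$ru[recs$tau == 0.5], mean(conf0$fn))
  expect_equal(recs$mi[recs$tau == 0.5], mean(conf0$fp))
})

test_that("best-score extraction maximizes F, minimizes S, ties to lowest tau", {
  recs <- data.frame(filename = "m", ns = "x",
                     tau = c(0, 0.5, 0.9), n = 2, cov = 1,
                     pr = 0, rc = 0, f = c(0.2, 0.9, 0.4),
                     wpr = 0, wrc = 0, wf = c(0.1, 0.2, 0.2),
                     ru = 0, mi = 0, s = c(5, 3, 4))
  b <- bestScores(recs)
  expect_equal(b$fmax$f, 0.9)
  expect_equal(b$fmax$tau, 0.5)
  expect_equal(b$smin$s, 3)
  expect_equal(b$smin$tau, 0.5)
  expect_equal(b$wfmax$tau, 0.5)  # tie 0.2 at 0.5 and 0.9: lowest tau wins

  const <- transform(recs, f = 0.5)
  expect_equal(bestScores(const)$fmax$tau, 0)
})
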