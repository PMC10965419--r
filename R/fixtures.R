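## Synthetic benchmark generators. These produce real OBO/TSV files so the
## public parsers sit inside every test loop; with a fixed seed the emitted
## text is byte-identical across runs.

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic ontology as OBO text
#'
#' Builds one or more namespaces of \code{nTerms} terms each. Within a
#' namespace, term j > 1 receives one parent drawn uniformly from the
#' earlier terms (so the graph is acyclic by construction and term 1 is a
#' root) plus each earlier term as an extra parent with probability
#' \code{edgeProb / j}. Term ids sort in generation order, so the
#' lexicographic term index matches construction order.
#'
#' @param nTerms terms per namespace (>= 1).
#' @param nNamespaces number of independent namespaces.
#' @param edgeProb controls the density of extra (multi-parent) edges.
#' @param seed integer seed; identical seed and arguments give
#'   byte-identical output.
#' @return Character vector of OBO lines (parseable by
#'   \code{\link{readOBO}}).
#' @export
genOntology <- function(nTerms, nNamespaces = 1L, edgeProb = 0.3,
                        seed = NULL) {
  stopifnot(nTerms >= 1L, nNamespaces >= 1L, edgeProb >= 0, edgeProb <= 1)
  .withSeed(seed, {
    lines <- c("format-version: 1.2", "ontology: synthetic")
    for (k in seq_len(nNamespaces)) {
      nsTag <- sprintf("ns%d", k)
      ids <- sprintf("S%d:%04d", k, seq_len(nTerms))
      for (j in seq_len(nTerms)) {
        parents <- character()
        if (j > 1L) {
          parents <- ids[sample.int(j - 1L, 1L)]
          if (j > 2L) {
            extra <- which(stats::runif(j - 1L) < edgeProb / j)
            parents <- unique(c(parents, ids[extra]))
          }
        }
        isa <- if (length(parents)) paste0("is_a: ", sort(parents))
               else character()
        lines <- c(lines, "", "[Term]",
                   paste0("id: ", ids[j]),
                   paste0("name: synthetic term ", j),
                   paste0("namespace: ", nsTag),
                   isa)
      }
    }
    lines
  })
}

#' Generate direct ground-truth annotations for a synthetic ontology
#'
#' Each target receives \code{termsPerTarget} distinct terms, sampled with
#' a leaf bias (childless terms are three times as likely as internal
#' ones) so that propagation has depth to work with.
#'
#' @param graph an \linkS4class{OntologyDAG}.
#' @param nTargets number of targets.
#' @param termsPerTarget direct annotations per target (capped at the
#'   number of terms).
#' @param seed integer seed.
#' @return data.frame with columns \code{target}, \code{term} (direct,
#'   unpropagated pairs).
#' @export
genAnnotations <- function(graph, nTargets, termsPerTarget = 2L,
                           seed = NULL) {
  stopifnot(nTargets >= 1L, termsPerTarget >= 1L)
  .withSeed(seed, {
    m <- nTerms(graph)
    k <- min(termsPerTarget, m)
    wt <- ifelse(lengths(graph@children) == 0L, 3, 1)
    targets <- sprintf("prot_%s_%03d", ontNamespace(graph),
                       seq_len(nTargets))
    do.call(rbind, lapply(targets, function(tg) {
      data.frame(target = tg,
                 term = termIds(graph)[sample.int(m, k, prob = wt)],
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate prediction scores of controllable quality
#'
#' Emulates a predictor of tunable skill against the propagated truth.
#' Every term in a target's ancestor closure is scored from a high mode
#' (near 1) with probability \code{quality} and from a low mode (near
#' 0.3) otherwise; terms outside the closure are predicted with
#' probability \code{0.15 * (1 - quality)}, from the low mode. The
#' \code{noise} scale spreads both modes. At \code{quality = 1},
#' \code{noise = 0} the prediction is exactly the propagated truth with
#' score 1 everywhere — the perfect predictor.
#'
#' @param graph an \linkS4class{OntologyDAG}.
#' @param annotations data.frame from \code{\link{genAnnotations}}.
#' @param quality probability in [0, 1] that a true term is scored from
#'   the high mode.
#' @param noise non-negative spread of the score distributions.
#' @param seed integer seed.
#' @return data.frame with columns \code{target}, \code{term},
#'   \code{score}.
#' @export
genPredictions <- function(graph, annotations, quality, noise = 0.1,
                           seed = NULL) {
  stopifnot(quality >= 0, quality <= 1, noise >= 0)
  .withSeed(seed, {
    closure <- .ancestorClosureSets(graph)
    ids <- termIds(graph)
    rows <- lapply(split(annotations$term, annotations$target), function(tt) {
      true <- unique(unlist(closure[tt]))
      false <- setdiff(ids, true)
      high <- stats::runif(length(true)) < quality
      sTrue <- ifelse(high,
                      pmin(1, pmax(0.001, 1 - abs(stats::rnorm(length(true))) * noise)),
                      pmin(1, pmax(0.001, 0.3 + stats::rnorm(length(true)) * noise)))
      hit <- stats::runif(length(false)) < 0.15 * (1 - quality)
      sFalse <- pmin(1, pmax(0.001,
                             0.3 + stats::rnorm(sum(hit)) * noise))
      data.frame(term = c(true, false[hit]),
                 score = round(c(sTrue, sFalse), 6),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Map(cbind.data.frame,
                              target = names(rows), rows))
    rownames(out) <- NULL
    out[out$score > 0, , drop = FALSE]
  })
}

## Ancestor-or-self id sets for every term, by simple recursion (small
## graphs only; fixtures are tiny by design).
.ancestorClosureSets <- function(graph) {
  ids <- termIds(graph)
  memo <- vector("list", length(ids))
  anc <- function(i) {
    if (!is.null(memo[[i]])) return(memo[[i]])
    res <- i
    for (p in graph@parents[[i]]) res <- union(res, anc(p))
    memo[[i]] <<- res
    res
  }
  stats::setNames(lapply(seq_along(ids), function(i) ids[anc(i)]), ids)
}

#' Write a complete synthetic benchmark to disk
#'
#' Emits \code{ontology.obo}, \code{gt.tsv}, \code{ia.tsv} and one
#' prediction file per entry of \code{qualities} under
#' \code{pred/}, all as plain text, then re-reads nothing: the files are
#' meant to be consumed through the public parsers. Information-accretion
#' weights are drawn uniformly on [0, 5] per term.
#'
#' @param outDir output directory (created if absent).
#' @param nTerms,nNamespaces,edgeProb see \code{\link{genOntology}}.
#' @param nTargets,termsPerTarget see \code{\link{genAnnotations}}.
#' @param qualities named numeric vector; one prediction file
#'   \code{pred/<name>.tsv} per entry.
#' @param noise see \code{\link{genPredictions}}.
#' @param seed master seed; all per-file seeds derive from it.
#' @return Named list of paths: \code{obo}, \code{gt}, \code{ia},
#'   \code{predDir}, \code{pred} (vector).
#' @export
genBenchmark <- function(outDir, nTerms = 25L, nNamespaces = 2L,
                         edgeProb = 0.3, nTargets = 20L,
                         termsPerTarget = 3L,
                         qualities = c(good = 0.9, fair = 0.6, poor = 0.3),
                         noise = 0.1, seed = 1L) {
  stopifnot(length(qualities) >= 1L, !is.null(names(qualities)))
  dir.create(file.path(outDir, "pred"), recursive = TRUE,
             showWarnings = FALSE)
  obo <- file.path(outDir, "ontology.obo")
  writeLines(genOntology(nTerms, nNamespaces, edgeProb, seed = seed), obo)
  graphs <- suppressWarnings(readOBO(obo))

  ann <- do.call(rbind, lapply(seq_along(graphs), function(k)
    genAnnotations(graphs[[k]], nTargets, termsPerTarget,
                   seed = seed + 1000L + k)))
  gt <- file.path(outDir, "gt.tsv")
  writeLines(paste(ann$target, ann$term, sep = "\t"), gt)

  ia <- file.path(outDir, "ia.tsv")
  iaw <- .withSeed(seed + 2000L, {
    ids <- unlist(lapply(graphs, termIds), use.names = FALSE)
    data.frame(term = ids, w = round(stats::runif(length(ids), 0, 5), 4))
  })
  writeLines(paste(iaw$term, iaw$w, sep = "\t"), ia)

  pred <- character()
  for (q in seq_along(qualities)) {
    rows <- do.call(rbind, lapply(seq_along(graphs), function(k) {
      a <- ann[grepl(paste0("_", ontNamespace(graphs[[k]]), "_"),
                     ann$target), , drop = FALSE]
      genPredictions(graphs[[k]], a, qualities[[q]], noise,
                     seed = seed + 3000L + 100L * q + k)
    }))
    path <- file.path(outDir, "pred",
                      paste0(names(qualities)[q], ".tsv"))
    writeLines(paste(rows$target, rows$term, rows$score, sep = "\t"), path)
    pred <- c(pred, path)
  }
  list(obo = obo, gt = gt, ia = ia,
       predDir = file.path(outDir, "pred"), pred = pred)
}
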