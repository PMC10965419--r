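#' Parse an OBO ontology into per-namespace DAGs
#'
#' Reads a flat-file OBO document and builds one \linkS4class{OntologyDAG}
#' per namespace. Hierarchical edges are taken from \code{is_a} keys and,
#' optionally, from \code{relationship: part_of} lines. Obsolete terms are
#' excluded together with their edges; \code{alt_id} accessions are recorded
#' so annotations using secondary ids resolve to the canonical term. Edges
#' whose endpoints lie in different namespaces, or whose parent is not a
#' (non-obsolete) term of the document, are dropped with a warning.
#'
#' Each namespace is treated as an independent ontology: terms are indexed
#' 1..m in lexicographic id order, a children-first topological order is
#' computed with Kahn's algorithm (ties broken by term index, so the result
#' is reproducible byte for byte) and the root set (terms without parents)
#' is recorded. A cyclic hierarchy is a fatal error naming one cycle member.
#'
#' @param file path to an OBO file.
#' @param text alternatively, the OBO document as a character vector of
#'   lines (overrides \code{file}).
#' @param includePartOf logical; also use \code{relationship: part_of}
#'   lines as hierarchical edges (default \code{FALSE}: \code{is_a} only).
#' @return A named list of \linkS4class{OntologyDAG}, one per namespace.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: T:1", "name: root", "",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1 ! root")
#' graphs <- readOBO(text = obo)
#' termIds(graphs$default)
#' @export
readOBO <- function(file = NULL, text = NULL, includePartOf = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    text <- readLines(file, warn = FALSE)
  }
  stanzas <- .oboStanzas(text)
  terms <- lapply(stanzas, .oboTerm, includePartOf = includePartOf)
  terms <- terms[!vapply(terms, is.null, logical(1))]
  if (length(terms) == 0L)
    stop("empty ontology: no usable [Term] stanzas found")

  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids[!obsolete]))
    stop("duplicated term id: ", ids[!obsolete][duplicated(ids[!obsolete])][1])
  terms <- terms[!obsolete]
  ids <- ids[!obsolete]
  if (length(terms) == 0L)
    stop("empty ontology: all terms are obsolete")

  ns <- vapply(terms, `[[`, character(1), "namespace")
  nsOf <- stats::setNames(ns, ids)

  alt <- unlist(lapply(terms, function(tr)
    stats::setNames(rep(tr$id, length(tr$altIds)), tr$altIds)))
  if (is.null(alt)) alt <- character()
  alt <- alt[!names(alt) %in% ids]  # a primary id shadows any alt_id use

  crossNs <- 0L
  unknownParent <- 0L
  graphs <- lapply(sort(unique(ns)), function(nsTag) {
    sel <- which(ns == nsTag)
    tid <- sort(ids[sel])
    idx <- stats::setNames(seq_along(tid), tid)
    byId <- terms[sel][match(tid, ids[sel])]
    parents <- vector("list", length(tid))
    for (i in seq_along(tid)) {
      p <- byId[[i]]$parents
      if (length(p) == 0L) {
        parents[[i]] <- integer()
        next
      }
      hit <- !is.na(match(p, names(alt)))
      p[hit] <- alt[p[hit]]
      known <- p %in% ids
      unknownParent <<- unknownParent + sum(!known)
      p <- p[known]
      sameNs <- nsOf[p] == nsTag
      crossNs <<- crossNs + sum(!sameNs)
      parents[[i]] <- sort(unique(unname(idx[p[sameNs]])))
    }
    children <- .invertParents(parents)
    topo <- .kahnOrder(parents, children, tid)
    methods::new("OntologyDAG",
      namespace = nsTag,
      terms     = tid,
      termNames = vapply(byId, `[[`, character(1), "name"),
      parents   = parents,
      children  = children,
      topoOrder = topo,
      roots     = which(lengths(parents) == 0L),
      altIds    = alt[nsOf[alt] == nsTag]
    )
  })
  names(graphs) <- vapply(graphs, ontNamespace, character(1))
  if (crossNs > 0L)
    warning(crossNs, " cross-namespace edge(s) dropped")
  if (unknownParent > 0L)
    warning(unknownParent,
            " edge(s) to unknown or obsolete parent term(s) dropped")
  graphs
}

## Split OBO lines into stanzas: list(header = "[Term]", lines = <body>).
.oboStanzas <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  hdr <- grep("^\\[[^]]+\\]$", lines)
  if (length(hdr) == 0L) return(list())
  ends <- c(hdr[-1] - 1L, length(lines))
  mapply(function(h, e) {
    body <- if (h + 1L <= e) lines[(h + 1L):e] else character()
    list(header = lines[h], lines = body[nzchar(body)])
  }, hdr, ends, SIMPLIFY = FALSE)
}

## Parse one stanza into a term record; NULL for non-Term stanzas or
## stanzas without an id.
.oboTerm <- function(stanza, includePartOf = FALSE) {
  if (!identical(stanza$header, "[Term]")) return(NULL)
  kv <- regmatches(stanza$lines,
                   regexec("^([A-Za-z_]+):\\s*(.*)$", stanza$lines))
  keys <- vapply(kv, function(x) if (length(x) == 3L) x[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(x) if (length(x) == 3L) x[3] else NA_character_,
                 character(1))
  getAll <- function(k) vals[!is.na(keys) & keys == k]
  get1 <- function(k, default = NA_character_) {
    v <- getAll(k)
    if (length(v)) v[1] else default
  }
  id <- .stripOboComment(get1("id"))
  if (is.na(id) || !nzchar(id)) return(NULL)
  parents <- vapply(getAll("is_a"), .stripOboComment, character(1),
                    USE.NAMES = FALSE)
  parents <- parents[nzchar(parents)]
  if (includePartOf) {
    rel <- vapply(getAll("relationship"), .stripOboComment, character(1),
                  USE.NAMES = FALSE)
    po <- regmatches(rel, regexec("^part_of\\s+(\\S+)$", rel))
    parents <- c(parents,
                 vapply(po[lengths(po) == 2L], `[[`, character(1), 2L))
  }
  list(
    id        = id,
    name      = get1("name", ""),
    namespace = .stripOboComment(get1("namespace", "default")),
    parents   = unique(parents),
    altIds    = unique(vapply(getAll("alt_id"), .stripOboComment,
                              character(1), USE.NAMES = FALSE)),
    obsolete  = identical(tolower(.stripOboComment(get1("is_obsolete",
                                                        "false"))), "true")
  )
}

.stripOboComment <- function(x) {
  if (is.na(x)) return(x)
  trimws(sub("\\s*!.*$", "", x))
}

.invertParents <- function(parents) {
  m <- length(parents)
  children <- vector("list", m)
  for (i in seq_len(m)) children[[i]] <- integer()
  for (i in seq_len(m)) {
    for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)
  }
  lapply(children, sort)
}

## Children-first topological order (Kahn). Edges run child -> parent, so
## the frontier starts at the leaves and roots come out last. Ties are
## broken by smallest term index via a binary min-heap, which makes the
## order a pure function of the graph.
.kahnOrder <- function(parents, children, termIdsVec) {
  m <- length(parents)
  remaining <- lengths(children)
  heap <- .heapNew(m)
  for (i in which(remaining == 0L)) heap <- .heapPush(heap, i)
  order <- integer(m)
  k <- 0L
  while (heap$n > 0L) {
    res <- .heapPop(heap)
    heap <- res$heap
    i <- res$value
    k <- k + 1L
    order[k] <- i
    for (p in parents[[i]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) heap <- .heapPush(heap, p)
    }
  }
  if (k < m) {
    left <- setdiff(seq_len(m), order[seq_len(k)])
    stop("cyclic hierarchy detected involving term '",
         termIdsVec[min(left)], "'")
  }
  order
}

.heapNew <- function(capacity) list(v = integer(capacity), n = 0L)

.heapPush <- function(h, x) {
  h$n <- h$n + 1L
  i <- h$n
  h$v[i] <- x
  while (i > 1L) {
    p <- i %/% 2L
    if (h$v[p] <= h$v[i]) break
    tmp <- h$v[p]; h$v[p] <- h$v[i]; h$v[i] <- tmp
    i <- p
  }
  h
}

.heapPop <- function(h) {
  top <- h$v[1L]
  h$v[1L] <- h$v[h$n]
  h$n <- h$n - 1L
  i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= h$n && h$v[l] < h$v[s]) s <- l
    if (r <= h$n && h$v[r] < h$v[s]) s <- r
    if (s == i) break
    tmp <- h$v[s]; h$v[s] <- h$v[i]; h$v[i] <- tmp
    i <- s
  }
  list(heap = h, value = top)
}

#' Load per-term information-accretion weights
#'
#' Reads a headerless two-column TSV (term id, non-negative weight) and
#' returns a weight for every term of \code{graph}, in term-index order.
#' Secondary ids resolve to their canonical term. Terms absent from the
#' file get weight 0 and file entries naming unknown terms are ignored;
#' both situations emit a warning. A negative or non-numeric weight is a
#' fatal error naming the offending line.
#'
#' @param file path to the information-accretion file.
#' @param graph an \linkS4class{OntologyDAG}.
#' @param text alternatively, the file content as a character vector of
#'   lines (overrides \code{file}).
#' @return Named numeric vector of length \code{nTerms(graph)} in term
#'   index order.
#' @export
readIA <- function(file = NULL, graph, text = NULL) {
  stopifnot(is(graph, "OntologyDAG"))
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  text <- text[nzchar(trimws(text))]
  w <- stats::setNames(numeric(nTerms(graph)), termIds(graph))
  seen <- character()
  unknown <- 0L
  for (ln in seq_along(text)) {
    fields <- strsplit(text[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("information-accretion file: line ", ln, " has fewer than 2 fields")
    id <- trimws(fields[1])
    val <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(val) || val < 0)
      stop("information-accretion file: non-numeric or negative weight ",
           "on line ", ln, " ('", trimws(fields[2]), "')")
    if (id %in% names(graph@altIds)) id <- unname(graph@altIds[id])
    if (id %in% names(w)) {
      w[id] <- val
      seen <- c(seen, id)
    } else {
      unknown <- unknown + 1L
    }
  }
  if (unknown > 0L)
    warning(unknown, " information-accretion entr(y/ies) for unknown ",
            "term(s) ignored")
  missing <- setdiff(names(w), seen)
  if (length(missing) > 0L)
    warning(length(missing), " ontology term(s) missing from the ",
            "information-accretion file; assigned weight 0")
  w
}
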