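# Small hand-written ontologies used across the suite.

# chain: D is_a B is_a A (root A)
chainOBO <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: A", "name: root", "",
    "[Term]", "id: B", "name: mid", "is_a: A", "",
    "[Term]", "id: D", "name: leaf", "is_a: B")
}

# diamond: D is_a B is_a A and D is_a C is_a A (root A)
diamondOBO <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: A", "name: root", "",
    "[Term]", "id: B", "name: left", "is_a: A", "",
    "[Term]", "id: C", "name: right", "is_a: A", "",
    "[Term]", "id: D", "name: bottom", "is_a: B", "is_a: C")
}

writeTmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

parseOBOText <- function(lines, ...) readOBO(text = lines, ...)

tsv <- function(...) paste(..., sep = "\t")

# direct (unpropagated) truth/score matrices for a single-namespace graph
gtFromPairs <- function(pairs, graphs) {
  readGroundTruth(text = vapply(pairs, function(p) tsv(p[1], p[2]),
                                character(1)),
                  graphs = graphs)
}
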