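#' Build plotting curves from a written evaluation table
#'
#' Reads the evaluation TSV and a best-score TSV (as written by
#' \code{\link{runEvaluation}}) and reshapes them into per-method,
#' per-namespace curves — precision/recall points for \code{kind = "pr"},
#' remaining-uncertainty/misinformation points for \code{kind = "rumi"} —
#' ordered by threshold, with the best-scoring point flagged. Every
#' plotted point is a verbatim table row; no interpolation or smoothing
#' is applied. When a team map is given, the curves are restricted to the
#' per-team winners (see \code{\link{dedupeTeams}}) and display names are
#' substituted.
#'
#' @param table path to \code{evaluation_all.tsv}, or the equivalent
#'   data.frame.
#' @param best path to the matching best-score TSV (\code{fmax.tsv} for
#'   \code{"pr"}, \code{smin.tsv} for \code{"rumi"}), or the data.frame.
#' @param kind \code{"pr"} or \code{"rumi"}.
#' @param teamMap optional data.frame from \code{\link{readTeamMap}} (or
#'   a path).
#' @return data.frame of curve points: \code{filename}, \code{display},
#'   \code{ns}, \code{tau}, \code{x}, \code{y}, \code{best} (logical),
#'   \code{label} (legend text with the best value).
#' @export
buildCurves <- function(table, best, kind = c("pr", "rumi"),
                        teamMap = NULL) {
  kind <- match.arg(kind)
  if (is.character(table)) table <- utils::read.delim(table)
  if (is.character(best)) best <- utils::read.delim(best)
  if (is.character(teamMap)) teamMap <- readTeamMap(teamMap)
  stopifnot(nrow(table) >= 1L)
  cols <- if (kind == "pr") c(x = "rc", y = "pr", metric = "f")
          else c(x = "ru", y = "mi", metric = "s")
  for (cn in cols)
    if (is.null(table[[cn]]))
      stop("evaluation table lacks required column '", cn, "'")
  if (is.null(table$filename)) table$filename <- "prediction"
  if (is.null(best$filename)) best$filename <- "prediction"

  if (!is.null(teamMap)) {
    tab <- if (kind == "pr") "fmax" else "smin"
    best <- dedupeTeams(stats::setNames(list(best), tab), teamMap)[[tab]]
  } else {
    best$display <- best$filename
  }
  keep <- paste(table$filename, table$ns) %in%
    paste(best$filename, best$ns)
  table <- table[keep, , drop = FALSE]

  hit <- match(paste(table$filename, table$ns),
               paste(best$filename, best$ns))
  bestVal <- best[[cols[["metric"]]]][hit]
  out <- data.frame(
    filename = table$filename,
    display = best$display[hit],
    ns = table$ns,
    tau = table$tau,
    x = table[[cols[["x"]]]],
    y = table[[cols[["y"]]]],
    best = table$tau == best$tau[hit] &
      table[[cols[["metric"]]]] == bestVal,
    label = sprintf("%s (%s=%.3f)", best$display[hit],
                    if (kind == "pr") "Fmax" else "Smin", bestVal),
    stringsAsFactors = FALSE)
  out <- out[order(out$ns, out$filename, out$tau), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render precision/recall or RU/MI curves to image files
#'
#' One figure per namespace, drawn in threshold order with the
#' best-scoring point marked. Output files are named
#' \code{<kind>_<namespace>.<format>} under \code{outDir}.
#'
#' @param curves data.frame from \code{\link{buildCurves}}.
#' @param kind \code{"pr"} or \code{"rumi"} (controls axis labels and
#'   file names).
#' @param outDir output directory, created if absent.
#' @param format image format understood by \code{ggplot2::ggsave}
#'   (e.g. \code{"png"}, \code{"svg"}, \code{"pdf"}).
#' @param width,height figure size in inches.
#' @return (Invisibly) character vector of the written file paths.
#' @export
plotCurves <- function(curves, kind = c("pr", "rumi"), outDir = ".",
                       format = "png", width = 7, height = 5) {
  kind <- match.arg(kind)
  stopifnot(nrow(curves) >= 1L)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  labs <- if (kind == "pr") c(x = "Recall", y = "Precision")
          else c(x = "Remaining uncertainty", y = "Misinformation")
  paths <- character()
  for (nsTag in sort(unique(curves$ns))) {
    d <- curves[curves$ns == nsTag, , drop = FALSE]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                         color = .data$label)) +
      ggplot2::geom_path(linewidth = 0.6) +
      ggplot2::geom_point(data = d[d$best, , drop = FALSE],
                          size = 2.5, shape = 18) +
      ggplot2::labs(x = labs[["x"]], y = labs[["y"]],
                    color = NULL, title = nsTag) +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "bottom",
                     legend.direction = "vertical")
    if (kind == "pr")
      p <- p + ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
    path <- file.path(outDir, sprintf("%s_%s.%s", kind, nsTag, format))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    paths <- c(paths, path)
  }
  invisible(paths)
}
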