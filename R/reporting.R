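# Summaries and figures: presence/absence matrix rendering and event
# summaries (divergence-time, intron-length and relative-position counts).

.status_colors <- c(present = "#c0392b",   # red
                    absent = "#2980b9",    # blue
                    uncovered = "#9e9e9e") # grey

#' Render a presence/absence matrix as an SVG figure
#'
#' Rows are ordered by the tree's tip order (cladewise traversal); cells are
#' red for introns present at the focal position, blue for absent, grey for
#' uncovered.  The SVG is emitted directly, so output bytes are
#' deterministic for fixed input.
#'
#' @param pm A `presence_matrix`.
#' @param tree Species tree whose leaves cover the matrix species.
#' @param path Output file (`.svg`).
#' @param cell Cell size in pixels.
#' @return Invisibly, `path`.
#' @export
render_matrix <- function(pm, tree, path, cell = 14L) {
  if (nrow(pm) == 0L) stop("render_matrix: empty matrix")
  species <- attr(pm, "species")
  missing <- setdiff(unname(species), tree$tip.label)
  if (length(missing)) {
    stop("render_matrix: species not in tree: ",
         paste(missing, collapse = ", "))
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  tip_order <- tree$tip.label[tree$edge[tree$edge[, 2] <=
                                          length(tree$tip.label), 2]]
  rows <- names(species)[order(match(unname(species), tip_order))]
  label_w <- 10L + 7L * max(nchar(c(species, "species")))
  w <- label_w + cell * ncol(pm) + 10L
  h <- 10L + cell * length(rows) + 10L
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            w, h),
    '<style>text{font-family:monospace;font-size:11px;}</style>')
  for (i in seq_along(rows)) {
    acc <- rows[i]
    y <- 10L + (i - 1L) * cell
    out <- c(out, sprintf('<text x="5" y="%d">%s</text>',
                          y + cell - 3L, species[[acc]]))
    for (j in seq_len(ncol(pm))) {
      out <- c(out, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="white"/>',
        label_w + (j - 1L) * cell, y, cell, cell,
        .status_colors[[pm[acc, j]]]))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Summarize intron gain events
#'
#' Computes, per event, the relative intron position (protein-coordinate
#' index of the intron divided by the protein length, in \[0, 1\]) and bins
#' events by clade age, intron length and relative position.
#'
#' @param events data.frame with columns `intron_length`, `protein_index`
#'   and `clade_age` (e.g. the accepted rows of the `candidates` table from
#'   [run_gain_pipeline()]).
#' @param protein_length Length of the focal protein (residues, unmarked).
#' @param age_breaks,length_breaks,position_breaks Histogram bin edges;
#'   defaults cover the data range.
#' @param path Optional path for a tab-separated per-event summary.
#' @return List of class `event_summary`: `events` (with
#'   `relative_position` added), `age_counts`, `length_counts`,
#'   `position_counts`.
#' @export
summarize_events <- function(events, protein_length, age_breaks = NULL,
                             length_breaks = NULL,
                             position_breaks = seq(0, 1, by = 0.1),
                             path = NULL) {
  if (is.null(events) || nrow(events) == 0L) {
    out <- list(events = data.frame(), age_counts = integer(0),
                length_counts = integer(0), position_counts = integer(0))
    class(out) <- "event_summary"
    return(out)
  }
  ev <- events
  ev$relative_position <- ev$protein_index / protein_length
  stopifnot(all(ev$relative_position >= 0 & ev$relative_position <= 1))
  bin <- function(x, breaks) {
    if (all(is.na(x))) return(integer(0))
    if (is.null(breaks)) {
      breaks <- pretty(range(x, na.rm = TRUE), n = 10)
    }
    table(cut(x, breaks, include.lowest = TRUE))
  }
  out <- list(events = ev,
              age_counts = bin(ev$clade_age, age_breaks),
              length_counts = bin(ev$intron_length, length_breaks),
              position_counts = bin(ev$relative_position, position_breaks))
  class(out) <- "event_summary"
  if (!is.null(path)) {
    utils::write.table(ev, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("<event_summary> %d event(s)\n", nrow(x$events)))
  invisible(x)
}
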