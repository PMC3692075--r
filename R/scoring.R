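# Per-column discriminativeness: how much a column's tree agrees with the
# final consensus topology, and the blue-to-red colour mapping.

#' Score one column tree against the consensus
#'
#' The discriminativeness of an ungapped column is the fraction of the
#' consensus bipartitions its own tree recovers:
#' \eqn{|B(consensus) \cap B(column)| / |B(consensus)|}. A column whose
#' tree reproduces the whole consensus topology scores 1 (highly
#' discriminant, red); one sharing no split scores 0 (poorly discriminant,
#' blue). When the consensus is a star (no internal edges) the score is
#' defined as 0. Summing `score * |B(consensus)|` over columns returns the
#' total of the consensus support counts, so the two bookkeepings of
#' "supporting positions" agree exactly.
#'
#' @param column_tree A `phylo` built from one column's distance matrix.
#' @param consensus The consensus `phylo`.
#' @return A number in \[0, 1\].
#' @export
column_support_score <- function(column_tree, consensus) {
  if (!identical(sort(column_tree$tip.label), sort(consensus$tip.label)))
    trmsd_error("leaf_set", "column tree and consensus have different leaf sets")
  cons <- names(tree_bipartitions(consensus))
  if (length(cons) == 0L) return(0)
  col <- names(tree_bipartitions(column_tree))
  length(intersect(cons, col)) / length(cons)
}

#' Map a score to the blue-to-red colour scheme
#'
#' Linear interpolation in RGB from blue `#0000FF` (score 0, poorly
#' discriminant) to red `#FF0000` (score 1, highly discriminant), rounding
#' each channel to the nearest integer. With `palette = "discrete"` the
#' unit interval is first snapped to the midpoints of 9 equal bins.
#'
#' @param score Number(s) in \[0, 1\].
#' @param palette `"continuous"` or `"discrete"`.
#' @return Hex RGB string(s) like `"#800080"`.
#' @examples
#' score_to_color(c(0, 0.5, 1))  # "#0000FF" "#800080" "#FF0000"
#' @export
score_to_color <- function(score, palette = c("continuous", "discrete")) {
  palette <- match.arg(palette)
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    trmsd_error("range", "scores must lie in [0, 1]")
  if (palette == "discrete") {
    bin <- pmin(floor(score * 9), 8)
    score <- (bin + 0.5) / 9
  }
  r <- round(255 * score)
  b <- round(255 * (1 - score))
  sprintf("#%02X%02X%02X", r, 0L, b)
}

# Scores for a whole run: one row per ungapped column.
score_columns <- function(column_trees, consensus, column_map,
                          palette = "continuous") {
  cons_keys <- names(tree_bipartitions(consensus))
  shared <- vapply(column_trees, function(t)
    length(intersect(cons_keys, names(tree_bipartitions(t)))), integer(1))
  score <- if (length(cons_keys) == 0L) rep(0, length(column_trees))
  else shared / length(cons_keys)
  data.frame(
    ungapped_index = seq_along(column_trees),
    alignment_column = column_map$columns,
    score = score,
    shared_splits = shared,
    color = score_to_color(score, palette),
    stringsAsFactors = FALSE
  )
}
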