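# Report writers: everything a completed run leaves on disk.

# PHYLIP square distance-matrix text: count line, then one row per label
# (label left-justified to >= 10 characters, 6-decimal distances).
phylip_square <- function(M) {
  labels <- rownames(M)
  c(sprintf("%5d", nrow(M)),
    vapply(seq_len(nrow(M)), function(i)
      paste0(formatC(labels[i], width = -10),
             paste(sprintf("%.6f", M[i, ]), collapse = " ")),
      character(1)))
}

# Colored-MSA HTML: a score track with one span per ungapped column, then
# the alignment with ungapped residues highlighted by column score.
msa_colored_html <- function(msa, scores) {
  colmap <- setNames(scores$color, scores$alignment_column)
  track <- vapply(seq_len(msa$length), function(j) {
    col <- colmap[as.character(j)]
    if (is.na(col)) " "
    else sprintf("<span style=\"background-color:%s\">&nbsp;</span>", col)
  }, character(1))
  width <- max(nchar(msa$ids)) + 2L
  pad <- function(s) formatC(s, width = -width)
  rows <- vapply(msa$ids, function(id) {
    chars <- strsplit(msa$seqs[[id]], "")[[1]]
    cells <- vapply(seq_along(chars), function(j) {
      col <- colmap[as.character(j)]
      if (is.na(col)) chars[j]
      else sprintf("<b style=\"background-color:%s\">%s</b>", col, chars[j])
    }, character(1))
    paste0(pad(id), paste(cells, collapse = ""))
  }, character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Colored alignment</title>",
    "<style>body{font-family:monospace;white-space:pre;} b{font-weight:normal;color:#fff;}</style>",
    "</head><body>",
    "Column discriminativeness, blue (poorly discriminant) to red (highly discriminant):",
    paste0(pad("score"), paste(track, collapse = "")),
    rows,
    "</body></html>")
}

#' Write all report files for a completed run
#'
#' Emits, under `out_dir`:
#' \itemize{
#'   \item `consensus.nwk` — the consensus tree with supports (count or
#'     fraction per the run's `support` setting);
#'   \item `columns.nwk` — the per-column neighbor-joining trees, one
#'     Newick per line in column order;
#'   \item `matrices.txt` — the per-column distance matrices, PHYLIP
#'     square format, concatenated in column order;
#'   \item `column_scores.tsv` — 1-based alignment column, 1-based
#'     ungapped index, score, shared split count, colour;
#'   \item `msa_colored.html` — the alignment with ungapped columns
#'     coloured by score;
#'   \item `run_log.json` — parameters and provenance of the run.
#' }
#'
#' @param result A `trmsd` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    trmsd_error("io", sprintf("cannot create output directory %s", out_dir))
  p <- result$params
  write_newick(result$consensus, file.path(out_dir, "consensus.nwk"),
               support_mode = p$support, K = result$K)
  write_newick(result$column_trees, file.path(out_dir, "columns.nwk"),
               support_mode = "none")
  writeLines(unlist(lapply(result$matrices, phylip_square)),
             file.path(out_dir, "matrices.txt"))
  sc <- result$scores[, c("alignment_column", "ungapped_index", "score",
                          "shared_splits", "color")]
  utils::write.table(format(sc, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(out_dir, "column_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(msa_colored_html(result$msa, result$scores),
             file.path(out_dir, "msa_colored.html"))
  log <- c(p, list(n_sequences = length(result$msa$ids),
                   alignment_columns = result$msa$length,
                   K = result$K))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
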