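#' Structure-based clustering of an aligned protein family
#'
#' Runs the full analysis: the alignment and one structure per sequence
#' are validated and mapped, the ungapped columns are located, a
#' dRMSD-difference distance matrix is computed for every ungapped column,
#' each matrix is turned into a neighbor-joining tree, and the per-column
#' trees are combined into a strict majority-rule consensus whose internal
#' nodes carry the number of supporting ungapped positions. Every column
#' is then scored for its contribution to the consensus topology
#' (discriminativeness, mapped to the blue-to-red colour scheme).
#'
#' @param msa Path to an aligned FASTA/ClustalW file, or a `trmsd_msa`.
#' @param templates Path to a template list, or a `trmsd_templates`
#'   (ignored when `structures` is given).
#' @param structures Optional named list of `trmsd_structure` objects,
#'   bypassing file loading.
#' @param out_dir If non-`NULL`, all report files are written there (see
#'   [write_reports()]).
#' @param format Alignment format passed to [read_msa()].
#' @param atom Representative atom, `"CA"` or `"CB"` (CB falls back to CA
#'   for glycine).
#' @param support How supports are written in reports: `"count"` (number
#'   of supporting columns) or `"fraction"` (count/K, 3 decimals).
#' @param palette Colour palette for scores, `"continuous"` or
#'   `"discrete"`.
#' @param max_seqs Soft cap on the number of sequences (default 150).
#' @param clamp_negative Clamp negative NJ branch lengths to 0 in the
#'   written per-column trees (display only; the consensus uses topology
#'   alone and is unaffected).
#' @param pdb_dir Directory for the T-Coffee template dialect (see
#'   [read_templates()]).
#' @param seed Recorded in the run log for provenance; the pipeline itself
#'   is deterministic.
#' @return An object of class `trmsd`: list with `msa`, `column_map`,
#'   `matrices` (per-column distance matrices), `column_trees`,
#'   `consensus` (a `phylo` with support-count node labels), `scores`
#'   (data frame, one row per ungapped column), `K` and `params`.
#' @examples
#' fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 15,
#'                    noise_sigma = 0.05, angle_step = 40, seed = 1)
#' fit <- trmsd(fam$msa, structures = fam$structures)
#' fit
#' @export
trmsd <- function(msa, templates = NULL, structures = NULL, out_dir = NULL,
                  format = "auto", atom = c("CA", "CB"),
                  support = c("count", "fraction"),
                  palette = c("continuous", "discrete"),
                  max_seqs = 150L, clamp_negative = FALSE, pdb_dir = NULL,
                  seed = NULL) {
  atom <- match.arg(atom)
  support <- match.arg(support)
  palette <- match.arg(palette)

  if (is.character(msa)) msa <- read_msa(msa, format = format)
  if (!inherits(msa, "trmsd_msa"))
    trmsd_error("format", "msa must be a file path or a trmsd_msa object")
  if (length(msa$ids) > max_seqs)
    trmsd_error("validation", sprintf(
      "alignment has %d sequences, above the configured cap of %d (raise max_seqs to override)",
      length(msa$ids), max_seqs))

  if (is.null(structures)) {
    if (is.null(templates))
      trmsd_error("validation", "either templates or structures must be provided")
    if (is.character(templates))
      templates <- read_templates(templates,
                                  pdb_dir = pdb_dir %||% dirname(templates))
    missing_ids <- setdiff(msa$ids, templates$seq_id)
    if (length(missing_ids) > 0L)
      trmsd_error("validation", sprintf(
        "no template entry for sequence(s): %s", paste(missing_ids, collapse = ", ")))
    structures <- setNames(lapply(msa$ids, function(id) {
      row <- templates[templates$seq_id == id, ]
      read_structure(row$structure_path, row$chain_id, id, atom = atom)
    }), msa$ids)
  }

  mappings <- map_sequences_to_structures(msa, structures)
  column_map <- find_ungapped_columns(msa, mappings, structures)
  intras <- setNames(lapply(msa$ids, function(id)
    intra_distances(structures[[id]], column_map)), msa$ids)
  matrices <- all_column_matrices(column_map, intras)
  column_trees <- lapply(matrices, neighbor_joining)
  consensus <- majority_consensus(column_trees, K = column_map$K)
  scores <- score_columns(column_trees, consensus, column_map, palette = palette)

  if (clamp_negative)
    column_trees <- lapply(column_trees, function(t) {
      t$edge.length <- pmax(t$edge.length, 0)
      t
    })

  res <- structure(list(
    msa = msa, column_map = column_map, matrices = matrices,
    column_trees = column_trees, consensus = consensus, scores = scores,
    K = column_map$K,
    params = list(atom = atom, support = support, palette = palette,
                  max_seqs = max_seqs, clamp_negative = clamp_negative,
                  seed = seed,
                  drmsd_normalization = "1/(K-1) over the K-1 column pairs",
                  consensus_rule = "strict majority (> K/2), PHYLIP-style",
                  nj_tie_break = "lexicographic by current label order",
                  version = as.character(utils::packageVersion("trmsd")))),
    class = "trmsd")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

#' @export
print.trmsd <- function(x, ...) {
  ns <- length(x$msa$ids)
  nsplit <- length(tree_bipartitions(x$consensus))
  cat(sprintf("Structure-based clustering of %d sequences\n", ns))
  cat(sprintf("  ungapped columns (K): %d of %d alignment columns\n",
              x$K, x$msa$length))
  cat(sprintf("  consensus splits: %d (max possible %d)\n", nsplit, max(ns - 3L, 0L)))
  if (nsplit > 0) {
    sup <- split_supports(x$consensus)
    cat(sprintf("  split support: %d-%d columns (of %d)\n",
                as.integer(min(sup)), as.integer(max(sup)), x$K))
  }
  cat(sprintf("  mean column discriminativeness: %.3f\n", mean(x$scores$score)))
  invisible(x)
}

#' @export
summary.trmsd <- function(object, ...) {
  sup <- split_supports(object$consensus)
  out <- list(
    n_sequences = length(object$msa$ids),
    alignment_columns = object$msa$length,
    K = object$K,
    consensus_splits = length(sup),
    supports = if (length(sup)) as.integer(sup) else integer(0),
    score_summary = summary(object$scores$score),
    top_columns = utils::head(
      object$scores[order(-object$scores$score), c("alignment_column", "score")], 5L)
  )
  class(out) <- "summary.trmsd"
  out
}

#' @export
print.summary.trmsd <- function(x, ...) {
  cat(sprintf("trmsd run: %d sequences, %d/%d ungapped columns\n",
              x$n_sequences, x$K, x$alignment_columns))
  cat(sprintf("Consensus: %d splits; supports: %s\n", x$consensus_splits,
              paste(x$supports, collapse = ", ")))
  cat("Column discriminativeness:\n")
  print(x$score_summary)
  cat("Most discriminant columns (1-based alignment index):\n")
  print(x$top_columns, row.names = FALSE)
  invisible(x)
}

#' Plot the consensus tree of a run
#'
#' @param x A `trmsd` object.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.trmsd <- function(x, ...) {
  tr <- ape::compute.brlen(x$consensus, 1)
  ape::plot.phylo(tr, show.node.label = TRUE, ...)
  invisible(x)
}
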