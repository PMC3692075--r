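#' Serialise a tree to a Newick string
#'
#' Fixed-format Newick: branch lengths (when the tree has them) with 6
#' decimals, internal-node support labels as integer counts
#' (`support_mode = "count"`), as `count/K` with 3 decimals
#' (`"fraction"`), or omitted (`"none"`). Labels containing punctuation
#' are single-quoted per Newick rules. The output is byte-deterministic.
#'
#' @param tree A `phylo`; internal node labels, if any, hold support counts.
#' @param support_mode One of `"count"`, `"fraction"`, `"none"`.
#' @param K Divisor for `"fraction"` mode.
#' @return A single Newick string, terminated by `;`.
#' @export
newick_string <- function(tree, support_mode = c("count", "fraction", "none"),
                          K = NULL) {
  support_mode <- match.arg(support_mode)
  if (support_mode == "fraction" && is.null(K))
    trmsd_error("format", "fraction support mode needs K")
  ntip <- length(tree$tip.label)
  root <- tree_root(tree)
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(ntip + tree$Nnode)))
  elen <- NULL
  if (!is.null(tree$edge.length))
    elen <- setNames(tree$edge.length, tree$edge[, 2])

  lab_for <- function(node) {
    if (support_mode == "none" || node == root || is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - ntip]
    if (is.na(lab) || !nzchar(lab)) return("")
    val <- suppressWarnings(as.numeric(lab))
    if (is.na(val)) return(newick_escape(lab))
    if (support_mode == "count") format(val, scientific = FALSE)
    else sprintf("%.3f", val / K)
  }
  len_for <- function(node) {
    if (is.null(elen)) return("")
    sprintf(":%.6f", elen[[as.character(node)]])
  }
  render <- function(node) {
    kids <- children[[node]]
    body <- if (length(kids) == 0L) newick_escape(tree$tip.label[node])
    else paste0("(", paste(vapply(kids, function(k)
      paste0(render(k), len_for(k)), character(1)), collapse = ","), ")",
      lab_for(node))
    body
  }
  paste0(render(root), ";")
}

#' Write a tree (or trees) in Newick format
#'
#' @param tree A `phylo` or a list of them (one tree per output line).
#' @param path Output file path.
#' @inheritParams newick_string
#' @return `path`, invisibly. Re-reading the file with [read_newick()]
#'   reproduces the bipartition set and support values exactly.
#' @export
write_newick <- function(tree, path, support_mode = c("count", "fraction", "none"),
                         K = NULL) {
  support_mode <- match.arg(support_mode)
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  writeLines(vapply(trees, newick_string, character(1),
                    support_mode = support_mode, K = K), path)
  invisible(path)
}

#' Read Newick trees
#'
#' Thin wrapper over [ape::read.tree()]; internal node labels (supports)
#' are preserved.
#'
#' @param path File with one Newick tree per line.
#' @return A `phylo` (single tree) or `multiPhylo` (several).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) trmsd_error("io", sprintf("tree file not found: %s", path))
  out <- ape::read.tree(path)
  if (is.null(out)) trmsd_error("format", sprintf("no trees in %s", path))
  out
}
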