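#' Strict majority-rule consensus with split support counts
#'
#' Combines a collection of trees on one leaf set into the consensus tree
#' containing exactly the bipartitions present in strictly more than half
#' of the input trees. Such splits are always mutually compatible, so the
#' consensus needs no arbitration; splits short of a strict majority
#' collapse into polytomies. Each retained internal edge carries the number
#' of input trees containing its split — here, the number of ungapped
#' alignment positions supporting it, analogous to a bootstrap value. The
#' consensus carries no branch lengths.
#'
#' @param trees List of `phylo` trees sharing one leaf set (order of leaves
#'   may differ).
#' @param K Number of trees the majority is taken over; defaults to
#'   `length(trees)`.
#' @return An unrooted `phylo` tree whose internal node labels are the
#'   support counts (the root label is empty). Leaves are emitted in
#'   lexicographic order, making the Newick form independent of input
#'   order.
#' @export
majority_consensus <- function(trees, K = length(trees)) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L || K < 1L)
    trmsd_error("matrix", "consensus requires at least one tree")
  leafset <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), leafset))
      trmsd_error("leaf_set", "input trees do not share the same leaf set")
  }
  keys <- unlist(lapply(trees, function(t) names(tree_bipartitions(t))))
  counts <- table(keys)
  majority <- counts[counts > K / 2]
  sides <- lapply(names(majority), split_from_key)
  build_tree_from_splits(leafset, sides, as.integer(majority))
}

# Assemble a phylo from a compatible (laminar, after anchoring) split set.
# The tree is rooted at the first leaf's side: every split's block not
# containing the anchor is a clade; clades nest because the splits are
# pairwise compatible.
build_tree_from_splits <- function(labels, sides, supports = NULL) {
  labels <- sort(labels)
  anchor <- labels[1]
  blocks <- lapply(sides, function(s) {
    if (anchor %in% s) sort(setdiff(labels, s)) else sort(s)
  })
  if (length(blocks) > 1L) {
    ord <- order(-lengths(blocks), vapply(blocks, split_key, character(1)))
    blocks <- blocks[ord]
    supports <- supports[ord]
  }
  nb <- length(blocks)
  # parent of block i = smallest strictly containing block (0 = root)
  parent <- integer(nb)
  for (i in seq_len(nb)) {
    parent[i] <- 0L
    if (i > 1L) for (j in (i - 1L):1L) {
      if (length(blocks[[j]]) > length(blocks[[i]]) && all(blocks[[i]] %in% blocks[[j]])) {
        parent[i] <- j
        break
      }
    }
  }
  # leaves attach to the smallest block containing them (0 = root)
  leaf_home <- vapply(labels, function(lf) {
    inb <- which(vapply(blocks, function(b) lf %in% b, logical(1)))
    if (length(inb) == 0L) 0L else max(inb)  # blocks sorted big->small, nested
  }, integer(1))

  render <- function(node) {
    kid_blocks <- which(parent == node)
    kid_leaves <- labels[leaf_home == node]
    items <- c(newick_escape(kid_leaves), vapply(kid_blocks, render, character(1)))
    lab <- if (node == 0L || is.null(supports)) "" else as.character(supports[node])
    paste0("(", paste(items, collapse = ","), ")", lab)
  }
  txt <- paste0(render(0L), ";")
  ape::read.tree(text = txt)
}

#' Convert split support counts to fractions (or leave as counts)
#'
#' @param t A `phylo` whose internal node labels are support counts.
#' @param K Total number of column trees the supports were counted over.
#' @param mode `"count"` (identity) or `"fraction"` (labels become
#'   `count/K` rounded to 3 decimals).
#' @return The tree with transformed node labels.
#' @export
normalize_support <- function(t, K, mode = c("count", "fraction")) {
  mode <- match.arg(mode)
  if (mode == "count" || is.null(t$node.label)) return(t)
  lab <- t$node.label
  num <- suppressWarnings(as.numeric(lab))
  t$node.label <- ifelse(is.na(num) | !nzchar(lab), lab, sprintf("%.3f", num / K))
  t
}
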