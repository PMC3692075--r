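# Bipartitions (splits) of unrooted leaf-labelled trees.
#
# A split is stored as its canonical side: the smaller of the two leaf
# blocks, ties broken by the lexicographically smallest sorted block. Keys
# join the sorted side with an unprintable separator so arbitrary labels
# are safe.

SPLIT_SEP <- "\x1f"

split_key <- function(side) paste(sort(side), collapse = SPLIT_SEP)

split_from_key <- function(key) strsplit(key, SPLIT_SEP, fixed = TRUE)[[1]]

canonical_side <- function(side, labels) {
  other <- setdiff(labels, side)
  if (length(side) < length(other)) return(sort(side))
  if (length(other) < length(side)) return(sort(other))
  a <- split_key(side); b <- split_key(other)
  if (a <= b) sort(side) else sort(other)
}

# Tip-label sets below every node, computed by our own postorder sweep
# (children accumulate before parents).
node_tip_sets <- function(tr) {
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

tree_root <- function(tr) setdiff(tr$edge[, 1], tr$edge[, 2])[1]

#' Bipartitions of an unrooted tree
#'
#' Returns the non-trivial bipartitions (one per internal edge) of a tree,
#' each as the canonical (smaller; ties lexicographic) block of leaf
#' labels. Trivial splits cutting off a single leaf are excluded. The tree
#' is interpreted as unrooted; a degree-2 root does not create a duplicate
#' split.
#'
#' @param t A `phylo` tree.
#' @return A named list of character vectors (canonical split sides); names
#'   are internal canonical keys usable for set operations.
#' @export
tree_bipartitions <- function(t) {
  labels <- t$tip.label
  n <- length(labels)
  if (n < 4L) return(structure(list(), names = character(0)))
  desc <- node_tip_sets(t)
  root <- tree_root(t)
  ntip <- n
  internal <- setdiff(unique(t$edge[, 1]), root)
  sides <- list()
  for (v in internal) {
    below <- desc[[v]]
    if (length(below) < 2L || length(below) > n - 2L) next
    side <- canonical_side(below, labels)
    sides[[split_key(side)]] <- side
  }
  sides
}

# key -> support value (numeric) taken from internal node labels.
split_supports <- function(t) {
  labels <- t$tip.label
  n <- length(labels)
  if (is.null(t$node.label) || n < 4L) return(setNames(numeric(0), character(0)))
  desc <- node_tip_sets(t)
  root <- tree_root(t)
  out <- numeric(0)
  for (v in setdiff(unique(t$edge[, 1]), root)) {
    below <- desc[[v]]
    if (length(below) < 2L || length(below) > n - 2L) next
    key <- split_key(canonical_side(below, labels))
    lab <- t$node.label[v - n]
    if (!is.na(lab) && nzchar(lab)) out[key] <- suppressWarnings(as.numeric(lab))
  }
  out
}

# Two splits over the same leaf set are compatible iff one of the four
# pairwise block intersections is empty.
splits_compatible <- function(side1, side2, labels) {
  o1 <- setdiff(labels, side1); o2 <- setdiff(labels, side2)
  length(intersect(side1, side2)) == 0L ||
    length(intersect(side1, o2)) == 0L ||
    length(intersect(o1, side2)) == 0L ||
    length(intersect(o1, o2)) == 0L
}

# Is `group` a clan of the tree (a connected subtree under some rooting)?
# True for trivial groups, or when the group|rest bipartition is present.
is_clan <- function(t, group) {
  labels <- t$tip.label
  group <- sort(intersect(group, labels))
  if (length(group) <= 1L || length(group) >= length(labels) - 1L) return(TRUE)
  key <- split_key(canonical_side(group, labels))
  key %in% names(tree_bipartitions(t))
}
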