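#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair
#' \eqn{(i,j)} minimising \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) -
#' \sum_k d(j,k)} is joined, limb lengths follow the standard formulas
#' \eqn{l_i = d(i,j)/2 + (R_i - R_j)/(2(n-2))}, and distances to the new
#' node are \eqn{(d(i,k) + d(j,k) - d(i,j))/2}. Ties in \eqn{Q} are broken
#' by the smallest \eqn{(i,j)} in current label order (new nodes are
#' appended at the end), which makes the output deterministic even on
#' degenerate matrices. Negative branch lengths are retained as computed.
#'
#' The method is consistent: on a matrix that is exactly additive on a
#' binary tree it recovers that tree and its branch lengths.
#'
#' @param m Symmetric numeric matrix with zero diagonal and row/column
#'   names (the leaf labels), or a `trmsd_distmat`.
#' @return An unrooted `phylo` tree. For 2 labels the two limbs sum to
#'   `d`; for `n >= 3` the tree is fully binary (the root trifurcation is
#'   the unrooted representation).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(m) {
  m <- as.matrix(m)
  labels <- rownames(m)
  n <- length(labels)
  if (is.null(labels) || n < 2L)
    trmsd_error("matrix", "distance matrix needs row names and at least 2 labels")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE)) ||
      any(!is.finite(m)) || any(diag(m) != 0))
    trmsd_error("matrix", "distance matrix must be symmetric, finite, with zero diagonal")

  num <- function(x) sprintf("%.17g", x)
  frag <- newick_escape(labels)
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", frag[1], num(m[1, 2] / 2), frag[2], num(m[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  D <- unname(m)
  while (nrow(D) > 3L) {
    nc <- nrow(D)
    R <- rowSums(D)
    Q <- (nc - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, in current order among the minima
    best <- which(Q == min(Q[upper.tri(Q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (nc - 2))
    lj <- D[i, j] - li
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(nc), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    frag <- c(frag[keep],
              sprintf("(%s:%s,%s:%s)", frag[i], num(li), frag[j], num(lj)))
  }
  # final three limbs, solved exactly
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], num(l1), frag[2], num(l2), frag[3], num(l3))
  ape::read.tree(text = txt)
}
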