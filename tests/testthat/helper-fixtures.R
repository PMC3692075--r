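# Shared fixtures and independent oracles used across the suite.

# --- tiny PDB fixture builder (fixed-column ATOM records) -------------------

pdb_atom_line <- function(serial, atom, res3, chain, resno, x, y, z,
                          occ = 1.00, alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, atom, alt, res3, chain, resno, x, y, z, occ, 0.0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a plain 3-residue chain A: ALA CYS ASP at x = 0, 1, 2
simple_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "CYS", "A", 2, 1, 0, 0),
    pdb_atom_line(3, "CA", "ASP", "A", 3, 2, 0, 0)
  ), path)
}

# --- in-memory structure builder --------------------------------------------

make_structure <- function(seq_id, aa, xyz, chain = "A") {
  structure(list(seq_id = seq_id, chain_id = chain,
                 residues = data.frame(label = as.character(seq_along(aa)),
                                       aa = aa,
                                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                       stringsAsFactors = FALSE)),
            class = "trmsd_structure")
}

make_msa <- function(ids, rows) trmsd:::new_msa(ids, rows)

# random rigid motion applied to a coordinate matrix
apply_rigid <- function(xyz, seed) {
  set.seed(seed)
  q <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% t(R), 2, runif(3, -10, 10), `+`)
}

# --- independent geometry oracle: naive double loop -------------------------

# inter-structure distance at column c from raw coordinate matrices
# (rows = ungapped columns), written without any package code
naive_column_matrix <- function(c, coord_list) {
  n <- length(coord_list)
  K <- nrow(coord_list[[1]])
  M <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    acc <- 0
    for (cp in seq_len(K)) {
      if (cp == c) next
      da <- sqrt(sum((coord_list[[a]][c, ] - coord_list[[a]][cp, ])^2))
      db <- sqrt(sum((coord_list[[b]][c, ] - coord_list[[b]][cp, ])^2))
      acc <- acc + (da - db)^2
    }
    M[a, b] <- sqrt(acc / (K - 1))
  }
  dimnames(M) <- list(names(coord_list), names(coord_list))
  M
}

# run the package's per-column matrices directly from coordinate matrices
pkg_column_matrices <- function(coord_list) {
  ids <- names(coord_list)
  K <- nrow(coord_list[[1]])
  structures <- lapply(ids, function(id)
    make_structure(id, rep("A", K), coord_list[[id]]))
  names(structures) <- ids
  cm <- structure(list(columns = seq_len(K),
                       residues = matrix(rep(seq_len(K), length(ids)),
                                         ncol = length(ids),
                                         dimnames = list(NULL, ids)),
                       K = K),
                  class = "trmsd_columnmap")
  intras <- lapply(structures, intra_distances, column_map = cm)
  all_column_matrices(cm, intras)
}

# --- independent split oracle via ape::prop.part ----------------------------

oracle_splits <- function(tr) {
  labs <- tr$tip.label
  n <- length(labs)
  pp <- ape::prop.part(tr)
  keys <- character(0)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    other <- setdiff(labs, side)
    pick <- if (length(side) < length(other)) side
    else if (length(other) < length(side)) other
    else {
      a <- paste(sort(side), collapse = "|"); b <- paste(sort(other), collapse = "|")
      if (a <= b) side else other
    }
    keys <- c(keys, paste(sort(pick), collapse = "|"))
  }
  unique(keys)
}

# package bipartitions rendered with the same "|" keys for comparison
pkg_splits <- function(tr) {
  sides <- tree_bipartitions(tr)
  unname(vapply(sides, function(s) paste(sort(s), collapse = "|"), character(1)))
}

# --- random additive matrices on known binary trees -------------------------

random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.5, 2))
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[tr$tip.label, tr$tip.label])
}
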