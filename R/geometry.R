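# Core geometry: residue mapping, ungapped columns, intramolecular
# distances, and the per-column dRMSD-difference distance matrices.

#' Map alignment columns to structure residues
#'
#' For each sequence, the k-th non-gap character of its aligned row is
#' identified with the k-th residue of its structure model; gap columns map
#' to `NA`. The gap-stripped row and the structure's residue sequence must
#' have equal length and matching letters (the `X` wildcard on either side
#' matches anything).
#'
#' @param msa A `trmsd_msa`.
#' @param structures Named list of `trmsd_structure`, one per sequence id.
#' @return Named list of integer vectors (length = alignment columns):
#'   residue ordinal in the structure, or `NA` at gap columns.
#' @export
map_sequences_to_structures <- function(msa, structures) {
  missing_ids <- setdiff(msa$ids, names(structures))
  if (length(missing_ids) > 0L)
    trmsd_error("mapping", sprintf(
      "no structure provided for sequence(s): %s", paste(missing_ids, collapse = ", ")))
  chars <- msa_matrix(msa)
  out <- lapply(msa$ids, function(id) {
    row <- chars[id, ]
    st <- structures[[id]]
    nongap <- which(row != "-")
    saa <- st$residues$aa
    if (length(nongap) != length(saa))
      trmsd_error("mapping", sprintf(
        "sequence '%s': alignment row has %d residues but structure has %d",
        id, length(nongap), length(saa)))
    ok <- aa_match(row[nongap], saa)
    if (!all(ok)) {
      k <- which(!ok)[1]
      trmsd_error("mapping", sprintf(
        "sequence '%s': residue mismatch at alignment column %d ('%s' in alignment vs '%s' in structure)",
        id, nongap[k], row[nongap[k]], saa[k]))
    }
    map <- rep(NA_integer_, msa$length)
    map[nongap] <- seq_along(nongap)
    map
  })
  setNames(out, msa$ids)
}

#' Find the ungapped alignment columns
#'
#' A column is ungapped when every sequence has a residue there (no gap)
#' and that residue's representative-atom coordinate is resolved in every
#' structure. Ungapped columns are the coordinate system of the whole
#' analysis; the method requires at least two of them.
#'
#' @param msa A `trmsd_msa`.
#' @param mappings Output of [map_sequences_to_structures()].
#' @param structures Named list of `trmsd_structure`.
#' @return An object of class `trmsd_columnmap`: list with `columns`
#'   (1-based alignment column indices, strictly increasing), `residues`
#'   (K x n integer matrix of residue ordinals, columns named by sequence
#'   id) and `K`.
#' @export
find_ungapped_columns <- function(msa, mappings, structures) {
  ids <- msa$ids
  mapmat <- do.call(cbind, mappings[ids])  # L x n
  has_res <- !is.na(mapmat)
  has_coord <- has_res
  for (id in ids) {
    resolved <- !is.na(structures[[id]]$residues$x)
    col <- match(id, ids)
    idx <- mapmat[, col]
    has_coord[, col] <- has_res[, col] & resolved[ifelse(is.na(idx), 1L, idx)]
  }
  ungapped <- which(rowSums(has_coord) == length(ids))
  K <- length(ungapped)
  if (K < 2L)
    trmsd_error("insufficient_columns", sprintf(
      "only %d ungapped column(s) found; the analysis requires at least 2 columns with an aligned, coordinate-resolved residue in every sequence", K))
  residues <- mapmat[ungapped, , drop = FALSE]
  colnames(residues) <- ids
  rownames(residues) <- NULL
  structure(list(columns = as.integer(ungapped), residues = residues, K = K),
            class = "trmsd_columnmap")
}

#' @export
print.trmsd_columnmap <- function(x, ...) {
  cat(sprintf("Column map: %d ungapped columns over %d sequences\n",
              x$K, ncol(x$residues)))
  invisible(x)
}

#' Intramolecular distances at ungapped columns
#'
#' Euclidean distances (Angstroms) between one structure's representative
#' atoms at every pair of ungapped columns. These are invariant to rigid
#' motion of the structure, which is what lets the method skip
#' superposition entirely.
#'
#' @param structure A `trmsd_structure`.
#' @param column_map A `trmsd_columnmap`.
#' @return A K x K symmetric matrix with zero diagonal.
#' @export
intra_distances <- function(structure, column_map) {
  ord <- column_map$residues[, structure$seq_id]
  xyz <- structure_coords(structure)[ord, , drop = FALSE]
  if (any(is.na(xyz)))
    trmsd_error("mapping", sprintf(
      "structure '%s' lacks coordinates at a mapped ungapped column", structure$seq_id))
  as.matrix(stats::dist(xyz))
}

#' Per-column inter-structure distance matrix
#'
#' The distance between structures A and B at ungapped column c is the
#' root-mean-square difference of their intramolecular distances from c to
#' every other ungapped column:
#' \deqn{M_c(A,B) = \sqrt{ \frac{1}{K-1} \sum_{c' \ne c} \big( d_A(c,c') - d_B(c,c') \big)^2 }}
#' a distance-RMSD (dRMSD) restricted to the column's distance set; the
#' 1/(K-1) normalisation makes columns comparable across alignments.
#'
#' @param c Ungapped-column index (1-based, into the column map).
#' @param intras Named list of intramolecular distance matrices (all K x K,
#'   same label order), as from [intra_distances()].
#' @return A symmetric n x n matrix (class `trmsd_distmat`) with sequence
#'   ids as dimnames and attribute `ungapped_index`.
#' @export
column_distance_matrix <- function(c, intras) {
  K <- nrow(intras[[1]])
  if (c < 1L || c > K) trmsd_error("matrix", sprintf("column index %d out of range", c))
  # rows of profile = the K-1 distances d(c, c') for each structure
  profile <- vapply(intras, function(D) D[c, -c], numeric(K - 1L))
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1L,
                                               dimnames = list(NULL, names(intras)))
  M <- as.matrix(stats::dist(t(profile))) / sqrt(K - 1)
  dimnames(M) <- list(names(intras), names(intras))
  attr(M, "ungapped_index") <- c
  class(M) <- c("trmsd_distmat", class(M))
  M
}

#' All per-column distance matrices
#'
#' @param column_map A `trmsd_columnmap`.
#' @param intras Named list of intramolecular distance matrices.
#' @return List of K matrices in column order; each carries its 1-based
#'   alignment column as attribute `alignment_column`.
#' @export
all_column_matrices <- function(column_map, intras) {
  lapply(seq_len(column_map$K), function(c) {
    M <- column_distance_matrix(c, intras)
    attr(M, "alignment_column") <- column_map$columns[c]
    M
  })
}
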