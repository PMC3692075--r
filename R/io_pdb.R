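#' Read one chain of a PDB file as a structure model
#'
#' Extracts one representative coordinate per residue of the requested
#' chain, from the first MODEL only. The representative atom is the alpha
#' carbon (CA) by default; with `atom = "CB"` the beta carbon is used,
#' falling back to CA for glycine (which has no CB). Residues whose
#' representative atom is absent keep their place in the sequence with a
#' missing (`NA`) coordinate. Alternate locations are resolved by highest
#' occupancy, ties broken by alphabetical altloc code. Residue order is
#' file order; residue labels combine the author residue number and any
#' insertion code.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param chain_id Single-character chain identifier.
#' @param seq_id Sequence identifier to attach to the model.
#' @param atom Representative atom, `"CA"` or `"CB"`.
#' @return An object of class `trmsd_structure`: a list with `seq_id`,
#'   `chain_id` and a data frame `residues` with columns `label`, `aa`
#'   (one-letter code, `X` for unknown residues) and `x`, `y`, `z`
#'   (Angstroms; `NA` when the representative atom is unresolved).
#' @export
read_structure <- function(path, chain_id, seq_id, atom = c("CA", "CB")) {
  atom <- match.arg(atom)
  if (!file.exists(path)) trmsd_error("io", sprintf("structure file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) trmsd_error("format",
      sprintf("failed to parse PDB file %s: %s", path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!chain_id %in% at$chain) {
    avail <- sort(unique(at$chain))
    trmsd_error("chain", sprintf(
      "chain '%s' not found in %s (available: %s)",
      chain_id, path, paste(avail, collapse = ", ")))
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  reskey <- paste0(at$resno, ins)
  # residue order = first appearance in the file
  labels <- reskey[!duplicated(reskey)]
  res3 <- at$resid[!duplicated(reskey)]
  aa <- aa_three_to_one(res3)

  pick_coord <- function(key, want) {
    rows <- at[reskey == key & at$elety == want, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    occ <- ifelse(is.na(rows$o), 1, rows$o)
    alt <- ifelse(is.na(rows$alt), "", rows$alt)
    rows <- rows[order(-occ, alt), , drop = FALSE]
    c(rows$x[1], rows$y[1], rows$z[1])
  }
  coords <- lapply(seq_along(labels), function(i) {
    want <- atom
    if (atom == "CB" && aa[i] == "G") want <- "CA"  # glycine has no CB
    co <- pick_coord(labels[i], want)
    if (is.null(co) && want == "CB") co <- pick_coord(labels[i], "CA")
    co %||% c(NA_real_, NA_real_, NA_real_)
  })
  xyz <- do.call(rbind, coords)
  residues <- data.frame(label = labels, aa = aa,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE)
  if (all(is.na(residues$x)))
    trmsd_error("empty_structure", sprintf(
      "chain '%s' of %s has no residues with %s coordinates", chain_id, path, atom))
  bad <- !is.na(residues$x) & !(is.finite(residues$x) & is.finite(residues$y) & is.finite(residues$z))
  if (any(bad))
    trmsd_error("format", sprintf("non-finite coordinates in %s", path))
  structure(list(seq_id = seq_id, chain_id = chain_id, residues = residues),
            class = "trmsd_structure")
}

#' @export
print.trmsd_structure <- function(x, ...) {
  cat(sprintf("Structure model '%s' (chain %s): %d residues, %d with coordinates\n",
              x$seq_id, x$chain_id, nrow(x$residues), sum(!is.na(x$residues$x))))
  invisible(x)
}

structure_coords <- function(s) as.matrix(s$residues[, c("x", "y", "z")])

#' Write a structure model as a PDB file
#'
#' Emits fixed-column ATOM records (one representative atom per residue,
#' occupancy 1.00) followed by TER/END. Residues with missing coordinates
#' are skipped. Used by the synthetic-family generator and handy for
#' exporting models.
#'
#' @param s A `trmsd_structure`.
#' @param path Output file path.
#' @param atom_name Atom name to write (default `"CA"`).
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path, atom_name = "CA") {
  res <- s$residues
  keep <- !is.na(res$x)
  res3 <- ifelse(res$aa %in% names(AA1TO3), AA1TO3[res$aa], "UNK")
  lines <- character(0)
  serial <- 0L
  for (i in which(keep)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s %1s%4s    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial, paste0(" ", atom_name), res3[i], s$chain_id,
      res$label[i], res$x[i], res$y[i], res$z[i], 1.0, 0.0))
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
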