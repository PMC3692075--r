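#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or ClustalW file into a `trmsd_msa` object: an
#' ordered set of equally long aligned rows over the amino-acid alphabet
#' plus the gap character `-`. Rows are upper-cased and `.` gap characters
#' are normalised to `-`. ClustalW files may split the alignment over
#' several blocks; blocks are concatenated in order.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"clustal"`. `"auto"` sniffs
#'   the format from the first non-blank character (`>` means FASTA, a
#'   leading `CLUSTAL` header means ClustalW).
#' @return An object of class `trmsd_msa` with elements `ids` (unique
#'   sequence identifiers), `seqs` (aligned rows, named by id) and `length`
#'   (number of alignment columns).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-D", ">s2", "ACED"), fa)
#' msa <- read_msa(fa)
#' msa$length  # 4
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) trmsd_error("io", sprintf("alignment file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L)
    trmsd_error("format", sprintf("empty alignment file: %s", path))
  if (format == "auto") {
    format <- if (startsWith(nonblank[1], ">")) "fasta"
    else if (grepl("^CLUSTAL", nonblank[1])) "clustal"
    else trmsd_error("format", sprintf(
      "cannot sniff alignment format of %s (expected '>' or a CLUSTAL header)", path))
  }
  raw <- switch(format,
    fasta   = read_msa_fasta(path),
    clustal = read_msa_clustal(lines, path)
  )
  new_msa(raw$ids, raw$seqs)
}

read_msa_fasta <- function(path) {
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE, set.attributes = FALSE),
    error = function(e) trmsd_error("format",
      sprintf("failed to parse FASTA file %s: %s", path, conditionMessage(e))))
  list(ids = names(recs), seqs = unlist(recs, use.names = FALSE))
}

# ClustalW block format. Lines starting with whitespace are conservation
# annotation; a line's first token is the id, the second the sequence chunk;
# an optional trailing integer (cumulative residue count) is dropped.
read_msa_clustal <- function(lines, path) {
  if (!grepl("^CLUSTAL", lines[nzchar(trimws(lines))][1]))
    trmsd_error("format", sprintf("%s lacks a CLUSTAL header line", path))
  body <- lines[-match(TRUE, grepl("^CLUSTAL", lines))]
  ids <- character(0)
  seqs <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next  # blank or conservation
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2L)
      trmsd_error("format", sprintf("malformed CLUSTAL line in %s: %s", path, ln))
    if (length(tok) >= 3L && grepl("^[0-9]+$", tok[length(tok)]))
      tok <- tok[-length(tok)]
    id <- tok[1]
    chunk <- paste(tok[-1], collapse = "")
    i <- match(id, ids)
    if (is.na(i)) {
      ids <- c(ids, id)
      seqs <- c(seqs, chunk)
    } else {
      seqs[i] <- paste0(seqs[i], chunk)
    }
  }
  if (length(ids) == 0L)
    trmsd_error("format", sprintf("no sequences found in CLUSTAL file %s", path))
  list(ids = ids, seqs = seqs)
}

# Constructor + invariant checks shared by both formats.
new_msa <- function(ids, seqs) {
  seqs <- chartr(".", "-", toupper(seqs))
  if (any(duplicated(ids)))
    trmsd_error("duplicate_id", sprintf(
      "duplicate sequence id(s): %s", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(!nzchar(ids)) || any(grepl("\\s", ids)))
    trmsd_error("format", "sequence ids must be non-empty and contain no whitespace")
  if (length(ids) < 2L)
    trmsd_error("format", "an alignment needs at least 2 sequences")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    bad <- ids[len != stats::median(len)][1]
    trmsd_error("ragged_alignment", sprintf(
      "aligned rows differ in length (e.g. '%s' has %d columns, expected %d)",
      bad, nchar(seqs[match(bad, ids)]), as.integer(stats::median(len))))
  }
  if (len[1] < 1L) trmsd_error("format", "alignment has zero columns")
  structure(list(ids = ids, seqs = setNames(seqs, ids), length = len[1]),
            class = "trmsd_msa")
}

#' @export
print.trmsd_msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

# Alignment as a character matrix (rows = sequences, columns = positions).
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  rownames(m) <- msa$ids
  m
}

#' Write a multiple sequence alignment
#'
#' Writes a `trmsd_msa` to aligned FASTA (60 residues per line) or ClustalW
#' (blocks of 60 columns). `read_msa()` on the written file reproduces the
#' records exactly.
#'
#' @param msa A `trmsd_msa` object.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- unlist(lapply(msa$ids, function(id) {
      s <- msa$seqs[[id]]
      starts <- seq(1L, nchar(s), by = 60L)
      c(paste0(">", id), substring(s, starts, pmin(starts + 59L, nchar(s))))
    }))
  } else {
    width <- max(nchar(msa$ids)) + 4L
    starts <- seq(1L, msa$length, by = 60L)
    out <- "CLUSTAL W multiple sequence alignment"
    for (st in starts) {
      block <- vapply(msa$ids, function(id)
        paste0(formatC(id, width = -width),
               substr(msa$seqs[[id]], st, min(st + 59L, msa$length))),
        character(1))
      out <- c(out, "", block)
    }
  }
  writeLines(out, path)
  invisible(path)
}
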