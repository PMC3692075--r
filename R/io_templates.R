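#' Read a template list
#'
#' A template list associates each sequence identifier with the coordinate
#' file and chain that provide its 3-D evidence. Two dialects are accepted,
#' possibly mixed in one file:
#' \itemize{
#'   \item TSV (canonical): `seq_id<TAB>structure_path<TAB>chain_id`, with
#'     `#` comment lines skipped. Relative paths resolve against the
#'     directory of the template file.
#'   \item T-Coffee: `>seq_id _P_ pdbcode_chain` (or `pdbcodeC` with a
#'     single trailing chain letter), resolved to `pdbcode.pdb` inside
#'     `pdb_dir`.
#' }
#'
#' @param path Path to the template file.
#' @param pdb_dir Directory holding `<pdbcode>.pdb` files for the T-Coffee
#'   dialect; defaults to the template file's directory.
#' @return An object of class `trmsd_templates`: a data frame with columns
#'   `seq_id`, `structure_path`, `chain_id`.
#' @export
read_templates <- function(path, pdb_dir = dirname(path)) {
  if (!file.exists(path)) trmsd_error("io", sprintf("template file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    trmsd_error("format", sprintf("template file %s contains no entries", path))
  entries <- lapply(lines, function(ln) {
    ln <- trimws(ln)
    if (startsWith(ln, ">")) {
      tok <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
      if (length(tok) < 3L || tok[2] != "_P_")
        trmsd_error("format", sprintf("malformed T-Coffee template line: %s", ln))
      spec <- tok[3]
      if (grepl("_", spec)) {
        parts <- strsplit(spec, "_")[[1]]
        code <- paste(parts[-length(parts)], collapse = "_")
        chain <- parts[length(parts)]
      } else {
        code <- substr(spec, 1, nchar(spec) - 1L)
        chain <- substr(spec, nchar(spec), nchar(spec))
      }
      list(seq_id = tok[1],
           structure_path = file.path(pdb_dir, paste0(code, ".pdb")),
           chain_id = chain)
    } else {
      tok <- strsplit(ln, "\t")[[1]]
      if (length(tok) != 3L)
        trmsd_error("format", sprintf(
          "expected 3 tab-separated fields (seq_id, path, chain): %s", ln))
      p <- tok[2]
      if (!file.exists(p) && !grepl("^(/|[A-Za-z]:)", p))
        p <- file.path(dirname(path), p)
      list(seq_id = tok[1], structure_path = p, chain_id = tok[3])
    }
  })
  df <- do.call(rbind, lapply(entries, as.data.frame, stringsAsFactors = FALSE))
  if (any(duplicated(df$seq_id)))
    trmsd_error("duplicate_id", sprintf(
      "duplicate template entries for: %s",
      paste(unique(df$seq_id[duplicated(df$seq_id)]), collapse = ", ")))
  missing <- !file.exists(df$structure_path)
  if (any(missing))
    trmsd_error("path", sprintf(
      "structure file not found for sequence '%s': %s",
      df$seq_id[missing][1], df$structure_path[missing][1]))
  if (any(nchar(df$chain_id) != 1L))
    trmsd_error("format", "chain identifiers must be single characters")
  structure(df, class = c("trmsd_templates", "data.frame"))
}
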