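# Internal helpers: classed error conditions, amino-acid tables, label escaping.

# All user-facing failures are classed conditions so callers (and the CLI)
# can distinguish validation errors from internal ones.
trmsd_error <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("trmsd_", class), "trmsd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @importFrom stats setNames
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common nonstandard residues; anything else maps to the X wildcard
  MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", CME = "C"
)

AA1TO3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

aa_three_to_one <- function(res3) {
  out <- AA3TO1[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Two residue letters "match" if equal or either is the X wildcard.
aa_match <- function(a, b) a == b | a == "X" | b == "X"

# Newick label escaping: quote when the label contains characters outside
# the safe set, doubling embedded single quotes.
newick_escape <- function(label) {
  vapply(label, function(x) {
    if (grepl("^[A-Za-z0-9_.-]+$", x)) x
    else paste0("'", gsub("'", "''", x), "'")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
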