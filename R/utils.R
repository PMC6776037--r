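# Internal helpers shared across modules.

# IUPAC nucleotide alphabet (uppercase); ambiguity codes retained in sequences,
# downstream modules decide their own handling.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Evaluate code with a temporary, isolated RNG seed
#'
#' All stochastic operations in the package take an explicit seed and run
#' under an isolated RNG state, so no function touches the global random
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed for stage i of a seeded procedure,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

# Reverse complement of an ACGTN character string (fast path; ambiguity codes
# other than N are complemented via the full IUPAC map).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  rc <- chartr("ACGTUacgtuRYSWKMBDHVNryswkmbdhvn",
               "TGCAAtgcaaYRSWMKVHDBNyrswmkvhdbn", x)
  paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
}

# Uppercase and validate a nucleotide sequence against the IUPAC alphabet.
check_iupac <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seq))
  if (length(bad) > 0 && nzchar(bad)) {
    stop(sprintf("%s contains non-IUPAC character '%s'", what, bad), call. = FALSE)
  }
  seq
}

# Stable TSV writers so pipeline outputs are byte-identical across runs.
write_tsv_stable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_stable <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
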