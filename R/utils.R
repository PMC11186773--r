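# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x))
    stop(what, " contains characters outside {", alphabet, "}", call. = FALSE)
  invisible(x)
}

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
CODON_TABLE <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

translate_codon <- function(codon) {
  aa <- unname(CODON_TABLE[codon])
  ifelse(is.na(aa), "X", aa)
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Write a data.frame as a delimited table with '#'-prefixed metadata header
# lines (schema/coordinate-convention notes), readable back by read_table_meta.
write_table_meta <- function(df, path, meta = character(), sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_meta <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Seed handling: run `expr` under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
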