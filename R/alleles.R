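#' Default affine alignment scoring
#'
#' Match +2, mismatch -1, gap open -8, gap extend -1 per base (a length-L
#' gap costs 8 + L). `N` bases score as mismatches against everything,
#' including `N`.
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -1, gap_open = -8, gap_extend = -1)
}

# Substitution matrix over A/C/G/T/N for the scoring scheme above.
scoring_matrix <- function(scoring) {
  b <- c(DNA_BASES, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match
  m
}

#' Global alignment of reads against a reference amplicon
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring,
#' computed with [Biostrings::pairwiseAlignment()]. Tie-breaking among
#' co-optimal alignments is deterministic.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N).
#' @param ref Reference sequence (single string).
#' @param scoring Scoring scheme, see [default_scoring()].
#' @return A list of alignments; each element has `aligned_read`,
#'   `aligned_ref` (equal-length gapped strings) and `score`.
#' @examples
#' global_align("ACGT", "ACGT")[[1]]$score  # 8
#' @export
global_align <- function(reads, ref, scoring = default_scoring()) {
  if (length(reads) == 0L) stop("EmptyInput: no reads", call. = FALSE)
  if (any(!nzchar(reads)) || !nzchar(ref))
    stop("EmptyInput: empty sequence", call. = FALSE)
  pat <- Biostrings::DNAStringSet(reads)
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(ref), type = "global",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  ar <- as.character(Biostrings::alignedPattern(aln))
  as <- as.character(Biostrings::alignedSubject(aln))
  sc <- Biostrings::score(aln)
  lapply(seq_along(reads), function(i)
    structure(list(aligned_read = ar[i], aligned_ref = as[i], score = sc[i]),
              class = "beshield_alignment"))
}

#' Extract the window-restricted allele from one alignment
#'
#' Returns the read bases aligned to the window interval, reported in
#' protospacer orientation. Any gap column touching the window interior
#' (a deletion covering a window base, or an insertion between two window
#' bases) classifies the read as `"INDEL"`.
#'
#' @param aln One element of a [global_align()] result.
#' @param window An [resolve_window()] result (or a list with `start`,
#'   `end`, `strand`).
#' @return Window allele string, or `"INDEL"`.
#' @export
extract_window_allele <- function(aln, window) {
  rc <- chars(aln$aligned_ref)
  qc <- chars(aln$aligned_read)
  ref_pos <- cumsum(rc != "-")
  in_win <- rc != "-" & ref_pos >= window$start & ref_pos <= window$end
  ins_in_win <- rc == "-" & ref_pos >= window$start & ref_pos < window$end
  if (any(qc[in_win] == "-") || any(ins_in_win)) return("INDEL")
  allele <- paste(qc[in_win], collapse = "")
  if (identical(window$strand, "-")) allele <- revcomp(allele)
  allele
}

#' Build a window-restricted allele frequency table from merged reads
#'
#' Reads are filtered (length, N content), globally aligned to the amplicon,
#' screened for a minimum alignment score, and their quantification-window
#' alleles tabulated. Reads with any indel column inside the window form a
#' single `INDEL` class and remain in the frequency denominator. Alleles
#' below `other_threshold` are flagged `is_other` (pool them with
#' [pool_other_alleles()] for reporting); the flag never applies to the
#' `INDEL` class, which is its own category.
#'
#' @param reads Character vector of merged read sequences.
#' @param amplicon An [amplicon_ref()].
#' @param proto A [locate_protospacer()] result on that amplicon.
#' @param window Resolved window; default is the quantification window
#'   (centre -10, size 15) resolved against `proto`.
#' @param other_threshold Frequency below which an allele is flagged as
#'   "other" (default 0.008, i.e. the 0.8% rule).
#' @param scoring Alignment scoring, see [default_scoring()].
#' @param min_len Minimum read length; reads shorter are dropped (default:
#'   the window span).
#' @param max_n_frac Maximum fraction of `N` bases per read (default 0.05).
#' @param min_score_frac Reads aligning below this fraction of their perfect
#'   score are dropped as unalignable (default 0.6).
#' @return A data.frame of class `allele_table` with columns `allele`,
#'   `n_reads`, `frequency`, `is_indel`, `is_other`, and attributes
#'   `total_reads`, `ref_allele`, `window` and a `filter_log` recording
#'   (n_in, n_out, reason) for every filter step.
#' @export
build_allele_table <- function(reads, amplicon, proto, window = NULL,
                               other_threshold = 0.008,
                               scoring = default_scoring(),
                               min_len = NULL, max_n_frac = 0.05,
                               min_score_frac = 0.6) {
  if (length(reads) == 0L) stop("EmptyInput: zero reads", call. = FALSE)
  if (is.null(window))
    window <- resolve_window(window_spec(-10L, 15L, "quantification"),
                             proto, amplicon)
  if (is.null(min_len)) min_len <- window$end - window$start + 1L
  log <- list()
  note <- function(n_in, n_out, reason)
    log[[length(log) + 1L]] <<- data.frame(n_in = n_in, n_out = n_out,
                                           reason = reason)
  n0 <- length(reads)
  reads <- reads[nchar(reads) >= min_len]
  note(n0, length(reads), "min_read_length")
  n1 <- length(reads)
  nfrac <- vapply(reads, function(r)
    sum(chars(r) == "N") / nchar(r), numeric(1), USE.NAMES = FALSE)
  reads <- reads[nfrac <= max_n_frac]
  note(n1, length(reads), "max_n_fraction")
  if (length(reads) == 0L)
    stop("EmptyInput: no reads pass the input filters", call. = FALSE)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads),
    Biostrings::DNAString(amplicon$sequence), type = "global",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  scores <- Biostrings::score(aln)
  keep <- scores >= min_score_frac * scoring$match * nchar(reads)
  note(length(reads), sum(keep), "min_alignment_score")
  if (!any(keep))
    stop("EmptyInput: no reads aligned above the score threshold",
         call. = FALSE)
  aln <- aln[keep]

  # Fast window extraction: aligned() reports each read in reference
  # coordinates (deletions as '-', inserted bases dropped); the few reads
  # carrying insertions are re-extracted by the exact column walk.
  in_ref <- as.character(Biostrings::aligned(aln))
  alleles <- substr(in_ref, window$start, window$end)
  alleles[grepl("-", alleles, fixed = TRUE)] <- "INDEL"
  if (identical(window$strand, "-")) {
    flip <- alleles != "INDEL"
    alleles[flip] <- vapply(alleles[flip], revcomp, character(1),
                            USE.NAMES = FALSE)
  }
  has_ins <- S4Vectors::elementNROWS(
    Biostrings::insertion(Biostrings::indel(aln))) > 0L
  if (any(has_ins)) {
    sub <- aln[has_ins]
    ar <- as.character(Biostrings::alignedPattern(sub))
    as_ <- as.character(Biostrings::alignedSubject(sub))
    alleles[has_ins] <- vapply(seq_along(ar), function(i)
      extract_window_allele(list(aligned_read = ar[i],
                                 aligned_ref = as_[i]), window),
      character(1))
  }
  total <- length(alleles)
  counts <- sort(table(alleles), decreasing = TRUE)
  tab <- data.frame(allele = names(counts),
                    n_reads = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$frequency <- tab$n_reads / total
  tab$is_indel <- tab$allele == "INDEL"
  tab$is_other <- !tab$is_indel & tab$frequency < other_threshold
  ref_allele <- substr(amplicon$sequence, window$start, window$end)
  if (identical(window$strand, "-")) ref_allele <- revcomp(ref_allele)
  structure(tab, class = c("allele_table", "data.frame"),
            total_reads = total, ref_allele = ref_allele, window = window,
            other_threshold = other_threshold,
            filter_log = do.call(rbind, log))
}

#' Pool sub-threshold alleles into a single "other" row
#'
#' @param tab An [build_allele_table()] result.
#' @return An `allele_table` where all `is_other` rows are collapsed into
#'   one row with allele `"other"`.
#' @export
pool_other_alleles <- function(tab) {
  stopifnot(inherits(tab, "allele_table"))
  if (!any(tab$is_other)) return(tab)
  pooled <- tab[tab$is_other, , drop = FALSE]
  keep <- tab[!tab$is_other, , drop = FALSE]
  other <- data.frame(allele = "other", n_reads = sum(pooled$n_reads),
                      frequency = sum(pooled$frequency),
                      is_indel = FALSE, is_other = TRUE,
                      stringsAsFactors = FALSE)
  out <- rbind(keep, other)
  attributes(out)[c("total_reads", "ref_allele", "window",
                    "other_threshold", "filter_log")] <-
    attributes(tab)[c("total_reads", "ref_allele", "window",
                      "other_threshold", "filter_log")]
  class(out) <- class(tab)
  rownames(out) <- NULL
  out
}

#' Write an allele table as TSV with a metadata header
#'
#' @param tab An `allele_table`.
#' @param path Output path.
#' @export
write_allele_table <- function(tab, path) {
  w <- attr(tab, "window")
  meta <- c("beshield allele table v1",
            "coordinates: 1-based closed; alleles in protospacer orientation",
            sprintf("window: amplicon %d-%d strand %s", w$start, w$end,
                    w$strand),
            sprintf("total_reads: %d", attr(tab, "total_reads")),
            sprintf("ref_allele: %s", attr(tab, "ref_allele")))
  write_table_meta(as.data.frame(tab), path, meta = meta)
}

#' Import a CRISPResso2-style allele frequency table
#'
#' Reads the `Alleles_frequency_table.txt` dialect: tab-separated with an
#' aligned-sequence column, a read-count column (`#Reads`) and a percent
#' column (`%Reads`). Rows whose aligned sequence contains `-`, or whose
#' `n_deleted`/`n_inserted` columns are positive, are classed as `INDEL`.
#'
#' @param path Path to the table.
#' @param other_threshold Frequency below which alleles are flagged
#'   `is_other` (default 0.008).
#' @return An `allele_table` (window metadata unavailable from this format).
#' @export
read_crispresso_alleles <- function(path, other_threshold = 0.008) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  nm <- names(df)
  seq_col <- nm[grepl("aligned", nm, ignore.case = TRUE)][1L]
  cnt_col <- nm[grepl("^#?\\s*Reads$|n_reads", nm, ignore.case = TRUE)][1L]
  if (is.na(seq_col) || is.na(cnt_col))
    stop("unrecognized allele-table dialect: need an aligned-sequence and ",
         "a read-count column", call. = FALSE)
  alleles <- toupper(df[[seq_col]])
  indel <- grepl("-", alleles, fixed = TRUE)
  for (col in c("n_deleted", "n_inserted"))
    if (col %in% nm) indel <- indel | df[[col]] > 0
  alleles[indel] <- "INDEL"
  agg <- stats::aggregate(list(n_reads = df[[cnt_col]]),
                          by = list(allele = alleles), FUN = sum)
  total <- sum(agg$n_reads)
  tab <- agg[order(-agg$n_reads), , drop = FALSE]
  tab$frequency <- tab$n_reads / total
  tab$is_indel <- tab$allele == "INDEL"
  tab$is_other <- !tab$is_indel & tab$frequency < other_threshold
  rownames(tab) <- NULL
  structure(tab, class = c("allele_table", "data.frame"),
            total_reads = total, ref_allele = NA_character_, window = NULL,
            other_threshold = other_threshold, filter_log = NULL)
}

#' Read merged reads from a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file with constant quality
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path (`.gz` suffix gzips).
#' @param qual Single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           vapply(nchar(reads), function(n)
                             strrep(qual, n), character(1))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
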