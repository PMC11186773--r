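# Base-editor outcome enumeration and the screening score.

#' Base-editor chemistry and editing window
#'
#' ABE converts A to G and CBE converts C to T, both defined on the
#' protospacer strand within a protospacer-relative editing window
#' (default positions 3--10, a conventional adenine-editor window;
#' configurable per editor).
#'
#' @param chemistry `"ABE"` (A>G) or `"CBE"` (C>T).
#' @param window Integer vector `c(lo, hi)` of protospacer positions.
#' @return An object of class `editor_spec`.
#' @export
editor_spec <- function(chemistry = c("ABE", "CBE"), window = c(3L, 10L)) {
  chemistry <- match.arg(chemistry)
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1L] <= window[2L], window[1L] >= 1L)
  src <- if (chemistry == "ABE") "A" else "C"
  tgt <- if (chemistry == "ABE") "G" else "T"
  structure(list(chemistry = chemistry, source = src, target = tgt,
                 window = window),
            class = "editor_spec")
}

#' Enumerate codon-level base-editing outcomes
#'
#' Finds every editable base (the editor's source base, read on the
#' protospacer strand) inside the editing window, enumerates all `2^k`
#' combinations of converting them, translates each combination, and
#' deduplicates by substitution set. This captures the intended edit and
#' every bystander combination (e.g. an AAG lysine codon with both
#' adenines editable yields the E/R/G substitution trio).
#'
#' @param amplicon An [amplicon_ref()].
#' @param proto A [locate_protospacer()] result.
#' @param editor An [editor_spec()].
#' @param map The amplicon's [build_codon_map()].
#' @param max_editable Cap on the number of editable bases (default 16);
#'   exceeding it raises an error rather than enumerating silently.
#' @return A data.frame of class `edit_outcomes`, one row per distinct
#'   substitution set: `genotype`, `n_variants` (number of nucleotide
#'   genotypes collapsing onto it), `min_edits`, and `alleles`
#'   (comma-separated edited window sequences in protospacer orientation).
#'   Attribute `editable_positions` records the protospacer positions used.
#' @export
enumerate_edit_outcomes <- function(amplicon, proto, editor, map,
                                    max_editable = 16L) {
  stopifnot(inherits(editor, "editor_spec"))
  win_pos <- editor$window[1L]:editor$window[2L]
  amp_pos <- proto_to_amp(proto, win_pos)
  if (any(amp_pos < 1L | amp_pos > nchar(amplicon$sequence)))
    stop("OutOfBounds: editing window extends beyond the amplicon",
         call. = FALSE)
  amp_base <- vapply(amp_pos, function(p)
    substr(amplicon$sequence, p, p), character(1))
  proto_base <- if (proto$strand == "-") complement_base(amp_base) else amp_base
  editable <- win_pos[proto_base == editor$source]
  k <- length(editable)
  if (k > max_editable)
    stop("TooManyOutcomes: ", k, " editable bases exceed the cap of ",
         max_editable, call. = FALSE)
  # amplicon-strand replacement base at each editable position
  amp_target <- if (proto$strand == "-") complement_base(editor$target)
                else editor$target
  edit_amp_pos <- proto_to_amp(proto, editable)

  window_slice <- function(seq) {
    s <- paste(vapply(amp_pos, function(p) substr(seq, p, p), character(1)),
               collapse = "")
    if (proto$strand == "-") revcomp(s) else s
  }
  n_sets <- 2L^k
  res <- vector("list", n_sets)
  for (mask in seq_len(n_sets) - 1L) {
    on <- if (k) which(bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L) else integer()
    mut <- amplicon$sequence
    for (i in on)
      substr(mut, edit_amp_pos[i], edit_amp_pos[i]) <- amp_target
    res[[mask + 1L]] <- data.frame(
      genotype = genotype_of_mutation(mut, amplicon, map),
      n_edits = length(on),
      allele = window_slice(mut),
      stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, res)
  out <- do.call(rbind, lapply(split(all_rows, all_rows$genotype), function(g)
    data.frame(genotype = g$genotype[1L], n_variants = nrow(g),
               min_edits = min(g$n_edits),
               alleles = paste(unique(g$allele), collapse = ","),
               stringsAsFactors = FALSE)))
  out <- out[order(out$min_edits, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("edit_outcomes", "data.frame"),
            editable_positions = editable, editor = editor)
}

#' Base-editing screening score
#'
#' `score = log((sum of editing frequencies / number of edited positions) + 1)`
#' for one condition (editor x sgRNA), where "edited positions" are those
#' with a nonzero measured frequency. Defined as 0 when no position is
#' edited. Frequencies are percentages (0--100), as reported by
#' chromatogram deconvolution or NGS. The logarithm base defaults to 10;
#' the score is used for ranking conditions, which is base-invariant.
#'
#' @param freqs Numeric vector of per-position editing frequencies in
#'   percent (0--100).
#' @param base Logarithm base (default 10).
#' @return A single non-negative score, bounded by `log(101, base)`.
#' @examples
#' be_score(c(10, 20))  # log10(16) ~ 1.204
#' be_score(c(0, 0))    # 0
#' @export
be_score <- function(freqs, base = 10) {
  if (!is.numeric(freqs) || any(is.na(freqs)) ||
      any(freqs < 0 | freqs > 100))
    stop("editing frequencies must be percentages in [0, 100]",
         call. = FALSE)
  n_edited <- sum(freqs > 0)
  if (n_edited == 0L) return(0)
  log(sum(freqs) / n_edited + 1, base = base)
}

#' Score a table of per-position editing frequencies by condition
#'
#' @param df Data.frame with columns `condition` and `frequency` (percent);
#'   one row per editable position per condition.
#' @param base Logarithm base passed to [be_score()].
#' @return Data.frame with columns `condition` and `be_score`, sorted by
#'   decreasing score.
#' @export
be_score_table <- function(df, base = 10) {
  stopifnot(all(c("condition", "frequency") %in% names(df)))
  out <- do.call(rbind, lapply(split(df, df$condition), function(g)
    data.frame(condition = g$condition[1L],
               be_score = be_score(g$frequency, base = base),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$be_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
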