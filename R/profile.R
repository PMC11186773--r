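# Translate window alleles into named amino-acid substitution genotypes
# and aggregate them into a substitution profile.

# Genotype string for a fully mutated amplicon sequence vs. the reference,
# over the residues in `residues` (default: all codon-mapped residues).
# Returns "WT" (no nucleotide change), "silent" (changes, all synonymous)
# or canonically ordered substitutions like "N351S+K352G".
genotype_of_mutation <- function(mut_seq, amplicon, map,
                                 residues = NULL) {
  if (is.null(residues)) residues <- unique(map$residue)
  ref <- amplicon$sequence
  any_nt_change <- FALSE
  subs <- character()
  sub_res <- integer()
  for (r in sort(residues)) {
    pos <- residue_codon_positions(map, r)
    rb <- vapply(pos, function(p) substr(ref, p, p), character(1))
    mb <- vapply(pos, function(p) substr(mut_seq, p, p), character(1))
    if (identical(rb, mb)) next
    any_nt_change <- TRUE
    if (attr(map, "cds_strand") == "-") {
      rb <- complement_base(rb); mb <- complement_base(mb)
    }
    ref_aa <- translate_codon(paste(rb, collapse = ""))
    mut_aa <- translate_codon(paste(mb, collapse = ""))
    if (!identical(ref_aa, mut_aa)) {
      subs <- c(subs, sprintf("%s%d%s", ref_aa, r, mut_aa))
      sub_res <- c(sub_res, r)
    }
  }
  if (length(subs)) paste(subs[order(sub_res)], collapse = "+")
  else if (any_nt_change) "silent"
  else "WT"
}

#' Translate a window allele into a substitution genotype
#'
#' Substitutes the window allele back into the reference amplicon and
#' translates every codon overlapping the window under the standard genetic
#' code; codons only partially covered by the window are completed with
#' reference bases. Substitutions are named `<refAA><residue><altAA>`,
#' canonically ordered by residue number and joined with `+`.
#'
#' @param allele Window allele string in protospacer orientation (same
#'   length as the window).
#' @param amplicon The [amplicon_ref()].
#' @param window The resolved quantification window ([resolve_window()]).
#' @param map The amplicon's [build_codon_map()].
#' @return `"WT"` if the allele equals the reference window, `"silent"` if
#'   all changes are synonymous, otherwise a genotype string such as
#'   `"K352E"` or `"N351S+K352G"`.
#' @examples
#' # see aggregate_profile() for a full pipeline example
#' @export
translate_window_allele <- function(allele, amplicon, window, map) {
  span <- window$end - window$start + 1L
  if (nchar(allele) != span)
    stop("allele length ", nchar(allele), " does not match window span ",
         span, call. = FALSE)
  if (grepl("N", allele, fixed = TRUE))
    stop("Untranslatable: allele contains N", call. = FALSE)
  amp_allele <- if (identical(window$strand, "-")) revcomp(allele) else allele
  mut <- paste0(substr(amplicon$sequence, 1L, window$start - 1L), amp_allele,
                substr(amplicon$sequence, window$end + 1L,
                       nchar(amplicon$sequence)))
  residues <- unique(map$residue[map$amp_pos >= window$start &
                                   map$amp_pos <= window$end])
  if (length(residues) == 0L)
    stop("window does not overlap the coding sequence", call. = FALSE)
  genotype_of_mutation(mut, amplicon, map, residues)
}

#' Aggregate an allele table into an amino-acid substitution profile
#'
#' Each window allele is translated with [translate_window_allele()];
#' alleles mapping to the same substitution set are merged, then genotypes
#' below `other_threshold` are pooled into `"others"`. `INDEL` rows keep
#' their own class, untranslatable alleles (containing `N`) are routed to
#' `"others"`, and `"silent"` is reported separately from `"WT"`.
#'
#' @param tab An [build_allele_table()] result (or imported dialect).
#' @param amplicon,map The amplicon and its codon map.
#' @param window Resolved window; defaults to the table's `window`
#'   attribute.
#' @param other_threshold Pooling threshold (default 0.008).
#' @param merge_first If `TRUE` (default) merge alleles by genotype before
#'   thresholding; if `FALSE` apply the allele-level threshold first.
#' @param sample_id Optional provenance string stored on the result.
#' @return A data.frame of class `substitution_profile` with columns
#'   `genotype`, `frequency`, `n_reads`, ordered by decreasing frequency.
#' @export
aggregate_profile <- function(tab, amplicon, map, window = NULL,
                              other_threshold = 0.008, merge_first = TRUE,
                              sample_id = NA_character_) {
  stopifnot(inherits(tab, "allele_table"))
  if (is.null(window)) window <- attr(tab, "window")
  if (is.null(window))
    stop("no window available: pass `window` for imported tables",
         call. = FALSE)
  rows <- as.data.frame(tab)
  if (!merge_first && any(rows$is_other)) {
    pooled <- pool_other_alleles(tab)
    rows <- as.data.frame(pooled)
  }
  genotype <- vapply(seq_len(nrow(rows)), function(i) {
    a <- rows$allele[i]
    if (identical(a, "INDEL")) return("INDEL")
    if (identical(a, "other")) return("others")
    tryCatch(translate_window_allele(a, amplicon, window, map),
             error = function(e) "others")
  }, character(1))
  agg <- stats::aggregate(rows[c("frequency", "n_reads")],
                          by = list(genotype = genotype), FUN = sum)
  # pool sub-threshold genotypes into "others" (never the INDEL class)
  minor <- agg$frequency < other_threshold & agg$genotype != "INDEL"
  if (any(minor)) {
    others <- data.frame(genotype = "others",
                         frequency = sum(agg$frequency[minor]),
                         n_reads = sum(agg$n_reads[minor]))
    agg <- rbind(agg[!minor, , drop = FALSE], others)
    agg <- stats::aggregate(agg[c("frequency", "n_reads")],
                            by = list(genotype = agg$genotype), FUN = sum)
  }
  agg <- agg[order(-agg$frequency, agg$genotype), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("substitution_profile", "data.frame"),
            sample_id = sample_id, total_reads = attr(tab, "total_reads"),
            other_threshold = other_threshold)
}

#' Write a substitution profile as TSV
#'
#' @param profile A `substitution_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  meta <- c("beshield substitution profile v1",
            sprintf("sample: %s", attr(profile, "sample_id")),
            sprintf("total_reads: %s", attr(profile, "total_reads")),
            sprintf("other_threshold: %s", attr(profile, "other_threshold")))
  write_table_meta(as.data.frame(profile), path, meta = meta)
}
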