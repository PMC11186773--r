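# Off-target editing validation: windowed per-read edit calls, 2x2
# chi-squared tests against matched controls, BH FDR, dual criterion.

#' Classify one aligned read as edited or not
#'
#' A read is edited when it carries at least one source-to-target
#' conversion (protospacer-strand orientation) within the scoring window
#' (default protospacer positions 4--10). Reads whose alignment does not
#' cover the whole window with called bases are uncallable and return `NA`
#' (exclude them from both numerator and denominator).
#'
#' @param aln One element of a [global_align()] result against the site's
#'   amplicon.
#' @param proto The site's [locate_protospacer()] result.
#' @param positions Protospacer positions scored (default `4:10`).
#' @param source,target Conversion chemistry on the protospacer strand
#'   (default A>G, adenine editing).
#' @return `TRUE`, `FALSE`, or `NA` (uncallable).
#' @export
classify_read_edited <- function(aln, proto, positions = 4:10,
                                 source = "A", target = "G") {
  amp_pos <- proto_to_amp(proto, positions)
  rc <- chars(aln$aligned_ref)
  qc <- chars(aln$aligned_read)
  ref_idx <- cumsum(rc != "-")
  cols <- match(amp_pos, ifelse(rc == "-", NA_integer_, ref_idx))
  if (anyNA(cols)) return(NA)
  rb <- rc[cols]; qb <- qc[cols]
  if (any(qb == "-" | qb == "N")) return(NA)
  if (proto$strand == "-") {
    rb <- complement_base(rb); qb <- complement_base(qb)
  }
  any(rb == source & qb == target)
}

#' Editing frequency in percent
#'
#' @param edited,total Read counts; `total` must be positive.
#' @return `100 * edited / total`.
#' @export
editing_frequency <- function(edited, total) {
  if (any(total <= 0)) stop("Uncallable: total reads must be > 0",
                            call. = FALSE)
  if (any(edited < 0 | edited > total))
    stop("edited must lie in [0, total]", call. = FALSE)
  100 * edited / total
}

#' Pearson chi-squared test on a 2x2 edited/unedited table
#'
#' Closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom and no continuity correction; the p-value is the upper tail of
#' chi-squared(1). A zero margin (e.g. no edited reads in either sample)
#' returns `chi2 = 0, p = 1` by convention.
#'
#' @param treated,control Length-2 integer vectors `c(edited, unedited)`.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(treated, control) {
  stopifnot(length(treated) == 2L, length(control) == 2L)
  # doubles throughout: integer counts overflow in n * (ad - bc)^2
  a <- as.numeric(treated[1L]); b <- as.numeric(treated[2L])
  c_ <- as.numeric(control[1L]); d <- as.numeric(control[2L])
  if (any(c(a, b, c_, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (a + b == 0 || c_ + d == 0)
    stop("both samples need at least one read", call. = FALSE)
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(list(statistic = 0, p_value = 1))
  chi2 <- n * (a * d - b * c_)^2 / denom
  list(statistic = chi2,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, mapped back to input order and
#' capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("InvalidInput: p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the dual off-target significance criterion
#'
#' A site is validated when both `fdr <= fdr_max` and the editing-frequency
#' difference `delta = f_treated - f_control` (percentage points) is at
#' least `delta_min`.
#'
#' @param verdicts Data.frame with columns `fdr` and `delta`.
#' @param fdr_max FDR ceiling (default 0.05).
#' @param delta_min Minimum editing-frequency difference in percentage
#'   points (default 1).
#' @return The input with a logical `validated` column set/overwritten.
#' @export
validate_sites <- function(verdicts, fdr_max = 0.05, delta_min = 1) {
  stopifnot(all(c("fdr", "delta") %in% names(verdicts)))
  verdicts$validated <- verdicts$fdr <= fdr_max & verdicts$delta >= delta_min
  verdicts
}

#' Full off-target verdict table from per-site counts
#'
#' Computes treated/control editing frequencies, their difference, the 2x2
#' chi-squared test per site, BH FDR across all sites of the comparison
#' (one treated sample against its matched control), and the dual
#' significance criterion.
#'
#' @param counts Data.frame with columns `site_id`, `treated_edited`,
#'   `treated_total`, `control_edited`, `control_total`.
#' @param fdr_max,delta_min Dual-criterion thresholds (defaults 0.05 and 1
#'   percentage point).
#' @return Data.frame of class `site_verdicts`: `site_id`, `f_treated`,
#'   `f_control`, `delta` (percentage points), `chi2`, `p`, `fdr`,
#'   `validated`.
#' @export
offtarget_verdicts <- function(counts, fdr_max = 0.05, delta_min = 1) {
  need <- c("site_id", "treated_edited", "treated_total",
            "control_edited", "control_total")
  stopifnot(all(need %in% names(counts)))
  tests <- lapply(seq_len(nrow(counts)), function(i) {
    tr <- c(counts$treated_edited[i],
            counts$treated_total[i] - counts$treated_edited[i])
    ct <- c(counts$control_edited[i],
            counts$control_total[i] - counts$control_edited[i])
    chisq_2x2(tr, ct)
  })
  out <- data.frame(
    site_id = counts$site_id,
    f_treated = editing_frequency(counts$treated_edited,
                                  counts$treated_total),
    f_control = editing_frequency(counts$control_edited,
                                  counts$control_total),
    stringsAsFactors = FALSE)
  out$delta <- out$f_treated - out$f_control
  out$chi2 <- vapply(tests, `[[`, numeric(1), "statistic")
  out$p <- vapply(tests, `[[`, numeric(1), "p_value")
  out$fdr <- bh_fdr(out$p)
  out <- validate_sites(out, fdr_max = fdr_max, delta_min = delta_min)
  structure(out, class = c("site_verdicts", "data.frame"),
            fdr_max = fdr_max, delta_min = delta_min)
}

#' Configuration preset for pooled base-editor amplicon quantification
#'
#' Named preset mirroring the pooled-quantification settings used for
#' off-target count generation: window size 10 centred at -10, base-editor
#' output with A>G conversion scoring.
#'
#' @return Named list of settings.
#' @export
offtarget_count_preset <- function() {
  list(quantification_window_size = 10L,
       quantification_window_center = -10L,
       base_editor_output = TRUE,
       conversion_nuc_from = "A",
       conversion_nuc_to = "G",
       scoring_positions = 4:10)
}

#' Read per-site off-target counts from CSV
#'
#' Expected columns: `site_id`, `treated_edited`, `treated_total`,
#' `control_edited`, `control_total`.
#'
#' @param path CSV path.
#' @return Data.frame of counts.
#' @export
read_site_counts <- function(path) {
  read_table_meta(path, sep = ",")
}

#' Write a site verdict table as CSV
#'
#' @param verdicts An [offtarget_verdicts()] result.
#' @param path Output path.
#' @export
write_site_verdicts <- function(verdicts, path) {
  meta <- c("beshield off-target site verdicts v1",
            sprintf("dual criterion: FDR <= %s and delta >= %s percentage points",
                    attr(verdicts, "fdr_max"), attr(verdicts, "delta_min")))
  write_table_meta(as.data.frame(verdicts), path, meta = meta, sep = ",")
}
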