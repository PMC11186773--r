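# Donor chimerism from polymorphic indel-marker read counts.

#' Select informative markers for a donor pair
#'
#' A marker discriminates two donors when exactly one of them carries the
#' marker allele; the direction (which donor is allele-positive) is
#' recorded so marker-specific reads can be attributed.
#'
#' @param genotypes Data.frame with columns `marker`, `donor_a`, `donor_b`
#'   (logical or 0/1 allele presence).
#' @return Data.frame `marker`, `informative`, `informative_for` (`"A"`,
#'   `"B"`, or `NA`).
#' @export
select_informative_markers <- function(genotypes) {
  stopifnot(all(c("marker", "donor_a", "donor_b") %in% names(genotypes)))
  a <- as.logical(genotypes$donor_a)
  b <- as.logical(genotypes$donor_b)
  if (anyNA(a) || anyNA(b))
    stop("MissingGenotype: both donors need a genotype at every marker",
         call. = FALSE)
  inf <- xor(a, b)
  data.frame(marker = genotypes$marker, informative = inf,
             informative_for = ifelse(!inf, NA_character_,
                                      ifelse(a, "A", "B")),
             stringsAsFactors = FALSE)
}

#' Estimate the donor fraction from informative-marker read counts
#'
#' The donor fraction is the unweighted mean, across informative markers,
#' of the per-marker proportion of donor-specific reads among total reads
#' ("average proportion"); a depth-weighted mean is available as an
#' option. Per-marker proportions and their standard deviation are
#' reported alongside the estimate.
#'
#' @param counts Data.frame with columns `marker`, `donor_reads`,
#'   `total_reads` restricted to informative markers.
#' @param weighted If `TRUE`, weight markers by total read depth.
#' @param min_total_warn Warn when any marker's total is below this
#'   (default 100), a hint that host reads were not excluded upstream or
#'   amplification failed.
#' @return An object of class `chimerism_estimate`: list with `estimate`
#'   (in `[0, 1]`), `sd` (across markers), `n_markers`, and `per_marker`
#'   (data.frame with `proportion` per marker).
#' @export
estimate_donor_fraction <- function(counts, weighted = FALSE,
                                    min_total_warn = 100) {
  stopifnot(all(c("marker", "donor_reads", "total_reads") %in%
                  names(counts)))
  usable <- counts$total_reads > 0
  if (!any(usable))
    stop("Uncallable: no informative marker has reads", call. = FALSE)
  counts <- counts[usable, , drop = FALSE]
  if (any(counts$donor_reads < 0 | counts$donor_reads > counts$total_reads))
    stop("donor-specific reads must lie in [0, total]", call. = FALSE)
  if (any(counts$total_reads < min_total_warn))
    warning("some markers have implausibly low total read counts (< ",
            min_total_warn, ")", call. = FALSE)
  prop <- counts$donor_reads / counts$total_reads
  est <- if (weighted) stats::weighted.mean(prop, counts$total_reads)
         else mean(prop)
  structure(list(estimate = est,
                 sd = stats::sd(prop),
                 n_markers = nrow(counts),
                 per_marker = data.frame(marker = counts$marker,
                                         proportion = prop,
                                         total_reads = counts$total_reads,
                                         stringsAsFactors = FALSE)),
            class = "chimerism_estimate")
}

#' @export
print.chimerism_estimate <- function(x, ...) {
  cat(sprintf("<chimerism_estimate> donor fraction %.4f (s.d. %.4f across %d markers)\n",
              x$estimate, ifelse(is.na(x$sd), 0, x$sd), x$n_markers))
  invisible(x)
}

#' Read marker genotype or count tables from CSV
#'
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_marker_table <- function(path) {
  read_table_meta(path, sep = ",")
}

#' Write a chimerism estimate report as CSV
#'
#' One summary row followed by per-marker proportions.
#'
#' @param est An [estimate_donor_fraction()] result.
#' @param path Output path.
#' @export
write_chimerism_estimate <- function(est, path) {
  df <- rbind(
    data.frame(marker = "ESTIMATE", proportion = est$estimate,
               total_reads = sum(est$per_marker$total_reads)),
    est$per_marker)
  meta <- c("beshield chimerism estimate v1",
            sprintf("estimate: %.6f (unweighted mean over %d markers, s.d. %.6f)",
                    est$estimate, est$n_markers,
                    ifelse(is.na(est$sd), 0, est$sd)))
  write_table_meta(df, path, meta = meta, sep = ",")
}
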