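# Alanine-scan epitope calling from a variant x antibody binding matrix.

#' Call candidate epitope residues from an alanine-scan binding matrix
#'
#' A residue is a candidate epitope residue for antibody `m` when its
#' alanine variant retains at most `lo` percent residual binding for `m`
#' while at least one other antibody retains more than `hi` percent
#' (the other antibodies act as expression/folding controls). Residues
#' whose alanine variant loses binding for *all* antibodies are excluded:
#' such global loss likely reflects altered structure, conformation or
#' expression rather than a true epitope.
#'
#' @param matrix Data.frame with columns `residue`, `wt_aa`, then one
#'   numeric column per antibody with residual binding as percent of the
#'   wild-type signal (at least two antibody columns).
#' @param lo Low-binding threshold in percent (default 20). With
#'   `inclusive = TRUE` the test is `<= lo` ("up to 20%"); with `FALSE`
#'   it is `< lo` (the strict reading).
#' @param hi Control threshold in percent (default 70, tested as `> hi`).
#' @param inclusive Use `<= lo` (default) rather than `< lo`.
#' @return An object of class `epitope_calls`: list with `candidates`
#'   (data.frame `residue`, `wt_aa`, `mab`, `binding`), `excluded`
#'   (residues failing all antibodies) and `no_call`.
#' @export
call_epitope_residues <- function(matrix, lo = 20, hi = 70,
                                  inclusive = TRUE) {
  stopifnot(is.data.frame(matrix),
            all(c("residue", "wt_aa") %in% names(matrix)))
  mabs <- setdiff(names(matrix), c("residue", "wt_aa"))
  if (length(mabs) < 2L)
    stop("InsufficientControls: need at least two antibody columns",
         call. = FALSE)
  if (anyDuplicated(matrix$residue))
    stop("residue identifiers must be unique", call. = FALSE)
  vals <- as.matrix(matrix[mabs])
  if (any(vals < 0)) stop("binding values must be >= 0", call. = FALSE)
  is_low <- if (inclusive) vals <= lo else vals < lo
  is_ctrl <- vals > hi
  all_lost <- rowSums(is_low) == length(mabs)
  cand <- list()
  for (m in mabs) {
    other_ok <- rowSums(is_ctrl[, setdiff(mabs, m), drop = FALSE]) > 0
    hit <- is_low[, m] & other_ok & !all_lost
    if (any(hit))
      cand[[m]] <- data.frame(residue = matrix$residue[hit],
                              wt_aa = matrix$wt_aa[hit], mab = m,
                              binding = vals[hit, m],
                              stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand)) do.call(rbind, cand)
                else data.frame(residue = integer(), wt_aa = character(),
                                mab = character(), binding = numeric())
  rownames(candidates) <- NULL
  called <- unique(candidates$residue)
  structure(list(candidates = candidates,
                 excluded = matrix$residue[all_lost],
                 no_call = setdiff(matrix$residue,
                                   c(called, matrix$residue[all_lost]))),
            class = "epitope_calls", lo = lo, hi = hi,
            inclusive = inclusive)
}

#' @export
print.epitope_calls <- function(x, ...) {
  cat(sprintf("<epitope_calls> %d candidate calls, %d excluded (global loss), %d no-call\n",
              nrow(x$candidates), length(x$excluded), length(x$no_call)))
  invisible(x)
}

#' Filter and flag candidate epitope residues with structural annotations
#'
#' Applies the residue-level exclusion rules: cysteines are removed
#' (disulfide bridges), residues annotated as post-translationally modified
#' or involved in domain-domain interfaces are removed, and buried residues
#' (surface accessibility below `buried_max`) are flagged as likely
#' indirect ("false positive") rather than true epitope residues.
#'
#' @param candidates The `candidates` data.frame of an
#'   [call_epitope_residues()] result (or the result itself).
#' @param annotations Data.frame with columns `residue`,
#'   `surface_accessibility` (percent), `is_cysteine`, `ptm_or_interface`.
#' @param buried_max Accessibility below which a residue is flagged buried
#'   (default 10 percent).
#' @return List with `retained` (data.frame of kept candidate calls) and
#'   `flagged` (data.frame `residue`, `mab`, `reason` with reason codes
#'   `cysteine`, `ptm_or_interface`, `buried_indirect`).
#' @export
prioritize_residues <- function(candidates, annotations, buried_max = 10) {
  if (inherits(candidates, "epitope_calls"))
    candidates <- candidates$candidates
  stopifnot(all(c("residue", "mab") %in% names(candidates)),
            all(c("residue", "surface_accessibility", "is_cysteine",
                  "ptm_or_interface") %in% names(annotations)))
  idx <- match(candidates$residue, annotations$residue)
  if (anyNA(idx))
    stop("MissingAnnotation: residues ",
         paste(unique(candidates$residue[is.na(idx)]), collapse = ", "),
         " have no annotation", call. = FALSE)
  ann <- annotations[idx, , drop = FALSE]
  reason <- rep(NA_character_, nrow(candidates))
  reason[ann$surface_accessibility < buried_max] <- "buried_indirect"
  reason[ann$ptm_or_interface] <- "ptm_or_interface"
  reason[ann$is_cysteine | candidates$wt_aa == "C"] <- "cysteine"
  keep <- is.na(reason)
  retained <- candidates[keep, , drop = FALSE]
  retained$surface_accessibility <- ann$surface_accessibility[keep]
  flagged <- data.frame(residue = candidates$residue[!keep],
                        mab = candidates$mab[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(retained) <- rownames(flagged) <- NULL
  list(retained = retained, flagged = flagged)
}

#' Read an alanine-scan binding matrix from CSV
#'
#' Expected columns: `residue`, `wt_aa`, then one column per antibody.
#'
#' @param path CSV path.
#' @return Data.frame usable by [call_epitope_residues()].
#' @export
read_binding_matrix <- function(path) {
  read_table_meta(path, sep = ",")
}

#' Write epitope calls (with optional prioritization) as CSV
#'
#' @param calls An [call_epitope_residues()] result.
#' @param path Output path.
#' @param prioritized Optional [prioritize_residues()] result; if given,
#'   reason codes are joined onto the candidate rows.
#' @export
write_epitope_calls <- function(calls, path, prioritized = NULL) {
  df <- calls$candidates
  df$status <- "candidate"
  if (!is.null(prioritized)) {
    key <- paste(df$residue, df$mab)
    fk <- paste(prioritized$flagged$residue, prioritized$flagged$mab)
    hit <- match(key, fk)
    df$status[!is.na(hit)] <- prioritized$flagged$reason[hit[!is.na(hit)]]
  }
  if (length(calls$excluded))
    df <- rbind(df, data.frame(residue = calls$excluded, wt_aa = NA,
                               mab = NA, binding = NA,
                               status = "excluded_global_loss"))
  meta <- c("beshield epitope calls v1",
            sprintf("thresholds: low %s%%%s, control > %s%%",
                    attr(calls, "lo"),
                    if (attr(calls, "inclusive")) " (inclusive)" else "",
                    attr(calls, "hi")))
  write_table_meta(df, path, meta = meta, sep = ",")
}
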