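# Synthetic-data generators: every pipeline input with known ground truth,
# byte-reproducible under a fixed seed.

#' Simulate amplicon sequencing reads from a known allele spectrum
#'
#' Reads are drawn multinomially from the spectrum and uniform per-base
#' substitution errors are applied (an erroneous base becomes one of the
#' three other bases with equal probability). No indel errors are
#' simulated by default; `indel_rate` introduces single-base deletions to
#' exercise the INDEL class.
#'
#' @param spectrum Data.frame with columns `label`, `sequence` (full
#'   amplicon allele) and `freq` (summing to 1), e.g.
#'   [cd45_demo_spectrum()].
#' @param n_reads Number of reads (default 10000).
#' @param error_rate Per-base substitution error probability (default
#'   0.001, i.e. 0.1%).
#' @param indel_rate Per-read probability of a single-base deletion at a
#'   uniform position (default 0).
#' @param seed Integer seed; identical seeds give identical reads.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `id`, `label` recording each read's source genotype).
#' @export
simulate_amplicon_reads <- function(spectrum, n_reads = 10000L,
                                    error_rate = 0.001, indel_rate = 0,
                                    seed = NULL) {
  stopifnot(all(c("label", "sequence", "freq") %in% names(spectrum)))
  if (abs(sum(spectrum$freq) - 1) > 1e-9)
    stop("InvalidSpec: spectrum frequencies must sum to 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 1 || indel_rate < 0 || indel_rate > 1)
    stop("InvalidSpec: rates must lie in [0, 1]", call. = FALSE)
  lens <- unique(nchar(spectrum$sequence))
  if (length(lens) != 1L)
    stop("InvalidSpec: substitution alleles must share the amplicon length",
         call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(spectrum), n_reads, replace = TRUE,
                      prob = spectrum$freq)
    allele_chars <- strsplit(spectrum$sequence, "", fixed = TRUE)
    M <- do.call(rbind, allele_chars[idx])
    if (error_rate > 0) {
      err <- which(matrix(stats::runif(n_reads * lens) < error_rate,
                          n_reads, lens))
      if (length(err)) {
        cur <- M[err]
        # draw uniformly among the three non-reference bases
        alt <- vapply(cur, function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
        M[err] <- alt
      }
    }
    reads <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
    if (indel_rate > 0) {
      del <- which(stats::runif(n_reads) < indel_rate)
      for (i in del) {
        p <- sample.int(lens, 1L)
        reads[i] <- paste0(substr(reads[i], 1L, p - 1L),
                           substr(reads[i], p + 1L, lens))
      }
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(id = ids, label = spectrum$label[idx],
                            stringsAsFactors = FALSE))
  })
}

#' Simulate paired treated/control off-target site counts
#'
#' Edited-read counts are drawn binomially: controls at the background
#' editing rate, treated samples at background plus a per-site true
#' editing increase.
#'
#' @param n_sites Number of sites (default 58: the nominated off-target
#'   panel size, on-target plus perfect-match site included).
#' @param depth Reads per site and sample (default 20000).
#' @param background Background editing fraction in both samples
#'   (default 0.001).
#' @param delta True treated-minus-control editing difference in
#'   percentage points; scalar or per-site vector (default 0).
#' @param seed Integer seed.
#' @return Data.frame with `site_id`, `treated_edited`, `treated_total`,
#'   `control_edited`, `control_total`, `true_delta`.
#' @export
simulate_offtarget_counts <- function(n_sites = 58L, depth = 20000L,
                                      background = 0.001, delta = 0,
                                      seed = NULL) {
  delta <- rep_len(delta, n_sites)
  p_treat <- background + delta / 100
  if (background < 0 || background > 1 || any(p_treat < 0 | p_treat > 1))
    stop("InvalidSpec: rates must lie in [0, 1]", call. = FALSE)
  with_seed(seed, data.frame(
    site_id = sprintf("site%02d", seq_len(n_sites)),
    treated_edited = stats::rbinom(n_sites, depth, p_treat),
    treated_total = depth,
    control_edited = stats::rbinom(n_sites, depth, background),
    control_total = depth,
    true_delta = delta,
    stringsAsFactors = FALSE))
}

#' Simulate an alanine-scan binding matrix with a planted epitope
#'
#' Each antibody is assigned a set of true epitope residues whose alanine
#' variants lose its binding (residual binding drawn uniformly in
#' `[0, epitope_max]`) while every other antibody retains binding
#' (uniform in `[control_min, 100]`). Optional Gaussian noise is added
#' and values clipped at 0.
#'
#' @param epitope_map Named list: antibody name -> integer vector of true
#'   epitope residues.
#' @param residues Integer vector of all scanned residues (superset of the
#'   planted ones).
#' @param wt_aa Optional wild-type amino acids per residue (defaults to
#'   `"X"` placeholders).
#' @param epitope_max,control_min Sampling bounds in percent (defaults 10
#'   and 85).
#' @param noise_sd Gaussian noise s.d. in percentage points (default 0).
#' @param seed Integer seed.
#' @return List with `matrix` (data.frame for
#'   [call_epitope_residues()]) and `truth` (data.frame `residue`, `mab`).
#' @export
simulate_binding_matrix <- function(epitope_map, residues,
                                    wt_aa = NULL,
                                    epitope_max = 10, control_min = 85,
                                    noise_sd = 0, seed = NULL) {
  mabs <- names(epitope_map)
  stopifnot(length(mabs) >= 2L)
  planted <- unlist(epitope_map, use.names = FALSE)
  stopifnot(all(planted %in% residues))
  if (is.null(wt_aa)) wt_aa <- rep("X", length(residues))
  with_seed(seed, {
    vals <- sapply(mabs, function(m) {
      lo <- residues %in% epitope_map[[m]]
      v <- ifelse(lo, stats::runif(length(residues), 0, epitope_max),
                  stats::runif(length(residues), control_min, 100))
      pmax(v + stats::rnorm(length(residues), 0, noise_sd), 0)
    })
    mat <- data.frame(residue = residues, wt_aa = wt_aa,
                      stringsAsFactors = FALSE)
    mat[mabs] <- as.data.frame(vals)
    truth <- do.call(rbind, lapply(mabs, function(m)
      if (length(epitope_map[[m]]))
        data.frame(residue = epitope_map[[m]], mab = m,
                   stringsAsFactors = FALSE)))
    list(matrix = mat, truth = truth)
  })
}

#' Simulate marker-specific reads for a two-donor mixture
#'
#' Donor-specific read counts per informative marker are binomial at the
#' true mixture fraction.
#'
#' @param fraction True donor fraction in `[0, 1]`.
#' @param n_markers Number of informative markers (default 10).
#' @param depth Total reads per marker (default 1000).
#' @param seed Integer seed.
#' @return Data.frame with `marker`, `donor_reads`, `total_reads`.
#' @export
simulate_chimerism_reads <- function(fraction, n_markers = 10L,
                                     depth = 1000L, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("InvalidSpec: fraction must lie in [0, 1]", call. = FALSE)
  with_seed(seed, data.frame(
    marker = sprintf("M%02d", seq_len(n_markers)),
    donor_reads = stats::rbinom(n_markers, depth, fraction),
    total_reads = depth,
    stringsAsFactors = FALSE))
}
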