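# Built-in CD45 demonstration fixtures.
#
# The protein-level fixture is the published recombinant D1-D2 construct
# sequence (extracellular domain residues 225-394 with short added N- and
# C-terminal tags). The DNA amplicons are SYNTHETIC: reverse-translated
# from that protein with fixed human-preferred codons, forcing the codons
# relevant to adenine-editing outcomes (AAT for N351, AAG for K352,
# ATA/CAT/AAT for I283/H285/N286). They stand in for the deposited
# sequencing amplicons so the whole pipeline runs offline with known truth.

CD45_D1D2_SEQ <- paste0(
  "ETGIEGRKPTCDEKYANITVDYLYNKETKLFTAKLNVNENVECGNNTCTNNEVHNLTECKNASVSISHN",
  "SCTAPDKTLILDVPPGVEKFQLHDCTQVEKADTTICLKWKNIETFTCDTQNITYRFQCGNMIFDNKEIK",
  "LENLEPEHEYKCDSEILYNNHKFTNASKIIKTDFGSPGEGTKHHHHHH")

#' The recombinant CD45 D1-D2 protein construct
#'
#' Returns the D1-D2 construct sequence used for protein-level spot checks
#' of residue numbering. Extracellular-domain residues 225--394 are
#' flanked by a short N-terminal linker and a C-terminal His tag; the
#' numbering offset is configurable rather than asserted.
#'
#' @param n_term_added Number of added N-terminal residues preceding
#'   residue 225 (default 7).
#' @return List with `sequence`, `residue_start` (225), `residue_end`
#'   (394) and `n_term_added`.
#' @export
cd45_d1d2_construct <- function(n_term_added = 7L) {
  list(sequence = CD45_D1D2_SEQ, residue_start = 225L, residue_end = 394L,
       n_term_added = as.integer(n_term_added))
}

#' Amino acid at a numbered CD45 residue of the D1-D2 construct
#'
#' @param residue Residue number (225--394).
#' @param construct A [cd45_d1d2_construct()] (default construct if
#'   omitted).
#' @return Single amino-acid letter.
#' @export
cd45_residue <- function(residue, construct = cd45_d1d2_construct()) {
  idx <- residue - construct$residue_start + 1L + construct$n_term_added
  if (any(idx < 1L | idx > nchar(construct$sequence)))
    stop("residue outside the construct", call. = FALSE)
  substring(construct$sequence, idx, idx)
}

# Fixed, deterministic codon choice (frequent human codons).
PREFERRED_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "CGG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC")

# Reverse-translate a residue range of the construct, with per-residue
# codon overrides (named by residue number).
reverse_translate_region <- function(from, to, overrides = character()) {
  aas <- vapply(from:to, cd45_residue, character(1))
  codons <- unname(PREFERRED_CODON[aas])
  if (length(overrides)) {
    idx <- match(as.integer(names(overrides)), from:to)
    codons[idx[!is.na(idx)]] <- overrides[!is.na(idx)]
  }
  paste(codons, collapse = "")
}

DEMO_FLANK_5 <- "CATTCGAGCTGTACG"
DEMO_FLANK_3 <- "TCGATCCAGTTGCAC"

#' Synthetic CD45 demonstration amplicon, guide and geometry
#'
#' Builds a synthetic amplicon for one of the two engineered CD45 regions,
#' together with a 20-nt guide placed so the editing window covers the
#' region's editable adenines:
#'
#' * `"K352"`: CDS residues 345--360 with N351 = `AAT` and K352 = `AAG`;
#'   the guide places the N351/K352 adenines at protospacer positions
#'   4, 5, 7 and 8, reproducing the intended K352 edits plus the
#'   N351D/N351S bystander repertoire.
#' * `"I283"`: CDS residues 276--295 with I283 = `ATA`, H285 = `CAT`,
#'   N286 = `AAT`; the guide places the three relevant adenines at
#'   protospacer positions 3, 8 and 10, whose joint conversion yields the
#'   I283M+H285R+N286D triple mutant.
#'
#' @param region `"K352"` or `"I283"`.
#' @return List with `amplicon` ([amplicon_ref()]), `guide` (20-nt
#'   string), `proto` ([locate_protospacer()] result), `map`
#'   ([build_codon_map()]) and `window` (the resolved centre -10 / size 15
#'   quantification window).
#' @export
cd45_demo_region <- function(region = c("K352", "I283")) {
  region <- match.arg(region)
  if (region == "K352") {
    cds <- reverse_translate_region(345L, 360L,
                                    overrides = c("351" = "AAT"))
    guide_start <- 31L
  } else {
    cds <- reverse_translate_region(276L, 295L,
                                    overrides = c("283" = "ATA",
                                                  "284" = "TCT",
                                                  "285" = "CAT",
                                                  "286" = "AAT"))
    guide_start <- 37L
  }
  seq <- paste0(DEMO_FLANK_5, cds, DEMO_FLANK_3)
  first_res <- if (region == "K352") 345L else 276L
  amp <- amplicon_ref(paste0("CD45_demo_", region), seq,
                      anchor_pos = nchar(DEMO_FLANK_5) + 1L,
                      anchor_residue = first_res, frame_offset = 0L,
                      cds_strand = "+")
  guide <- substr(seq, guide_start, guide_start + 19L)
  proto <- locate_protospacer(amp, guide)
  map <- build_codon_map(amp)
  win <- resolve_window(window_spec(-10L, 15L, "quantification"), proto, amp)
  list(amplicon = amp, guide = guide, proto = proto, map = map,
       window = win, region = region)
}

# Replace single positions of a sequence with a base.
mutate_positions <- function(seq, pos, base = "G") {
  for (p in pos) substr(seq, p, p) <- base
  seq
}

#' Ground-truth allele spectrum for the K352 demonstration region
#'
#' The genotype mix emulates the editing outcome of the selected
#' K352-targeting guide in HSPCs: a dominant unedited fraction, the two
#' intended shielding substitutions (K352E and K352G) and a minor
#' N351S+K352G bystander genotype.
#'
#' @param freqs Named numeric frequencies summing to 1. The defaults
#'   (WT 0.45, K352E 0.30, K352G 0.20, N351S+K352G 0.05) are the
#'   simulation study conditions.
#' @return Data.frame with columns `label`, `sequence` (full amplicon
#'   allele), `freq`.
#' @export
cd45_demo_spectrum <- function(freqs = c(WT = 0.45, K352E = 0.30,
                                         K352G = 0.20,
                                         `N351S+K352G` = 0.05)) {
  reg <- cd45_demo_region("K352")
  ref <- reg$amplicon$sequence
  k1 <- proto_to_amp(reg$proto, 7L)   # K352 codon adenine 1
  k2 <- proto_to_amp(reg$proto, 8L)   # K352 codon adenine 2
  n2 <- proto_to_amp(reg$proto, 5L)   # N351 codon adenine 2
  seqs <- c(
    WT = ref,
    K352E = mutate_positions(ref, k1),
    K352G = mutate_positions(ref, c(k1, k2)),
    `N351S+K352G` = mutate_positions(ref, c(n2, k1, k2)))
  if (!all(names(freqs) %in% names(seqs)))
    stop("unknown genotype label(s): ",
         paste(setdiff(names(freqs), names(seqs)), collapse = ", "),
         call. = FALSE)
  data.frame(label = names(freqs), sequence = unname(seqs[names(freqs)]),
             freq = unname(freqs), stringsAsFactors = FALSE)
}
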