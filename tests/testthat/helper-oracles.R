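# Independent oracles and shared fixtures for the test suite.
# Each oracle recomputes a quantity by a route disjoint from the package
# implementation it checks.

# Brute-force global affine alignment score: plain recursion over every
# monotone alignment path (match/mismatch, gap-in-a, gap-in-b), with
# affine gap costs (a length-L gap costs |open| + L * |extend|).
oracle_align_score <- function(a, b, sc = default_scoring()) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (ac[i] == bc[j]) sc$match else sc$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) {
      g <- sc$gap_extend + if (prev == 1L) 0 else sc$gap_open
      best <- max(best, g + rec(i + 1L, j, 1L))
    }
    if (j <= nb) {
      g <- sc$gap_extend + if (prev == 2L) 0 else sc$gap_open
      best <- max(best, g + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Full-amplicon codon-walk genotype oracle for the built-in demo regions:
# translates the whole CDS of the mutated amplicon with
# Biostrings::translate and names the amino-acid differences directly,
# without using the package's codon map or window plumbing.
oracle_genotype <- function(mut_seq, ref_seq, cds_start, cds_len,
                            first_residue) {
  translate_str <- function(s)
    strsplit(as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, cds_start, cds_start + cds_len - 1L)))), "")[[1]]
  if (identical(mut_seq, ref_seq)) return("WT")
  ref_aa <- translate_str(ref_seq)
  mut_aa <- translate_str(mut_seq)
  d <- which(ref_aa != mut_aa)
  if (!length(d)) return("silent")
  paste(sprintf("%s%d%s", ref_aa[d], first_residue + d - 1L, mut_aa[d]),
        collapse = "+")
}

# Hand step-up Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Tiny plus-strand fixture: 9-codon CDS flanked by non-coding sequence,
# with a unique 20-nt guide on the plus strand.
tiny_fixture <- function() {
  cds <- "ATGCTGAAGCCTAAAGGCTTCGAGTAA"  # M L K P K G F E *
  seq <- paste0("CCGTT", cds, "GGACCTTAGC")
  amp <- amplicon_ref("tiny", seq, anchor_pos = 6L, anchor_residue = 1L)
  list(amp = amp, cds = cds, cds_start = 6L,
       map = build_codon_map(amp))
}
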