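test_that("amplicon_ref validates sequence and anchor", {
  expect_error(amplicon_ref("x", "ACGU", 1, 1), "outside|characters")
  expect_error(amplicon_ref("x", "", 1, 1), "non-empty")
  expect_error(amplicon_ref("x", "ACGT", 9, 1), "FrameError")
  expect_error(amplicon_ref("x", "ACGT", 1, 1, frame_offset = 3),
               "FrameError")
  amp <- amplicon_ref("x", "ATGAAAGGG", 1, 1)
  expect_s3_class(amp, "amplicon_ref")
})

test_that("protospacers are located uniquely on either strand", {
  guide <- "ACGTACGTAAGGCCTTACGT"
  amp_fwd <- amplicon_ref("f", paste0("CCGTT", guide, "TGGACTTAGC"), 1, 1)
  p <- locate_protospacer(amp_fwd, guide)
  expect_equal(p$strand, "+")
  expect_equal(p$start, 6L)
  expect_equal(p$pam_seq, "TGG")

  amp_rev <- amplicon_ref("r", paste0("CCGTT", revcomp(guide), "TGGACTTAGC"),
                          1, 1)
  p2 <- locate_protospacer(amp_rev, guide)
  expect_equal(p2$strand, "-")
  expect_equal(p2$start, 6L)

  amp_two <- amplicon_ref("t", paste0("CC", guide, "TT", guide, "GG"), 1, 1)
  expect_error(locate_protospacer(amp_two, guide), "Ambiguous")
  expect_error(locate_protospacer(amp_fwd, strrep("A", 20)), "NotFound")
  expect_error(locate_protospacer(amp_fwd, "ACGT"), "exactly 20 nt")
})

test_that("protospacer coordinates map to amplicon coordinates by strand", {
  guide <- "ACGTACGTAAGGCCTTACGT"
  amp <- amplicon_ref("f", paste0("CCGTT", guide, "TGGACTTAGC"), 1, 1)
  p <- locate_protospacer(amp, guide)
  expect_equal(proto_to_amp(p, 1L), 6L)
  expect_equal(proto_to_amp(p, 20L), 25L)
  amp_rev <- amplicon_ref("r", paste0("CCGTT", revcomp(guide), "TGGACTTAGC"),
                          1, 1)
  pr <- locate_protospacer(amp_rev, guide)
  # position 1 is the 5' end of the protospacer = rightmost amplicon base
  expect_equal(proto_to_amp(pr, 1L), 25L)
  expect_equal(proto_to_amp(pr, 20L), 6L)
})

test_that("window resolution follows the centre/size convention", {
  guide <- "ACGTACGTAAGGCCTTACGT"
  amp <- amplicon_ref("f", paste0("CCGTT", guide, "TGGACTTAGC"), 1, 1)
  p <- locate_protospacer(amp, guide)
  w <- resolve_window(window_spec(-10L, 15L), p, amp)
  expect_equal(c(w$proto_start, w$proto_end), c(3L, 17L))
  expect_equal(c(w$start, w$end), c(8L, 22L))
  w1 <- resolve_window(window_spec(-10L, 1L), p, amp)
  expect_equal(c(w1$proto_start, w1$proto_end), c(10L, 10L))
  # even size: extra base goes 3' of the centre
  w4 <- resolve_window(window_spec(-10L, 4L), p, amp)
  expect_equal(c(w4$proto_start, w4$proto_end), c(9L, 12L))
  # a PAM-centred window on a protospacer at the amplicon edge overflows
  amp_edge <- amplicon_ref("e", paste0("CC", guide, "T"), 1, 1)
  pe <- locate_protospacer(amp_edge, guide)
  expect_error(resolve_window(window_spec(0L, 15L), pe, amp_edge),
               "OutOfBounds")
})

test_that("window resolution is translation-equivariant", {
  guide <- "ACGTACGTAAGGCCTTACGT"
  for (shift in c(0L, 4L, 9L)) {
    seq <- paste0(strrep("C", shift), "CCGTT", guide, "TGGACTTAGC")
    amp <- amplicon_ref("s", seq, 1, 1)
    p <- locate_protospacer(amp, guide)
    w <- resolve_window(window_spec(-10L, 15L), p, amp)
    expect_equal(c(w$start, w$end), c(8L, 22L) + shift)
  }
})

test_that("strand flip commutes with window resolution", {
  guide <- "ACGTACGTAAGGCCTTACGT"
  seq <- paste0("CCGTT", guide, "TGGACTTAGC")
  amp <- amplicon_ref("f", seq, 1, 1)
  flipped <- amplicon_ref("rc", revcomp(seq), 1, 1)
  w <- resolve_window(window_spec(-10L, 15L),
                      locate_protospacer(amp, guide), amp)
  wf <- resolve_window(window_spec(-10L, 15L),
                       locate_protospacer(flipped, guide), flipped)
  L <- nchar(seq)
  expect_equal(c(wf$start, wf$end), c(L - w$end + 1L, L - w$start + 1L))
  expect_equal(wf$strand, "-")
})

test_that("codon maps tile the CDS and round-trip residues", {
  fx <- tiny_fixture()
  map <- fx$map
  # tiling extends in-frame across the whole amplicon; the CDS residues
  # 1..9 must be covered with the right codon coordinates
  expect_true(all(1:9 %in% map$residue))
  expect_equal(residue_codon_positions(map, 1L), 6:8)
  expect_equal(residue_codon_positions(map, 3L), 12:14)
  # round trip: amplicon position -> residue -> codon positions
  for (p in map$amp_pos) {
    r <- map$residue[map$amp_pos == p]
    expect_true(p %in% residue_codon_positions(map, r))
  }
  expect_error(residue_codon_positions(map, 99L), "not covered")
})

test_that("minus-strand CDS maps complement codons correctly", {
  fx <- tiny_fixture()
  flipped_seq <- revcomp(fx$amp$sequence)
  L <- nchar(flipped_seq)
  # anchor base of residue 1 (codon position 1) lands at L - 5 on the flip
  amp_rev <- amplicon_ref("rc", flipped_seq, anchor_pos = L - 5L,
                          anchor_residue = 1L, cds_strand = "-")
  map_rev <- build_codon_map(amp_rev)
  expect_true(all(1:9 %in% map_rev$residue))
  for (r in 1:9)
    expect_equal(beshield:::codon_of(amp_rev, map_rev, r),
                 beshield:::codon_of(fx$amp, fx$map, r))
})

test_that("frame errors are reported for inconsistent anchors", {
  expect_error(build_codon_map(amplicon_ref("x", "ACGT", 1, 1,
                                            frame_offset = 2L)),
               "FrameError")
})

test_that("amplicon FASTA and guide TSV readers round-trip", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">amp1", "ATGAAAGGGTTT", ">amp2", "ATGCCCGGGTTT"), fa)
  amps <- read_amplicon_fasta(fa, anchor_pos = 1, anchor_residue = 1)
  expect_length(amps, 2L)
  expect_equal(amps$amp2$sequence, "ATGCCCGGGTTT")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tsequence", "g1\tACGTACGTAAGGCCTTACGT"), tsv)
  g <- read_guides_tsv(tsv)
  expect_equal(unname(g["g1"]), "ACGTACGTAAGGCCTTACGT")
})
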