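test_that("global alignment scores match the scoring scheme", {
  sc <- default_scoring()
  a <- global_align("ACGTACGT", "ACGTACGT")[[1]]
  expect_equal(a$score, 8 * sc$match)
  expect_equal(a$aligned_read, a$aligned_ref)
  b <- global_align("ACGAACGT", "ACGTACGT")[[1]]
  expect_equal(b$score, 7 * sc$match + sc$mismatch)
  g <- global_align("ACGCGT", "ACGTACGT")[[1]]  # one length-2 gap
  expect_equal(g$score, 6 * sc$match + sc$gap_open + 2 * sc$gap_extend)
  expect_error(global_align(character(), "ACGT"), "EmptyInput")
  expect_error(global_align("", "ACGT"), "EmptyInput")
})

test_that("alignment score equals the brute-force enumeration optimum", {
  set.seed(101)
  for (i in 1:60) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
               collapse = "")
    expect_equal(global_align(a, b)[[1]]$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment score is invariant under joint reverse-complement", {
  set.seed(102)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
    expect_equal(global_align(a, b)[[1]]$score,
                 global_align(revcomp(a), revcomp(b))[[1]]$score)
  }
})

test_that("window alleles are extracted in protospacer orientation", {
  ref <- "CCGTTACGTACGTAAGGCCTTACGTTGGACTTAGC"
  win <- list(start = 10L, end = 17L, strand = "+")
  aln <- global_align(ref, ref)[[1]]
  expect_equal(extract_window_allele(aln, win), substr(ref, 10, 17))
  # substitution inside the window (ref position 12 is G)
  mutated <- paste0(substr(ref, 1, 11), "A", substr(ref, 13, nchar(ref)))
  aln2 <- global_align(mutated, ref)[[1]]
  allele <- extract_window_allele(aln2, win)
  expect_equal(allele, substr(mutated, 10, 17))
  d <- which(strsplit(allele, "")[[1]] !=
               strsplit(substr(ref, 10, 17), "")[[1]])
  expect_equal(d, 3L)
  # minus-strand window: reported reverse-complemented
  win_m <- list(start = 10L, end = 17L, strand = "-")
  expect_equal(extract_window_allele(aln, win_m),
               revcomp(substr(ref, 10, 17)))
})

test_that("gap columns inside the window yield the INDEL class", {
  ref <- "CCGTTACGTACGTAAGGCCTTACGTTGGACTTAGC"
  win <- list(start = 10L, end = 17L, strand = "+")
  # deletion overlapping the window
  del <- paste0(substr(ref, 1, 11), substr(ref, 14, nchar(ref)))
  expect_equal(extract_window_allele(global_align(del, ref)[[1]], win),
               "INDEL")
  # insertion inside the window
  ins <- paste0(substr(ref, 1, 12), "TTTT", substr(ref, 13, nchar(ref)))
  expect_equal(extract_window_allele(global_align(ins, ref)[[1]], win),
               "INDEL")
  # deletion entirely outside the window leaves the allele clean
  del_out <- paste0(substr(ref, 1, 25), substr(ref, 29, nchar(ref)))
  expect_equal(extract_window_allele(global_align(del_out, ref)[[1]], win),
               substr(ref, 10, 17))
})

test_that("allele tables count, normalize and flag sub-threshold alleles", {
  reg <- cd45_demo_region("K352")
  ref <- reg$amplicon$sequence
  k1 <- proto_to_amp(reg$proto, 7L)
  edited <- ref
  substr(edited, k1, k1) <- "G"
  reads <- c(rep(ref, 90), rep(edited, 10))
  names(reads) <- paste0("r", seq_along(reads))
  tab <- build_allele_table(reads, reg$amplicon, reg$proto,
                            window = reg$window)
  expect_equal(attr(tab, "total_reads"), 100L)
  expect_equal(sum(tab$frequency), 1)
  expect_equal(sum(tab$n_reads), 100L)
  expect_equal(sort(tab$frequency, decreasing = TRUE), c(0.9, 0.1))
  expect_false(any(tab$is_other))

  # one read in 200 sits below the 0.8% threshold and pools into "other"
  rare <- ref
  substr(rare, reg$window$start, reg$window$start) <- "T"
  reads2 <- c(rep(ref, 199), rare)
  tab2 <- build_allele_table(reads2, reg$amplicon, reg$proto,
                             window = reg$window)
  expect_true(any(tab2$is_other))
  pooled <- pool_other_alleles(tab2)
  expect_true("other" %in% pooled$allele)
  expect_equal(sum(pooled$frequency), 1)
  expect_error(build_allele_table(character(), reg$amplicon, reg$proto),
               "EmptyInput")
})

test_that("read filters are applied and logged", {
  reg <- cd45_demo_region("K352")
  ref <- reg$amplicon$sequence
  reads <- c(ref, ref,
             "ACGT",                                             # too short
             paste0(substr(ref, 1, 10), strrep("N", 8),
                    substr(ref, 19, nchar(ref))),                # N-rich
             strrep("AC", nchar(ref) %/% 2))                     # unalignable
  names(reads) <- paste0("r", 1:5)
  tab <- build_allele_table(reads, reg$amplicon, reg$proto,
                            window = reg$window)
  log <- attr(tab, "filter_log")
  expect_equal(log$reason,
               c("min_read_length", "max_n_fraction", "min_alignment_score"))
  expect_true(all(log$n_out <= log$n_in))
  expect_equal(attr(tab, "total_reads"), 2L)
})

test_that("vectorized window extraction matches the per-read column walk", {
  reg <- cd45_demo_region("K352")
  sim <- simulate_amplicon_reads(cd45_demo_spectrum(), n_reads = 300,
                                 error_rate = 0.005, indel_rate = 0.05,
                                 seed = 7)
  tab <- build_allele_table(sim$reads, reg$amplicon, reg$proto,
                            window = reg$window)
  slow <- vapply(global_align(sim$reads, reg$amplicon$sequence),
                 extract_window_allele, character(1), window = reg$window)
  slow_counts <- table(slow)
  for (a in tab$allele)
    expect_equal(tab$n_reads[tab$allele == a],
                 as.integer(slow_counts[[a]]), info = a)
})

test_that("allele frequency recovery stays within binomial error", {
  reg <- cd45_demo_region("K352")
  spectrum <- cd45_demo_spectrum()
  n <- 4000L
  sim <- simulate_amplicon_reads(spectrum, n_reads = n,
                                 error_rate = 0.001, seed = 11)
  tab <- build_allele_table(sim$reads, reg$amplicon, reg$proto,
                            window = reg$window)
  # map each truth genotype to its expected window allele
  for (i in seq_len(nrow(spectrum))) {
    allele <- substr(spectrum$sequence[i], reg$window$start, reg$window$end)
    f_hat <- tab$frequency[tab$allele == allele]
    f <- spectrum$freq[i]
    tol <- 3 * sqrt(f * (1 - f) / n) + 0.01  # + per-base error leakage
    expect_lt(abs(f_hat - f), tol)
  }
})

test_that("allele tables round-trip through TSV and the dialect importer", {
  reg <- cd45_demo_region("K352")
  ref <- reg$amplicon$sequence
  reads <- stats::setNames(rep(ref, 10), paste0("r", 1:10))
  tab <- build_allele_table(reads, reg$amplicon, reg$proto,
                            window = reg$window)
  f <- tempfile(fileext = ".tsv")
  write_allele_table(tab, f)
  back <- beshield:::read_table_meta(f)
  expect_equal(back$allele, tab$allele)
  expect_equal(back$n_reads, tab$n_reads)

  # CRISPResso2-style dialect
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("Aligned_Sequence\tReference_Sequence\tn_deleted\tn_inserted\t#Reads\t%Reads",
               "CAATGAGG\tCAATAAGG\t0\t0\t30\t30.0",
               "CAATAAGG\tCAATAAGG\t0\t0\t65\t65.0",
               "CAAT-AGG\tCAATAAGG\t1\t0\t5\t5.0"), f2)
  imp <- read_crispresso_alleles(f2)
  expect_equal(attr(imp, "total_reads"), 100L)
  expect_equal(imp$frequency[imp$allele == "INDEL"], 0.05)
  expect_equal(sum(imp$frequency), 1)
})

test_that("FASTQ writer and reader round-trip reads", {
  reads <- c(r1 = "ACGTACGTAA", r2 = "TTGGCCAATT")
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back, reads)
})
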