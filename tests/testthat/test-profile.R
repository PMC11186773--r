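test_that("window alleles translate to named substitutions", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  tr <- function(allele)
    translate_window_allele(allele, reg$amplicon, reg$window, reg$map)
  expect_equal(tr(ref_allele), "WT")

  # K352 codon AAG -> GAG: the intended glutamate substitution
  k1 <- proto_to_amp(reg$proto, 7L) - reg$window$start + 1L
  e_allele <- ref_allele
  substr(e_allele, k1, k1) <- "G"
  expect_equal(tr(e_allele), "K352E")

  # N351 AAT -> GAT plus K352 AAG -> GAG: the two-residue bystander outcome
  n1 <- proto_to_amp(reg$proto, 4L) - reg$window$start + 1L
  d_allele <- e_allele
  substr(d_allele, n1, n1) <- "G"
  expect_equal(tr(d_allele), "N351D+K352E")

  # synonymous-only change reports "silent", not WT
  e3 <- proto_to_amp(reg$proto, 12L) - reg$window$start + 1L  # GAG 3rd base
  s_allele <- ref_allele
  substr(s_allele, e3, e3) <- "A"                             # GAG -> GAA
  expect_equal(tr(s_allele), "silent")

  expect_error(tr(paste0("N", substr(ref_allele, 2, nchar(ref_allele)))),
               "Untranslatable")
  expect_error(tr("ACGT"), "length")
})

test_that("translation agrees with the full-amplicon codon-walk oracle", {
  reg <- cd45_demo_region("K352")
  ref <- reg$amplicon$sequence
  ref_allele <- substr(ref, reg$window$start, reg$window$end)
  span <- nchar(ref_allele)
  set.seed(202)
  for (i in 1:200) {
    allele <- ref_allele
    n_mut <- sample(0:4, 1)
    pos <- sample(span, n_mut)
    for (p in pos)
      substr(allele, p, p) <- sample(c("A", "C", "G", "T"), 1)
    mut <- ref
    substr(mut, reg$window$start, reg$window$end) <- allele
    expect_equal(
      translate_window_allele(allele, reg$amplicon, reg$window, reg$map),
      oracle_genotype(mut, ref, cds_start = 16L, cds_len = 48L,
                      first_residue = 345L),
      info = allele)
  }
})

make_table <- function(df, total = sum(df$n_reads), window = NULL) {
  df$frequency <- df$n_reads / total
  df$is_indel <- df$allele == "INDEL"
  df$is_other <- !df$is_indel & df$frequency < 0.008
  structure(df, class = c("allele_table", "data.frame"),
            total_reads = total, window = window, other_threshold = 0.008)
}

test_that("profiles merge alleles by genotype before thresholding", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  k1 <- proto_to_amp(reg$proto, 7L) - reg$window$start + 1L
  # two distinct nucleotide alleles that both translate to K352E
  gag <- ref_allele; substr(gag, k1, k1) <- "G"
  e3 <- proto_to_amp(reg$proto, 12L) - reg$window$start + 1L
  gaa <- gag; substr(gaa, e3, e3) <- "A"  # K352 GAG plus silent E353 GAA
  tab <- make_table(
    data.frame(allele = c(ref_allele, gag, gaa),
               n_reads = c(50L, 20L, 30L), stringsAsFactors = FALSE),
    window = reg$window)
  prof <- aggregate_profile(tab, reg$amplicon, reg$map,
                            window = reg$window)
  expect_equal(prof$frequency[prof$genotype == "K352E"], 0.5)
  expect_equal(prof$frequency[prof$genotype == "WT"], 0.5)
  expect_equal(sum(prof$frequency), 1)

  # merge-then-threshold keeps a genotype whose alleles are individually rare
  tab2 <- make_table(
    data.frame(allele = c(rep(ref_allele, 1), gag, gaa),
               n_reads = c(986L, 7L, 7L), stringsAsFactors = FALSE),
    window = reg$window)
  prof_merge <- aggregate_profile(tab2, reg$amplicon, reg$map,
                                  window = reg$window, merge_first = TRUE)
  expect_true("K352E" %in% prof_merge$genotype)
  prof_split <- aggregate_profile(tab2, reg$amplicon, reg$map,
                                  window = reg$window, merge_first = FALSE)
  expect_false("K352E" %in% prof_split$genotype)
  expect_equal(prof_split$frequency[prof_split$genotype == "others"],
               14 / 1000)
})

test_that("profiles are invariant to row order and row splitting", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  k1 <- proto_to_amp(reg$proto, 7L) - reg$window$start + 1L
  gag <- ref_allele; substr(gag, k1, k1) <- "G"
  base <- data.frame(allele = c(ref_allele, gag),
                     n_reads = c(70L, 30L), stringsAsFactors = FALSE)
  prof1 <- aggregate_profile(make_table(base, window = reg$window),
                             reg$amplicon, reg$map, window = reg$window)
  prof2 <- aggregate_profile(make_table(base[2:1, ], window = reg$window),
                             reg$amplicon, reg$map, window = reg$window)
  split_rows <- data.frame(allele = c(ref_allele, gag, gag),
                           n_reads = c(70L, 10L, 20L),
                           stringsAsFactors = FALSE)
  prof3 <- aggregate_profile(make_table(split_rows, window = reg$window),
                             reg$amplicon, reg$map, window = reg$window)
  expect_equal(prof1, prof2, ignore_attr = TRUE)
  expect_equal(prof1, prof3, ignore_attr = TRUE)
})

test_that("INDEL, untranslatable and pooled rows route to their classes", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  n_allele <- ref_allele; substr(n_allele, 2, 2) <- "N"
  tab <- make_table(
    data.frame(allele = c(ref_allele, "INDEL", n_allele),
               n_reads = c(900L, 50L, 50L), stringsAsFactors = FALSE),
    window = reg$window)
  prof <- aggregate_profile(tab, reg$amplicon, reg$map, window = reg$window)
  expect_equal(prof$frequency[prof$genotype == "INDEL"], 0.05)
  expect_equal(prof$frequency[prof$genotype == "others"], 0.05)
  expect_equal(sum(prof$frequency), 1)
})

test_that("a reference-only table profiles as pure WT", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  tab <- make_table(data.frame(allele = ref_allele, n_reads = 100L,
                               stringsAsFactors = FALSE),
                    window = reg$window)
  prof <- aggregate_profile(tab, reg$amplicon, reg$map, window = reg$window)
  expect_equal(as.data.frame(prof),
               data.frame(genotype = "WT", frequency = 1, n_reads = 100L),
               ignore_attr = TRUE)
})

test_that("profiles write to TSV with metadata", {
  reg <- cd45_demo_region("K352")
  ref_allele <- substr(reg$amplicon$sequence, reg$window$start,
                       reg$window$end)
  tab <- make_table(data.frame(allele = ref_allele, n_reads = 10L,
                               stringsAsFactors = FALSE),
                    window = reg$window)
  prof <- aggregate_profile(tab, reg$amplicon, reg$map, window = reg$window,
                            sample_id = "s1")
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f)
  expect_true(any(grepl("^# beshield substitution profile",
                        readLines(f))))
  back <- beshield:::read_table_meta(f)
  expect_equal(back$genotype, prof$genotype)
})
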