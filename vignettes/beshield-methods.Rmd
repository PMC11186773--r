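---
title: "Methods: quantifying base-editing outcomes for epitope shielding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying base-editing outcomes for epitope shielding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beshield)
```

# Scope and model

`beshield` analyses targeted amplicon deep sequencing from epitope-shielding
experiments: cells edited with an adenine base editor (ABE, A>G on the
protospacer strand) so that a surface epitope no longer binds a depleting
antibody. The package covers the six computational stages of that workflow
(allele quantification, substitution profiling, editor-outcome enumeration
and scoring, off-target validation, alanine-scan epitope calling, donor
chimerism) plus a synthetic-data module. This vignette records the
modelling assumptions, the tunable constants and why they have the values
they do, and the numerical conventions a maintainer needs.

# Coordinate model

All coordinates are **1-based, closed intervals**. A protospacer is the
20-nt genomic match of the guide, numbered 1–20 with position 20
PAM-proximal and the PAM at 21–23. `locate_protospacer()` requires a
unique exact match on one strand of the amplicon and records the PAM for
reporting only — it is never used as a filter, because near-PAMless
editors (SpRY) are in scope and guide placement is given by the match
itself.

Windows are defined by a centre offset relative to the protospacer 3' end
and a size: the centre sits at protospacer position `20 + offset` and the
window covers `[centre − floor((size−1)/2), centre + ceil((size−1)/2)]`.
With the default quantification window (offset −10, size 15) this is
positions 3–17. The floor/ceil split for even sizes is a package
convention, fixed here and tested as an explicit constant, because the
upstream tools this dialect mirrors do not document their rounding. With
this convention a window whose spec keeps it inside the protospacer can
never leave the amplicon; out-of-bounds errors arise only for windows that
reach past the protospacer ends (e.g. PAM-centred windows near an amplicon
edge), and are reported as such.

Codon bookkeeping hangs off a single anchor: one amplicon position tied to
a protein residue number and a frame offset. `build_codon_map()` tiles
codons in-frame across the whole amplicon from that anchor (including any
flanking sequence — harmless, since only codons overlapping observed
changes are ever translated) and supports minus-strand coding sequences by
complementing at translation time.

# Alignment and allele counting

Merged reads are globally aligned to the amplicon (Needleman–Wunsch,
affine gaps) via `Biostrings::pairwiseAlignment`. The scoring constants —
match +2, mismatch −1, gap open −8, gap extend −1 per base, `N` scored as
a mismatch against everything — are package defaults, overridable per
call; they favour substitution interpretations over gaps, which matches
the substitution-centric chemistry of base editing. Tie-breaking among
co-optimal alignments is the aligner's deterministic internal order; the
score, and hence every window call in practice, does not depend on it.
The test suite checks the score against a brute-force oracle that
enumerates every alignment of short pairs.

Three read filters run before counting, each logged with counts in/out:

* minimum read length (default: the window span) — shorter fragments
  cannot report a window allele;
* maximum `N` fraction (default 5%);
* minimum alignment score (default 60% of the read's perfect score) —
  discards unalignable contaminants.

Reads are assumed pre-merged and adapter-trimmed; paired-end merging and
quality trimming are upstream QC, out of scope.

The window allele is the read sequence aligned to the window interval,
reported in protospacer orientation. Any gap column touching the window
interior (deletion covering a window base, insertion between window bases)
classifies the read as `INDEL`. `INDEL` reads form their own class and
**stay in the denominator** of allele frequencies — the conservative
choice consistent with applying the 0.8% threshold to fractions of total
reads. Alleles below the 0.8% threshold (`other_threshold = 0.008`) are
flagged and can be pooled into a single `other` row for reporting; the
unpooled rows are kept so genotype aggregation can merge before
thresholding (below).

# Translation and substitution profiles

`translate_window_allele()` substitutes the window allele back into the
reference and translates every codon overlapping the window under the
standard genetic code. Codons only partially covered by the window are
completed with reference bases — by construction no edit can be observed
outside the window, so this is exact, not an approximation. Substitutions
are named `<refAA><residue><altAA>` and joined in residue order
(`N351S+K352G`). Nucleotide changes that are entirely synonymous report as
`silent`, kept distinct from `WT` so that dominant-genotype statements are
conservative. Alleles containing `N` are untranslatable and are routed to
`others`.

`aggregate_profile()` merges alleles by genotype **before** applying the
0.8% threshold (two rare nucleotide alleles of one genotype can jointly
clear it); the opposite order is available (`merge_first = FALSE`) since
the read-level threshold is also a defensible reading. The merge-first
default reflects the threshold being stated in terms of reads per
genotype class.

# Base-editor outcome enumeration and score

`enumerate_edit_outcomes()` finds the editor's source bases
(protospacer-strand orientation) inside the editing window, enumerates all
`2^k` conversion subsets, translates each, and deduplicates by
substitution set. The default editing window is protospacer positions
3–10, a conventional adenine-editor window; it is a per-editor parameter
because screened editor architectures differ. A cap (`max_editable = 16`)
turns pathological windows into an explicit error instead of a silent
65,536-row table. On the built-in K352 fixture the AAG lysine codon yields
exactly the E (GAG), R (AGG) and G (GGG) substitutions, and the I283
fixture yields the I283M+H285R+N286D triple among its eight outcomes.

The screening score is

`score = log10((Σ fᵢ / n_edited) + 1)`,

with `fᵢ` per-position editing percentages (0–100, the scale on which
chromatogram deconvolution and NGS report) and `n_edited` the number of
positions with nonzero measured frequency; the score is 0 when nothing is
edited. Two conventions are deliberately exposed as parameters: the
logarithm base (base 10 by default; the score is used for ranking, which
is base-invariant) and the reading of "edited positions" as measured > 0
rather than the window size. Note one property worth knowing: the score
is permutation-invariant and monotone in the frequency of any *already
edited* position, but activating a previously unedited position at low
frequency increases `n_edited` and can lower the mean-based score — a
real feature of mean-per-edited-position scores, not a bug.

# Off-target validation statistics

A read is *edited* at a site when it carries ≥ 1 A>G conversion
(protospacer strand) within scoring-window positions 4–10; reads not
covering the full window with called bases are excluded from numerator and
denominator. The editing frequency is `100 × edited / total`. Per site, a
2×2 table of edited/unedited counts in treated vs control is tested with
the Pearson chi-squared statistic (closed form
`n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`, 1 df, upper tail), **without**
Yates correction — the plain chi-squared test is the stated method, and a
zero margin returns `χ² = 0, p = 1` by convention. FDR is
Benjamini–Hochberg across the sites of one treated-vs-control comparison
(the unit of analysis), via `stats::p.adjust`; the hand step-up
calculation serves as the oracle in the tests. A site is **validated** iff
`FDR ≤ 0.05` and `Δ = f_treated − f_control ≥ 1` percentage point.

The dual criterion's operating characteristics are what the acceptance
checks compute: under a null of 0.1% background editing at depth 20,000
across 58 sites, the Δ ≥ 1 guard makes a validated site essentially
impossible (a site would need > 10 standard deviations of excess), so the
replicate-level false-validation rate is ~0; a true 2-point site at the
same depth validates in essentially every replicate.

# Epitope calling

From an alanine-scan matrix of residual binding (% of wild-type signal,
variants × antibodies), residue `r` is a candidate epitope residue for
antibody `m` iff binding(`m`) ≤ 20% while at least one other antibody
retains > 70% — the other antibodies act as folding/expression controls,
hence at least two antibody columns are required. Variants that lose *all*
antibodies are excluded as likely structural/expression artefacts. The
low threshold is inclusive (≤ 20) by default with a strict (<) option,
since both readings appear in common usage. `prioritize_residues()` then
removes cysteines (disulfide bridges) and annotated PTM/interface
residues, and flags candidates with surface accessibility below
`buried_max = 10%` as likely indirect; 10% is a package default chosen to
comfortably capture clearly buried residues (the motivating example is a
residue at 4% accessibility) while not flagging partially exposed ones —
it is a config knob, not a biological constant. Accessibility, epitope
probability and conservation are consumed as precomputed inputs; the
structural tools that produce them are out of scope.

# Chimerism

Markers are informative for a donor pair when exactly one donor carries
the allele; the donor fraction is the unweighted mean over informative
markers of donor-specific/total reads — "average proportion" taken
literally — with a depth-weighted option. Host (mouse) reads are assumed
excluded upstream; implausibly low marker totals trigger a warning. The
estimator is the binomial MLE per marker averaged equally, hence unbiased;
the tests verify bias < 0.005 across the full mixture grid at a combined
depth of 10,000 reads (10 markers × 1,000).

# Synthetic data: what it does and does not emulate

The generators produce every pipeline input with known truth and full
determinism under a seed (one R RNG stream, no iteration-order
dependence): multinomial allele mixtures with uniform per-base
substitution errors (0.1% default) and an optional single-base deletion
knob to exercise the `INDEL` class; binomial treated/control off-target
counts; planted-epitope binding matrices; binomial two-donor marker
mixtures. The default read spectrum — WT 0.45, K352E 0.30, K352G 0.20,
N351S+K352G 0.05 — is the simulation study condition for the K352 region:
a dominant unedited fraction, the two intended shielding substitutions,
and a minor bystander genotype.

Deliberately **not** modelled: realistic quality-score profiles,
PCR duplicates and chimeras, context-dependent error spectra, indel-rich
repair outcomes, and amplification bias. Passing tests therefore
demonstrate correctness of the counting, translation and statistics on
substitution-dominated data; they do not certify behaviour on indel-heavy
nuclease data, which is outside the package's analysis surface.

The DNA fixtures deserve a note: the protein-level fixture is the
published recombinant CD45 D1–D2 construct sequence (residues 225–394
with short added tags; the numbering offset is a parameter, not an
assertion), while the demo amplicons are *synthetic* — reverse-translated
from that protein with fixed human-preferred codons, forcing only the
codons that matter for adenine-editing outcomes (AAT at N351, AAG at
K352; ATA/TCT/CAT/AAT at I283–N286). They reproduce the codon-level
editing repertoire of the engineered regions without being genomic
sequence.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10,000 reads at 0.1%
error for spectrum recovery (each genotype recovered within 3 binomial
standard deviations); 500 alignment-oracle pairs of length ≤ 8; 1,000
translation-oracle alleles; 10,000 random 2×2 tables (closed-form
agreement to 1e−9); 500 null and 500 power replicates at 58 sites ×
depth 20,000; 200 replicates per point of the chimerism mixture grid.
These sizes make every stochastic check comfortably powered while keeping
a full run on one CPU in minutes.

Frequencies are validated to sum to 1 within 1e−9; chi-squared arithmetic
is done in doubles (integer counts overflow the `n(ad−bc)²` numerator at
realistic depths); percentage scales are used wherever the laboratory
convention reports percent (editing frequencies, binding, score inputs),
and fractions where estimates are probabilities (allele frequencies,
donor fraction).

# Known limitations

* Window-overlapping indels collapse into a single `INDEL` class; indel
  allele spectra and HDR outcomes are out of scope.
* The aligner's tie-break among co-optimal alignments is inherited from
  Biostrings, not configurable.
* Off-target calls from raw reads require the site's amplicon and guide;
  the count-table path is the primary interface, mirroring upstream
  pooled quantification output.
* Epitope calling consumes binding percentages as given; normalisation
  (MFI ratio vs % positive) happens upstream.
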