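---
title: "Methods: surveillance-factor binding and ribosome stall analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance-factor binding and ribosome stall analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostall)
```

# Overview

`ribostall` implements the computational procedures used to map where RNA
decay factors (the helicases MTR4 and SKIV2L, the exonuclease XRN1, and the
SKI-complex partner AVEN) contact mRNA, and to detect the translation
surveillance signatures those contacts leave behind: ribosome stall sites
read out from CRAC fragment 3' ends, collided-ribosome (disome) footprints,
non-templated 3' uridylation of cleavage products, accelerated mRNA decay,
and uORF-level regulation.

Every module consumes and produces plain data structures (data frames,
matrices, named vectors) so the pipeline can be driven from scripts; a
synthetic-data generator produces ground-truth inputs for each stage so
that every procedure can be validated by round-trip.  All coordinates are
0-based and half-open internally; SAM import/export converts at the
boundary.  The protocol convention of calling reading frames "1st/2nd/3rd"
is mapped to frame indices 0/1/2 throughout.

# Read-level filtering

CRAC reads are quality-processed with two sequential rules
(`quality_filter()`): 3' bases below a Phred threshold are trimmed, and a
read is kept only if a minimum percentage of remaining bases reaches a
minimum quality.  Presets encode the two parameterizations used for CRAC
(trim 25 / Q20 / 90%) and ribosome profiling (no trim / Q30 / 80%).
`demux_extract_umi()` takes the 4-nt UMI from the read start and requires
an exact inline-barcode match immediately after it.

`strip_low_complexity_3p()` removes the longest 3' suffix whose modal
nucleotide accounts for at least 80% of its positions.  The protocol's
wording for the minimum qualifying length is ambiguous ("2 nt more"); the
worked example (`...AAAAGAA`, 7 nt) is compatible with several readings, so
the minimum suffix length is a parameter with default 6 nt.

Unique-mapping selection (`filter_unique_alignments()`) keeps alignments
whose second-best score, where reported, is strictly below 0.8 times the
best score, whose MAPQ is at least 8, and whose 5' end is not soft-clipped.
The 5'-clip test is strand-aware: for a minus-strand alignment the read's
5' end is the right-hand CIGAR clip.  UMI deduplication
(`collapse_duplicates()`) groups alignments by (UMI, reference, strand,
5'-end position) and retains one survivor at random; groups are visited in
sorted key order under a caller-supplied seed so the choice is
reproducible.  Filtering precedes deduplication; both orders are possible
by composing the functions.  Footprint size selection uses inclusive
ranges: monosomes 26-35 nt, disomes 45-70 nt, total RNA 21-70 nt, and a
restricted 56-64 nt range for disome quantification.

# Non-templated 3' tails

`extract_3p_tails()` calls a tail when a transcriptome alignment carries a
non-empty, homopolymeric 3' soft clip; there is no minimum length, so
single-base tails count.  Two guards suppress templated artifacts: the read
must align better to the transcriptome than to the genome (an
exon-junction guard, applied when genome scores are available), and a clip
that exactly matches the next `len(tail)` templated transcript bases is
rejected.  The second guard is stated explicitly here because it makes the
false-positive behaviour testable: on simulations in which clipped
sequence never continues the template, tail recovery is exact.  A tailed
read still contributes to ordinary coverage counts; both uses are
intentional.  Tails must be extracted from reads whose 3' adapter was
found and removed and which were *not* low-complexity stripped, since
stripping would delete the tails themselves.

# Binding profiles and relative binding

`transcript_pileup()` and `metagene_profile()` build per-transcript
coverage and start/stop-anchored summaries: each transcript's pileup is
divided by its maximum depth, transcripts with fewer than five reads are
excluded, and normalized tracks are summed across transcripts.  The
plotted flank (default 100 nt) is a display choice and configurable.

`relative_binding()` allocates each transcript's CRAC signal among the
three decay factors: per-factor pooled counts are scaled so every column
total equals the smallest library, transcripts must exceed 1 normalized
count in all three datasets and 10 in at least one (strict inequalities,
as specified), and the retained rows are divided by their sums, so the
three shares sum to 1 by construction.  An optional flag divides by
RNA-seq RPKM first, to verify that transcript-level differences between
cell lines do not distort the allocation.  Embeddings (PCA, t-SNE) and
correlation matrices are computed from these tables with standard tools
and are out of scope here.

# Stall-site scoring from fragment 3' ends

For every mRNA with at least five qualifying CRAC reads, 204-nt windows
slide across the CDS at 1-nt steps (`hexamer_windows()`).  Each window is
keyed by the hexamer at its centre and that hexamer's frame relative to
the start codon.  Because 204 is even, "centre" is a convention: the
central 6-mer is taken to start at window position 99, exposed as a
parameter.  Fragment 3'-end counts in each window with at least five
counts are normalized to the window sum, and windows are averaged within
(hexamer, frame) groups (`hexamer_end_profiles()`).

A key is called bound (`call_bound_hexamers()`) when its central-hexamer
signal strictly exceeds the same key's value in every control dataset and
the value expected under an even spread of reads across the window,
6/204.  Controls are supplied by the caller (in practice, CRAC data for
unrelated proteins); keys missing from a control contribute a control
value of zero and are counted.  Bound hexamers are translated directly
into amino-acid pairs — the frame only classifies a key as in-frame or
out-of-frame — and per pair the proportion of bound hexamer/frame
combinations is reported when at least four combinations contribute
(`aa_pair_proportions()`).  Frame-specific enrichment of a pair indicates
that the encoded amino acids, not merely the underlying sequence, drive
binding.

`tract_profiles()` builds the companion views around repeat tracts:
runs of 3-4 identical amino acids, or in-frame polypurine runs of at least
12 nt trimmed to codon boundaries, extended by 96 nt either side, binned
at 6 nt, normalized per window (to the maximum for amino-acid repeats, to
the sum for polypurine tracts) and summed within groups (repeat residue,
G/A content, or >30%-lysine class).  Window lengths differ by up to 3 nt
between tract sizes, so bins are aligned on the window start, where the
flank is constant; truncated windows at transcript ends are zero-padded
and counted.

# Ribosome profiling quantification

Disome A-site assignment (`assign_disome_asite()`) uses the empirical
offset table: for footprint lengths 58, 59, 60, 62 and 63 nt the offsets
from the footprint 5' end are (45, 44, 43), (45, 44, 46), (45, 44, 46),
(48, 47, 46) and (48, 47, 49) for frames 0, 1 and 2.  Lengths 56, 57, 61
and 64 fall inside the quantification range but have no published offset;
they are deliberately unassigned rather than guessed.  Every tabulated
offset satisfies `(-offset) mod 3 = frame`, so assigned A-sites always
land on codon starts — this identity is what lets the synthetic generator
invert the table and guarantee exact round-trips.  Monosome offsets are
not part of the protocol's printed material; the shipped default (+15 for
26-30 nt, +16 for 31-35 nt) is standard practice and replaceable.

`select_expressed_transcripts()` keeps transcripts with FPKM > 0.2 and
isoform fraction > 0.05 jointly in at least two samples, and flags genes
with exactly one kept isoform; only those genes are used for uORF work.
`normalize_and_rpkm()` removes genes lacking 10 counts in a third of the
samples, computes upper-quartile scale factors (edgeR), and reports RPKM
as counts per kilobase of mappable length per million of the effective
library size, rescaled to preserve the geometric mean of the raw library
sizes — making RPKM invariant to a global rescaling of all libraries.
Genes with mean total RNA RPKM > 5 are flagged robustly expressed;
`ribosome_density()` divides footprint RPKM by total RNA RPKM (undefined
where the denominator is zero).  Differential testing of densities is
delegated to the standard count-model packages; this module prepares
their inputs.

# mRNA half-lives with ERCC anchoring

Decay time courses (0, 120, 240, 360 min after transcription shutoff,
with mock samples used only for QC) are normalized in two steps
(`ercc_size_factors()`).  Replicates within a timepoint are first
equalized by median-of-ratios (DESeq2's `estimateSizeFactorsForMatrix`).
The global decay scale then comes from the spike-ins: using ERCCs with a
mean above 50 raw counts, the per-sample ratio of total mRNA to total ERCC
counts is summarized by its within-timepoint median and rescaled so the
t = 0 factor is exactly 1.  These factors estimate the globally remaining
mRNA fraction (0.5 at t = 120 under a uniform 2-fold decay).

For the normalized counts themselves, each sample is anchored on its
total qualifying-ERCC counts (divided by the ratio of its ERCC total to
the t = 0 reference).  A subtlety motivates this choice: when libraries
are sequenced to a fixed depth, raw mRNA counts carry essentially no
global-decay signal — the decay is visible only in the rising ERCC share —
and a normalization that divides mRNA counts by the remaining-fraction
factor itself would move them in the wrong direction.  Anchoring on the
ERCC totals recovers abundances proportional to absolute amounts whether
or not depth confounding is present (both modes are simulated and tested),
and coincides with dividing by the reciprocal factor in the fixed-depth
case.

`fit_half_life()` fits ordinary least squares of `ln(counts + 1)` on time
and reports `t_half = -ln(2)/k` for negative slopes, `Inf` otherwise, with
the residual standard error as the goodness-of-fit measure.  The +1
pseudocount biases fits at low counts; at the simulated count scale
(N0 = 1000-3000) the bias on a 120-min half-life is below 1%.

# Structure and sequence motif enrichment

50-nt windows tile the 5'UTR and CDS at 10-nt offsets (`tile_windows()`);
partial tails are dropped.  Windows are folded by a pluggable backend
(`fold_window()`): either an adapter that reads precomputed dot-bracket /
MFE results from RNAfold-style output files, or a built-in fallback — a
maximum-weight base-pairing dynamic program (minimum loop 3, GU pairs
allowed) with fixed per-pair pseudo-energies (GC -3, AU -2, GU -1
kcal/mol) plus regex G-quadruplex annotation,
`G{3,}(N{1,7}G{3,}){3}`, marked `+`.  The fallback is explicitly *not* a
thermodynamic model; analyses that depend on folding are validated on
constructed sequences whose pairing is unambiguous, and the backend
identity is recorded in outputs.  For motif counting, brackets collapse to
a single "paired" symbol, giving the 3-letter alphabet
(paired / unpaired / quadruplex) over which structure 10-mers are counted;
sequence motifs are 6-mers.

Bound windows (`select_bound_windows()`) require transcript RNA-seq
RPKM of at least 10, at least six analyzed windows per transcript, and a
foreground CRAC/RNA-seq enrichment that exceeds every background dataset
and is at least 10; per transcript and region the maximum-enrichment
bound window is kept.  Background sets for `motif_zscores()` resample,
100 times, one window per foreground window from the same transcript
within 400 nt, excluding the foreground set (sampling is independent per
repeat; a foreground window with no eligible neighbour is omitted and
counted).  Per motif, `z = (fg - mean(bg)) / sd(bg)`; when the background
standard deviation is zero the score is 0 if the counts agree and signed
infinity otherwise.  Flags require `|z| > 2.5` and a total occurrence
(foreground + mean background) of at least 10 — the occurrence floor is
unspecified in the protocol and exposed as a parameter.  Comparing two
conditions directly (`motif_direct_comparison()`) replaces resampling with
per-motif counts in the two bound sets and their log2 ratio.

`structured_region_profile()` selects non-overlapping 50-nt windows with
MFE below -12 kcal/mol and a continuous run of at least 10 paired
nucleotides, extends them to 242 nt, normalizes coverage to the window
sum and bins at 6 nt.  242 is not divisible by 6; the trailing 2-nt bin is
kept and flagged rather than discarded, preserving totals.

# rRNA binding sites

`rrna_bin_coverage()` filters rRNA alignments (at least 20 nt aligned,
edit distance at most 1), piles them per position, converts to per-sample
counts per million and averages in 20-nt bins; it also returns raw per-bin
count sums.  `test_bound_bins()` fits, per bin, a negative binomial
regression of counts on the group factor with log library-size offsets
and compares it to an intercept-only null by a likelihood-ratio
chi-squared test (1 df), adjusting across bins by Benjamini-Hochberg at
FDR 0.05.  Fitting uses raw bin count sums with offsets rather than the
(continuous) mean CPM values, for statistical coherence; with equal-depth
normalization the two readings coincide up to a constant.

One calibration choice matters at few replicates: estimating the NB
dispersion separately per bin by maximum likelihood makes the chi-squared
reference strongly anticonservative at n = 5 per group (empirical type-I
roughly twice nominal in our null simulations).  Binned coverage shares
its mean-variance behaviour across bins, so the default pools a single
dispersion across bins by moment matching on the full-model residuals
(reducing to Poisson when the moment estimate is zero); the per-bin ML
variant remains available as `dispersion = "per_bin"`.  Under the pooled
default the null simulations in the test suite are calibrated and the
planted 5-fold bins are recovered with high power.

# Genomic windows and uORFs

`tile_and_classify()` tiles each chromosome into 1-kb windows in both
orientations and assigns each the highest-priority overlapping feature:
abundant ncRNA (either strand; lincRNAs excluded), mRNA exon (sense),
mRNA intron (sense), 1 kb upstream of an mRNA (sense), the same three
antisense, else intergenic.  Terminal sub-1-kb windows are emitted but
flagged and excluded from statistics by default.  `window_features()`
adds GC content, sORFs (every ATG with an in-frame stop inside the
window, strand-aware) and optionally an MFE, computed as the sum over
non-overlapping 50-nt tiles of the folding backend's MFE — a pragmatic
choice, since the fallback fold is cubic in window length.

Window counts are normalized by median-of-ratios (RNA-seq, ribosome
profiling) or to the minimum library size (CRAC), log2-transformed with a
pseudocount of 4 (`window_lfc()`), and classified by the SKIV2L contrast
into down / slight change / up / strongly up.  The cut points are not
printed in the protocol; the defaults (-0.5, 0.5, 1.5) anchor the +-0.5
boundaries on the fold-change threshold used elsewhere in the analysis
and are parameters.  Comparison LFCs are median-centred on the "down"
category (its median becomes exactly 0) and category pairs are compared
by two-sided rank-sum tests with Bonferroni correction across the pairs.

`annotate_uorfs()` applies the three printed rules on single-isoform
transcripts: AUG start wholly within the 5'UTR, in-frame stop within the
5'UTR or CDS (stops inside the CDS mark overlapping uORFs), and at least
6 nt including the stop.  `uorf_differential()` scales each sample's
combined uORF + CDS counts to 100,000, classes AVEN occupancy
(AVEN CRAC / wild-type monosome counts; low <= 5 < medium <= 20 < high),
computes differential uORF translation
`log2[(uORF/CDS)_KO / (uORF/CDS)_WT]` on monosome counts, and the SKIV2L
uORF fold change normalized to CDS monosome counts under the printed
detection filters (20 per 100k for SKIV2L in either genotype; 2 per 100k
for CDS monosomes in both).

# The synthetic-data generator

`synthetic_spec()` fixes the simulated study conditions; the generator is
deliberately minimal and fully inspectable:

* **Transcripts** are single-isoform, with random UTRs (defaults 60-150 nt
  5', 60-200 nt 3') and an ATG...stop CDS of sense codons (default
  300-900 nt).  Planted features — uORFs, stall hexamers, hairpin
  windows — are written into the sequence and recorded as ground truth.
* **CRAC reads** place fragment 3' ends uniformly, the simplest null
  consistent with the enrichment analyses; planted hexamer positions get
  multiplier-fold weight.  Reads are UMI + barcode + insert, and the
  emitted alignment records carry MAPQ, scores, edit distance and 3'
  soft-clips directly, so no external aligner is involved.  Tails are
  attached only at cleavage sites whose next templated base differs from
  the tail base: this keeps the templated-continuation guard from ever
  rejecting a planted tail, making noiseless recovery exact — the tail
  *rate* is unchanged, only its positions are constrained.
* **Footprints** invert the offset tables (5' end = A-site - offset), so
  A-site assignment must recover planted sites with zero error.
* **Decay counts** follow `N0 * 2^(-t/t_half)` at 0/120/240/360 min with
  three replicates, constant-expectation ERCCs, optional Poisson noise,
  optional mock samples, and an optional fixed-depth mode that rescales
  every library to a constant total to emulate composition confounding.
* **rRNA bins** draw negative binomial (or Poisson) counts with a common
  dispersion, optionally with fold-enriched bins in the foreground group.

What the generator does **not** emulate: sequencing errors, PCR
chimeras, splice isoforms, positional coverage biases (ligation, UV
crosslink preferences), overdispersion beyond Poisson in decay counts,
and correlated backgrounds between CRAC datasets.  Passing tests
therefore demonstrate correctness of the procedures under their stated
assumptions, not robustness to every artifact of real libraries.

Test and acceptance runs use deliberately small problem sizes — tens of
transcripts, hundreds of reads per transcript, 20-40 rRNA bins with 5
samples per group, about 100 resampling or seed repetitions — chosen so
the full suite completes in about a minute while keeping the Monte-Carlo
assertions (type-I rate, power, flag rates) well inside their bounds.

# Known limitations

* The fallback fold maximizes weighted pairings; its MFE is a
  pseudo-energy useful for thresholding constructed cases, not a
  thermodynamic prediction.  Use the file adapter with a real folding
  engine for biological sequences.
* Disome lengths without published offsets are dropped rather than
  interpolated.
* The genomic-window classifier treats annotation features as flat
  intervals; nested gene structures beyond exon/intron/upstream are the
  caller's responsibility.
* `ercc_size_factors()` assumes spike-in amounts are constant per sample;
  variable spike-in volumes would need an additional per-sample scaling.
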