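# ribostall

Tools for analysing protein–RNA crosslinking (CRAC/CLIP) and ribosome
profiling data in the context of cytoplasmic RNA surveillance — for
computational biologists studying how decay factors such as MTR4, SKIV2L,
XRN1 and AVEN engage translated mRNAs, where ribosomes stall and collide,
and what happens to the RNA afterwards.

The package implements the bespoke statistics of that analysis rather than
wrapping existing pipelines:

* **Read preparation** — UMI extraction and demultiplexing, FASTX-style
  quality trimming/filtering, 3′ low-complexity stripping, unique-mapping
  filters (second-best score < 0.8 × best, MAPQ ≥ 8, no 5′ soft-clip) and
  seeded UMI deduplication.
* **Non-templated 3′ tails** — homopolymeric soft-clip calls (U-tails)
  with exon-junction and templated-continuation guards; per-sample tail
  fractions.
* **Binding profiles** — per-transcript pileups, max-normalized metagene
  profiles around start/stop codons, and the three-way *relative binding*
  allocation: for each retained transcript the MTR4 + SKIV2L + XRN1 shares
  sum to 1.
* **Stall scoring** — 204-nt sliding windows keyed by their central
  hexamer and frame; fragment 3′-end profiles averaged per key; a key is
  *bound* when its central signal beats every control dataset and the
  uniform expectation 6/204; bound hexamers translate to amino-acid-pair
  proportions, split in-frame vs out-of-frame.
* **Ribosome quantification** — disome A-site assignment by the empirical
  (length, frame) offset table (58 nt → +45/+44/+43; 59–60 nt →
  +45/+44/+46; 62 nt → +48/+47/+46; 63 nt → +48/+47/+49), expressed-
  transcript selection, upper-quartile RPKM and ribosome densities
  (footprint RPKM / total RNA RPKM).
* **Half-lives** — ERCC-anchored normalization of decay time courses and
  per-transcript fits of ln(counts + 1) on time, *t*<sub>1/2</sub> = −ln 2 / *k*.
* **Motif enrichment** — bound 50-nt windows, structure/sequence *k*-mer
  z-scores against 100 resampled background sets (flagged at |z| > 2.5),
  and profiles over structured regions (MFE < −12 kcal/mol, ≥ 10
  contiguous paired bases).
* **rRNA binding sites** — negative-binomial likelihood-ratio tests on
  20-nt bins with Benjamini–Hochberg control at FDR 0.05.
* **Genomic windows and uORFs** — strand-specific 1-kb tiling with
  priority classification, pseudocount-4 log2 fold changes with
  down-centred category comparisons, and AUG/in-frame-stop/≥ 6-nt uORF
  annotation with occupancy classes and differential translation.

A first-class synthetic-data generator (`synthetic_spec()`,
`build_transcriptome()`, `simulate_*()`) emits ground-truth transcriptomes,
reads, alignments and count tables for every stage, so each procedure is
validated by exact round-trips.  See the methods vignette
(`vignettes/ribostall-methods.Rmd`) for the models, parameter defaults and
numerical choices.

## Worked example

```r
library(ribostall)
spec <- synthetic_spec(
  n_transcripts = 6, tail_prob = 0.15,
  planted_stall_hexamers = data.frame(hexamer = "AAGAAG", frame = 0,
                                      multiplier = 50),
  halflife_map = c(60, 60, 120, 120, 480, 480), seed = 7)
tx <- build_transcriptome(spec)

crac <- simulate_crac_reads(tx, spec, reads_per_transcript = 300)
tails <- extract_3p_tails(crac$segments, tx$models)
tail_fraction(tails, crac$segments, base = "T")
#>   group n_eligible n_tailed  fraction
#> 1    S1       1800      283 0.1572222

fp <- simulate_ribo_footprints(tx, spec, n_disome = 200, n_monosome = 0)
asite <- assign_disome_asite(fp$segments, tx$models)
mean(asite == fp$truth$a_site)
#> [1] 1

dc <- simulate_decay_counts(tx, spec, noise = "poisson", mock = FALSE)
es <- ercc_size_factors(dc$counts, dc$samples$timepoint)
round(es$factors, 3)
#>     0   120   240   360
#> 1.000 0.528 0.341 0.247
fits <- fit_half_life(es$normalized, dc$samples$timepoint)
data.frame(fits[, c("transcript_id", "t_half")],
           truth = tx$truth$halflife[fits$transcript_id], row.names = NULL)
#>   transcript_id    t_half truth
#> 1        TX0001  60.39843    60
#> 2        TX0002  60.83743    60
#> 3        TX0003 122.38195   120
#> 4        TX0004 122.07248   120
#> 5        TX0005 459.77408   480
#> 6        TX0006 501.74842   480
```

The tail fraction recovers the planted 15% rate (283/1800 ≈ 0.157, all
283 planted tails called with no false positives); every disome footprint
maps back to its planted A-site; the ERCC size factors are pinned to 1 at
t = 0 and track the mixed-panel global decay; and the semi-log fits
recover the planted half-lives across an 8-fold range.

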