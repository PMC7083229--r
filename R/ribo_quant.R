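#' Disome A-site offset table
#'
#' Empirical offsets from the footprint 5' end to the A-site of the stalled
#' (leading) ribosome, by footprint length and reading frame of the 5' end
#' relative to the CDS start.  Frames are 0-based: frame 0 here corresponds
#' to the "1st frame" of the protocol.  Lengths 56, 57, 61 and 64 fall in
#' the disome quantification range but have no published offset and are
#' deliberately absent: footprints of those lengths are not assigned.
#'
#' @return data frame with columns `length`, `frame`, `offset`.
#' @export
disome_offset_table <- function() {
  data.frame(
    length = rep(c(58L, 59L, 60L, 62L, 63L), each = 3L),
    frame = rep(0:2, 5L),
    offset = c(45L, 44L, 43L,
               45L, 44L, 46L,
               45L, 44L, 46L,
               48L, 47L, 46L,
               48L, 47L, 49L))
}

#' Default monosome A-site offset table
#'
#' Standard-practice offsets: +15 nt for footprint lengths 26-30 and
#' +16 nt for 31-35, applied to all frames.  Replace with a calibrated
#' table where available.
#'
#' @return data frame with columns `length`, `frame`, `offset`.
#' @export
default_monosome_offset_table <- function() {
  data.frame(length = rep(26:35, each = 3L), frame = rep(0:2, 10L),
             offset = rep(c(15L, 16L), c(15L, 15L)))
}

offset_lookup <- function(table, length, frame) {
  table$offset[match(paste(length, frame), paste(table$length, table$frame))]
}

asite_assign <- function(segments, models, table, len_range) {
  p5 <- five_prime_end(segments)
  cds_start <- models$cds_start[match(segments$reference_id,
                                      models$transcript_id)]
  tx_len <- models$tx_len[match(segments$reference_id, models$transcript_id)]
  frame <- (p5 - cds_start) %% 3L
  a <- p5 + offset_lookup(table, segments$read_length, frame)
  bad <- segments$read_length < len_range[1] |
    segments$read_length > len_range[2] | p5 < 0L | a >= tx_len
  a[bad] <- NA_integer_
  as.integer(a)
}

#' Assign disome footprints to the leading ribosome's A-site
#'
#' The frame of the footprint 5' end relative to the CDS start selects the
#' offset row for its length; the A-site is `5' end + offset`.  Footprints
#' outside the 56-64 nt quantification range, or of a length without a
#' table entry, return `NA`.
#'
#' @param segments disome alignment data frame.
#' @param models transcript model data frame.
#' @param table offset table, default [disome_offset_table()].
#' @return integer vector of 0-based transcript A-site positions (`NA`
#'   where unassignable), aligned to `segments` rows.
#' @export
assign_disome_asite <- function(segments, models,
                                table = disome_offset_table()) {
  asite_assign(segments, models, table, c(56L, 64L))
}

#' Assign monosome footprints to the ribosome A-site
#'
#' @param segments monosome alignment data frame (lengths 26-35 nt).
#' @param models transcript model data frame.
#' @param table offset table, default [default_monosome_offset_table()].
#' @return integer vector of A-site positions (`NA` where unassignable).
#' @export
assign_monosome_asite <- function(segments, models,
                                  table = default_monosome_offset_table()) {
  asite_assign(segments, models, table, c(26L, 35L))
}

#' Select expressed transcripts and single-isoform genes
#'
#' A transcript is kept when it has FPKM > `min_fpkm` **and** isoform
#' abundance fraction > `min_frac` in at least `min_samples` samples
#' (jointly per sample).  Genes with exactly one kept transcript are
#' flagged single-isoform.
#'
#' @param fpkm transcripts x samples FPKM matrix.
#' @param isoform_fraction matching matrix of within-gene isoform abundance
#'   fractions.
#' @param tx2gene named character vector mapping transcript id to gene id.
#' @param min_fpkm,min_frac,min_samples thresholds.
#' @return list with `transcripts` (kept ids) and `single_isoform_genes`.
#' @export
select_expressed_transcripts <- function(fpkm, isoform_fraction, tx2gene,
                                         min_fpkm = 0.2, min_frac = 0.05,
                                         min_samples = 2L) {
  ok <- rowSums(fpkm > min_fpkm & isoform_fraction > min_frac) >= min_samples
  kept <- rownames(fpkm)[ok]
  genes <- tx2gene[kept]
  tab <- table(genes)
  list(transcripts = kept,
       single_isoform_genes = names(tab)[tab == 1L])
}

#' Filter, normalize and compute RPKM for an expression count matrix
#'
#' Genes lacking at least `min_count` counts in at least one third of the
#' samples are removed before normalization.  Library scale factors use the
#' upper-quartile method (edgeR); RPKM is counts per kilobase of mappable
#' length per million of the effective (scaled) library size, whose
#' geometric mean equals the geometric mean of the raw library sizes.
#' Genes whose mean total-RNA RPKM exceeds `robust_rpkm` are flagged
#' robustly expressed.
#'
#' @param counts genes x samples count matrix.
#' @param mappable_len named vector of mappable/countable length in nt.
#' @param totalrna_samples column names of the total RNA samples (used for
#'   the robust flag; `NULL` skips it).
#' @param min_count,robust_rpkm thresholds.
#' @return list with `counts` (filtered), `norm_factors`, `eff_libsize`,
#'   `norm_counts` (counts divided by the relative effective library size),
#'   `rpkm` and `robust` (logical, `NA` when not computed).
#' @export
normalize_and_rpkm <- function(counts, mappable_len, totalrna_samples = NULL,
                               min_count = 10L, robust_rpkm = 5) {
  if (any(colSums(counts) == 0)) .stopf("sample with all-zero counts")
  keep <- rowSums(counts >= min_count) >= ceiling(ncol(counts) / 3)
  counts <- counts[keep, , drop = FALSE]
  nf <- edgeR::calcNormFactors(counts, method = "upperquartile")
  eff <- colSums(counts) * nf
  eff <- eff * exp(mean(log(colSums(counts)))) / exp(mean(log(eff)))
  len_kb <- unname(mappable_len[rownames(counts)]) / 1000
  rpkm <- sweep(counts / len_kb, 2, eff / 1e6, "/")
  norm_counts <- sweep(counts, 2, eff / exp(mean(log(eff))), "/")
  robust <- if (is.null(totalrna_samples)) rep(NA, nrow(counts))
  else rowMeans(rpkm[, totalrna_samples, drop = FALSE]) > robust_rpkm
  list(counts = counts, norm_factors = nf, eff_libsize = eff,
       norm_counts = norm_counts, rpkm = rpkm,
       robust = stats::setNames(robust, rownames(counts)))
}

#' Ribosome density (translational efficiency)
#'
#' Density is footprint RPKM divided by total RNA RPKM, per gene and
#' sample: undefined (`NA`) where total RNA RPKM is 0, and 0 where the
#' footprint RPKM is 0.
#'
#' @param fp_rpkm,rna_rpkm matching vectors or matrices of RPKM.
#' @param log2 return log2-transformed densities.
#' @return densities with the same shape as the inputs.
#' @export
ribosome_density <- function(fp_rpkm, rna_rpkm, log2 = FALSE) {
  d <- fp_rpkm / rna_rpkm
  d[rna_rpkm == 0] <- NA_real_
  if (log2) log2(d) else d
}
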