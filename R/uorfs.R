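#' Annotate upstream open reading frames
#'
#' On transcripts whose gene expresses a single isoform (so 5'UTR
#' footprints are unambiguous), every AUG lying wholly within the 5'UTR
#' with an in-frame stop codon within the 5'UTR or the CDS yields one uORF
#' ending after its stop codon; uORFs are at least 6 nt long including the
#' stop.  Stops inside the CDS mark overlapping uORFs.
#'
#' @param models transcript model data frame.
#' @param transcripts optional ids to restrict to (e.g. the single-isoform
#'   set from [select_expressed_transcripts()]).
#' @return data frame: `transcript_id`, `start`, `end` (0-based half-open,
#'   end after the stop), `len`, `overlaps_cds`.
#' @export
annotate_uorfs <- function(models, transcripts = NULL) {
  if (!is.null(transcripts))
    models <- models[models$transcript_id %in% transcripts, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    utr <- substr(m$sequence, 1L, m$cds_start)
    hits <- gregexpr("ATG", utr)[[1]]
    if (hits[1] == -1L) next
    for (s1 in as.integer(hits)) {
      j <- s1 + 3L
      while (j + 2L <= m$cds_end) {
        if (substr(m$sequence, j, j + 2L) %in% STOP_CODONS) {
          len <- j + 2L - s1 + 1L
          if (len >= 6L)
            out[[length(out) + 1L]] <- data.frame(
              transcript_id = m$transcript_id, start = s1 - 1L,
              end = j + 2L, len = len,
              overlaps_cds = j + 2L > m$cds_start)
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), len = integer(),
                      overlaps_cds = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' uORF occupancy classes and differential translation
#'
#' Counts of reads overlapping uORFs and main CDSes are scaled to 100,000
#' per sample (over the combined uORF + CDS counted population), then
#' averaged within (assay, genotype) groups.  Outputs per uORF:
#' AVEN occupancy (AVEN CRAC / wild-type monosome uORF counts, classed
#' low <= 5 < medium <= 20 < high), differential uORF translation
#' `log2[(uORF ribo / CDS ribo)_KO / (uORF ribo / CDS ribo)_WT]`, and the
#' SKIV2L uORF log2 fold change normalized to CDS monosome counts with the
#' detection filters applied (at least `min_skiv2l` per 100k for SKIV2L in
#' either genotype and at least `min_mono_cds` per 100k for CDS monosomes
#' in both).
#'
#' @param uorf_counts uORFs x samples count matrix.
#' @param cds_counts transcripts x samples count matrix of main-CDS counts.
#' @param uorf_tx transcript id of each uORF row.
#' @param samples data frame with `sample` (matching the column names),
#'   `assay` (`aven_crac`, `skiv2l_crac`, `monosome`) and `genotype`
#'   (`WT`, `KO`).
#' @param scale_to per-sample normalization total.
#' @param occ_cuts occupancy class cut points `c(low, medium)`.
#' @param min_skiv2l,min_mono_cds detection filters (per `scale_to`).
#' @return data frame per uORF: occupancy and class, `ribo_lfc`,
#'   `skiv2l_lfc` (NA where filtered), `skiv2l_kept`; attribute
#'   `n_zero_cds` counts uORFs dropped for a zero CDS denominator.
#' @export
uorf_differential <- function(uorf_counts, cds_counts, uorf_tx, samples,
                              scale_to = 1e5, occ_cuts = c(5, 20),
                              min_skiv2l = 20, min_mono_cds = 2) {
  stopifnot(identical(colnames(uorf_counts), samples$sample),
            identical(colnames(cds_counts), samples$sample),
            length(uorf_tx) == nrow(uorf_counts))
  fac <- (colSums(uorf_counts) + colSums(cds_counts)) / scale_to
  nu <- sweep(uorf_counts, 2, fac, "/")
  nc <- sweep(cds_counts, 2, fac, "/")
  grp_mean <- function(mat, assay, genotype) {
    cols <- samples$sample[samples$assay == assay &
                           samples$genotype == genotype]
    if (!length(cols)) return(NULL)
    rowMeans(mat[, cols, drop = FALSE])
  }
  cds_of <- function(v) if (is.null(v)) NULL else unname(v[uorf_tx])
  aven_wt <- grp_mean(nu, "aven_crac", "WT")
  mono_u_wt <- grp_mean(nu, "monosome", "WT")
  mono_u_ko <- grp_mean(nu, "monosome", "KO")
  mono_c_wt <- cds_of(grp_mean(nc, "monosome", "WT"))
  mono_c_ko <- cds_of(grp_mean(nc, "monosome", "KO"))
  sk_wt <- grp_mean(nu, "skiv2l_crac", "WT")
  sk_ko <- grp_mean(nu, "skiv2l_crac", "KO")
  n <- nrow(uorf_counts)
  nav <- rep(NA_real_, n)
  occupancy <- if (!is.null(aven_wt) && !is.null(mono_u_wt))
    ifelse(mono_u_wt > 0, aven_wt / mono_u_wt, NA_real_) else nav
  occ_class <- cut(occupancy, breaks = c(-Inf, occ_cuts, Inf),
                   labels = c("low", "medium", "high"))
  ribo_lfc <- nav
  if (!is.null(mono_u_wt) && !is.null(mono_c_wt) && !is.null(mono_u_ko)) {
    ok <- mono_c_wt > 0 & mono_c_ko > 0 & mono_u_wt > 0
    ribo_lfc[ok] <- log2((mono_u_ko[ok] / mono_c_ko[ok]) /
                         (mono_u_wt[ok] / mono_c_wt[ok]))
  }
  skiv2l_lfc <- nav; kept <- rep(FALSE, n); n_zero_cds <- 0L
  if (!is.null(sk_wt) && !is.null(sk_ko) && !is.null(mono_c_wt)) {
    zero_cds <- mono_c_wt == 0 | mono_c_ko == 0
    n_zero_cds <- sum(zero_cds)
    kept <- (sk_wt >= min_skiv2l | sk_ko >= min_skiv2l) &
      mono_c_wt >= min_mono_cds & mono_c_ko >= min_mono_cds & !zero_cds &
      sk_wt > 0
    skiv2l_lfc[kept] <- log2((sk_ko[kept] / mono_c_ko[kept]) /
                             (sk_wt[kept] / mono_c_wt[kept]))
  }
  structure(data.frame(uorf = rownames(uorf_counts) %||%
                         as.character(seq_len(n)),
                       transcript_id = uorf_tx, occupancy = occupancy,
                       occupancy_class = occ_class, ribo_lfc = ribo_lfc,
                       skiv2l_lfc = skiv2l_lfc, skiv2l_kept = kept,
                       row.names = NULL),
            n_zero_cds = n_zero_cds)
}
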