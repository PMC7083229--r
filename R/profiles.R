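#' Per-position read coverage on one transcript
#'
#' @param segments alignments on this transcript.
#' @param model one-row transcript model (or an integer transcript length).
#' @return numeric vector of depth at each transcript position.
#' @export
transcript_pileup <- function(segments, model) {
  len <- if (is.numeric(model)) as.integer(model) else model$tx_len
  if (!nrow(segments)) return(numeric(len))
  interval_coverage(segments$ref_start, segments$ref_end, len)
}

#' Metagene coverage profiles around the start or stop codon
#'
#' Each transcript's pileup is normalized by its maximum read depth (the
#' maximum becomes exactly 1), transcripts with fewer than `min_reads`
#' reads are excluded, and the normalized tracks are aligned on the anchor
#' (first base of the start codon, or first base of the stop codon) and
#' summed column-wise.  Positions outside a transcript are `NA` in its row
#' and ignored in the sum.
#'
#' @param segments alignments over the transcriptome.
#' @param models transcript model data frame.
#' @param anchor `"start"` or `"stop"`.
#' @param flank half-width of the plotted window in nt.
#' @param min_reads minimum reads for a transcript to be retained.
#' @return list with `matrix` (transcripts x positions, dimnames give the
#'   offsets), `summed` (column sums), `utr_len` (5' or 3' UTR length per
#'   retained transcript, for ordering), `anchor`, `flank`.
#' @export
metagene_profile <- function(segments, models, anchor = c("start", "stop"),
                             flank = 100L, min_reads = 5L) {
  anchor <- match.arg(anchor)
  offs <- seq.int(-flank, flank)
  tx <- split(seq_len(nrow(segments)), segments$reference_id)
  keep <- names(tx)[lengths(tx) >= min_reads]
  keep <- keep[keep %in% models$transcript_id]
  mat <- matrix(NA_real_, length(keep), 2L * flank + 1L,
                dimnames = list(keep, offs))
  utr <- numeric(length(keep))
  for (i in seq_along(keep)) {
    m <- models[models$transcript_id == keep[i], ]
    tr <- transcript_pileup(segments[tx[[keep[i]]], ], m)
    tr <- tr / max(tr)
    a <- if (anchor == "start") m$cds_start else m$cds_end - 3L
    pos <- a + offs
    ok <- pos >= 0L & pos < m$tx_len
    mat[i, ok] <- tr[pos[ok] + 1L]
    utr[i] <- if (anchor == "start") m$utr5_len else m$utr3_len
  }
  list(matrix = mat, summed = colSums(mat, na.rm = TRUE),
       utr_len = stats::setNames(utr, keep), anchor = anchor, flank = flank)
}

#' Relative binding of a transcript across the three decay factors
#'
#' Each factor's pooled count column is scaled so its total equals the
#' smallest column total; transcripts are retained when they have more than
#' `min_all` normalized counts in every dataset **and** more than `min_any`
#' in at least one; each retained transcript's normalized counts are then
#' divided by their row sum, so the shares across the three factors sum
#' to 1.
#'
#' @param counts matrix of pooled per-transcript counts, one column per
#'   factor (e.g. MTR4, SKIV2L, XRN1), rownames = transcript ids.
#' @param min_all,min_any the detection filter thresholds (strict
#'   inequalities on normalized counts).
#' @param rpkm optional named vector of RNA-seq RPKM; when supplied the
#'   normalized counts are additionally divided by it before shares are
#'   computed (control for transcript-level differences).
#' @return data frame: `transcript_id` plus one share column per factor.
#' @export
relative_binding <- function(counts, min_all = 1, min_any = 10, rpkm = NULL) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    .stopf("zero column total for: %s",
           paste(colnames(counts)[tot == 0], collapse = ", "))
  norm <- sweep(counts, 2, tot / min(tot), "/")
  keep <- rowSums(norm > min_all) == ncol(norm) & rowSums(norm > min_any) >= 1
  norm <- norm[keep, , drop = FALSE]
  if (!is.null(rpkm)) norm <- norm / unname(rpkm[rownames(norm)])
  shares <- norm / rowSums(norm)
  out <- data.frame(transcript_id = rownames(shares), shares, row.names = NULL)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
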