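#' Extract non-templated homopolymeric 3' tails
#'
#' A transcriptome alignment yields a tail call iff its 3' soft-clipped
#' sequence is non-empty and homopolymeric (length 1 counts: there is no
#' minimum length requirement).  Two guards remove templated artifacts:
#' reads must align better to the transcriptome than to the genome (a
#' genome score, where supplied, must be strictly below `score_best`; this
#' removes exon-junction "tails"), and a clip that exactly matches the next
#' `length(tail)` templated transcript bases is rejected.
#'
#' @param segments transcriptome alignment data frame; these reads must
#'   have had their 3' adapter identified and stripped, and must **not**
#'   have been low-complexity stripped.
#' @param models transcript models with `sequence` (enables the templated-
#'   continuation guard); `NULL` disables it.
#' @param genome_scores optional numeric vector named by `read_id` with each
#'   read's best genome alignment score.
#' @return tail calls: `read_id`, `base`, `length`, `transcript_id` and
#'   `cleavage_pos` (0-based transcript coordinate just after the last
#'   aligned base).
#' @export
extract_3p_tails <- function(segments, models = NULL, genome_scores = NULL) {
  empty <- data.frame(read_id = character(), base = character(),
                      length = integer(), transcript_id = character(),
                      cleavage_pos = integer())
  if (!nrow(segments)) return(empty)
  tail <- segments$clipped3_seq
  ok <- !is.na(tail) & tail != "" & is_homopolymer(tail)
  if (!is.null(genome_scores)) {
    gs <- unname(genome_scores[segments$read_id])
    ok <- ok & (is.na(gs) | segments$score_best > gs)
  }
  if (!is.null(models) && any(ok)) {
    seqs <- stats::setNames(models$sequence, models$transcript_id)
    idx <- which(ok)
    cont <- substr(seqs[segments$reference_id[idx]],
                   segments$ref_end[idx] + 1L,
                   segments$ref_end[idx] + nchar(tail[idx]))
    templated <- nchar(cont) == nchar(tail[idx]) & cont == tail[idx]
    ok[idx[templated]] <- FALSE
  }
  if (!any(ok)) return(empty)
  i <- which(ok)
  data.frame(read_id = segments$read_id[i],
             base = substr(tail[i], 1L, 1L),
             length = nchar(tail[i]),
             transcript_id = segments$reference_id[i],
             cleavage_pos = segments$ref_end[i])
}

#' Fraction of reads carrying a 3' tail of a given base
#'
#' @param calls tail calls from [extract_3p_tails()].
#' @param segments the eligible alignments (restricted to mRNA references).
#' @param base tail nucleotide to count (default `"T"`, i.e. U-tails).
#' @param by optional grouping vector aligned to `segments` rows (e.g.
#'   sample, or a differential-binding category); defaults to the `sample`
#'   column when present, else a single group.
#' @return data frame per group: eligible reads, tailed reads, fraction
#'   (`NA` when a group has no eligible reads).
#' @export
tail_fraction <- function(calls, segments, base = "T", by = NULL) {
  if (is.null(by))
    by <- if ("sample" %in% names(segments)) segments$sample
          else rep("all", nrow(segments))
  by <- as.character(by)
  tailed_ids <- calls$read_id[calls$base == base]
  is_tailed <- segments$read_id %in% tailed_ids
  groups <- sort(unique(by))
  n_elig <- vapply(groups, function(g) sum(by == g), integer(1))
  n_tail <- vapply(groups, function(g) sum(is_tailed & by == g), integer(1))
  data.frame(group = groups, n_eligible = n_elig, n_tailed = n_tail,
             fraction = ifelse(n_elig > 0, n_tail / n_elig, NA_real_),
             row.names = NULL)
}
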