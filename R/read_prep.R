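phred <- function(qual) lapply(qual, function(s) utf8ToInt(s) - 33L)

#' Quality-trim and quality-filter raw reads
#'
#' Two rules applied sequentially, as in the FASTX toolkit: (1) bases are
#' trimmed from the 3' end while their quality is below `trim_threshold`
#' (skipped when `NA`); (2) a read is kept only if at least `min_pct` percent
#' of its remaining bases have quality >= `min_q`.  Presets: `"crac"` =
#' (25, 20, 90); `"ribo"` = (no trimming, 30, 80).  Reads emptied by
#' trimming are dropped and counted in the returned tally.
#'
#' @param reads data frame with `id`, `seq`, `qual` (Phred+33).
#' @param trim_threshold,min_q,min_pct filter parameters.
#' @param preset `"crac"` or `"ribo"`; overrides the three parameters.
#' @return the retained reads, with a `tally` attribute (reads in/out per
#'   rule).
#' @export
quality_filter <- function(reads, trim_threshold = 25, min_q = 20,
                           min_pct = 90, preset = NULL) {
  if (!is.null(preset)) {
    p <- switch(preset, crac = c(25, 20, 90), ribo = c(NA, 30, 80),
                .stopf("unknown preset '%s'", preset))
    trim_threshold <- p[1]; min_q <- p[2]; min_pct <- p[3]
  }
  n_in <- nrow(reads)
  q <- phred(reads$qual)
  if (!is.na(trim_threshold)) {
    keep_to <- vapply(q, function(x) {
      ok <- which(x >= trim_threshold)
      if (length(ok)) max(ok) else 0L
    }, integer(1))
    reads$seq <- substr(reads$seq, 1L, keep_to)
    reads$qual <- substr(reads$qual, 1L, keep_to)
    q <- lapply(seq_along(q), function(i) q[[i]][seq_len(keep_to[i])])
    nonempty <- keep_to > 0L
  } else nonempty <- rep(TRUE, n_in)
  pct_ok <- vapply(q, function(x) {
    if (!length(x)) 0 else 100 * mean(x >= min_q)
  }, numeric(1))
  keep <- nonempty & pct_ok >= min_pct
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tally") <- data.frame(
    rule = c("trim_emptied", "pct_below_min_q"),
    dropped = c(sum(!nonempty), sum(nonempty & pct_ok < min_pct)))
  out
}

#' Demultiplex reads and extract UMIs
#'
#' Each read is `UMI + inline barcode + insert`.  The UMI is the first
#' `umi_len` bases; the barcode must match exactly immediately after it.
#' Both are removed from the stored sequence.  Reads matching no barcode are
#' discarded; when barcodes are nested the longest match wins.
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param barcode_table data frame with `sample`, `barcode` and optionally
#'   `umi_len` (default 4).  Duplicate barcodes are a configuration error.
#' @return retained reads annotated with `umi`, `barcode`, `sample`.
#' @export
demux_extract_umi <- function(reads, barcode_table) {
  if (anyDuplicated(barcode_table$barcode))
    .stopf("duplicate barcodes in barcode table")
  if (is.null(barcode_table$umi_len)) barcode_table$umi_len <- 4L
  bt <- barcode_table[order(-nchar(barcode_table$barcode)), , drop = FALSE]
  assigned <- rep(NA_integer_, nrow(reads))
  for (j in seq_len(nrow(bt))) {
    u <- bt$umi_len[j]; b <- bt$barcode[j]
    hit <- is.na(assigned) &
      substr(reads$seq, u + 1L, u + nchar(b)) == b
    assigned[hit] <- j
  }
  keep <- !is.na(assigned)
  out <- reads[keep, , drop = FALSE]
  j <- assigned[keep]
  u <- bt$umi_len[j]; blen <- nchar(bt$barcode[j])
  out$umi <- substr(out$seq, 1L, u)
  out$barcode <- bt$barcode[j]
  out$sample <- bt$sample[j]
  out$seq <- substring(out$seq, u + blen + 1L)
  out$qual <- substring(out$qual, u + blen + 1L)
  rownames(out) <- NULL
  out
}

#' Strip a low-complexity 3' suffix
#'
#' Removes the longest 3' suffix of length >= `min_len` whose modal
#' nucleotide makes up at least `dominance` of its positions (so e.g.
#' `...AAAAGAA` is stripped at the default 0.8).  If the whole read
#' qualifies an empty string is returned and the caller drops the read.
#'
#' @param seq character vector of sequences.
#' @param min_len minimum suffix length considered (default 6 nt).
#' @param dominance minimum modal-base fraction (default 0.8).
#' @return sequences with qualifying suffixes removed.
#' @export
strip_low_complexity_3p <- function(seq, min_len = 6L, dominance = 0.8) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < min_len) return(s)
    ch <- rev(strsplit(s, "")[[1]])
    cc <- vapply(c("A", "C", "G", "T", "N"), function(b) cumsum(ch == b),
                 numeric(n))
    if (n == 1L) cc <- matrix(cc, nrow = 1L)
    modal <- apply(cc, 1L, max)
    k <- seq_len(n)
    qual <- k >= min_len & modal >= dominance * k
    if (!any(qual)) return(s)
    substr(s, 1L, n - max(which(qual)))
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse duplicate alignments by UMI and 5' end
#'
#' Alignments sharing (UMI, reference, strand, 5'-end position) are
#' collapsed to a single survivor chosen at random with a seeded RNG;
#' groups are visited in sorted key order so the output is deterministic
#' under a fixed seed.
#'
#' @param segments alignment data frame.
#' @param seed RNG seed for the survivor draw.
#' @return the surviving alignments, in their original row order.
#' @export
collapse_duplicates <- function(segments, seed = 1L) {
  if (!nrow(segments)) return(segments)
  key <- paste(segments$umi, segments$reference_id, segments$strand,
               five_prime_end(segments), sep = "\r")
  groups <- split(seq_len(nrow(segments)), key)
  groups <- groups[order(names(groups))]
  survivors <- with_seed(seed, {
    vapply(groups, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  out <- segments[sort(unname(survivors)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_groups") <- length(groups)
  out
}

#' Keep uniquely mapping alignments
#'
#' Retains alignments with (i) second-best score, where reported, strictly
#' below 0.8 times the best score, (ii) MAPQ >= 8, and (iii) no soft-clip at
#' the read's 5' end (for minus-strand alignments the 5' end is the
#' right-hand CIGAR clip).
#'
#' @param segments alignment data frame.
#' @return the retained alignments.
#' @export
filter_unique_alignments <- function(segments) {
  if (!nrow(segments)) return(segments)
  first_op <- sub("^[0-9]+([A-Z]).*$", "\\1", segments$cigar)
  last_op <- sub("^.*[0-9]([A-Z])$", "\\1", segments$cigar)
  clip5 <- ifelse(segments$strand == "-", last_op == "S", first_op == "S")
  score_ok <- is.na(segments$score_second) |
    segments$score_second < 0.8 * segments$score_best
  out <- segments[score_ok & segments$mapq >= 8L & !clip5, , drop = FALSE]
  rownames(out) <- NULL
  out
}

FOOTPRINT_RANGES <- list(monosome = c(26L, 35L), disome = c(45L, 70L),
                         disome_quant = c(56L, 64L), totalRNA = c(21L, 70L))

#' Select reads by footprint size class
#'
#' Inclusive length ranges: monosome 26-35 nt, disome 45-70 nt,
#' `disome_quant` 56-64 nt (the restricted range used for A-site level
#' quantification), total RNA 21-70 nt.
#'
#' @param x reads or alignments: a data frame with `read_length` or `seq`,
#'   or a character vector of sequences.
#' @param read_class one of `"monosome"`, `"disome"`, `"disome_quant"`,
#'   `"totalRNA"`.
#' @return the subset of `x` within the class range.
#' @export
size_select <- function(x, read_class) {
  r <- FOOTPRINT_RANGES[[read_class]]
  if (is.null(r)) .stopf("unknown read class '%s'", read_class)
  len <- if (is.character(x)) nchar(x)
  else if ("read_length" %in% names(x)) x$read_length
  else nchar(x$seq)
  keep <- len >= r[1] & len <= r[2]
  if (is.character(x)) x[keep]
  else { out <- x[keep, , drop = FALSE]; rownames(out) <- NULL; out }
}
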