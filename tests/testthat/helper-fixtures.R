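# Shared fixture builders: everything is generated in code at test time.

# one-row transcript model from explicit region sequences
toy_model <- function(utr5, cds, utr3, id = "TX1", gene = "G1") {
  stopifnot(nchar(cds) %% 3 == 0)
  data.frame(transcript_id = id, gene_id = gene,
             utr5_len = nchar(utr5), cds_len = nchar(cds),
             utr3_len = nchar(utr3),
             cds_start = nchar(utr5), cds_end = nchar(utr5) + nchar(cds),
             tx_len = nchar(utr5) + nchar(cds) + nchar(utr3),
             sequence = paste0(utr5, cds, utr3))
}

# minimal alignment record constructor
toy_segment <- function(read_id = "r1", reference_id = "TX1", ref_start = 0L,
                        ref_end = 20L, strand = "+", umi = "ACGT",
                        cigar = NULL, mapq = 42L, score_best = 20L,
                        score_second = NA_integer_, edit_distance = 0L,
                        clipped3_seq = "", read_length = NULL,
                        sample = "S1") {
  w <- ref_end - ref_start
  data.frame(read_id = read_id, umi = umi, reference_id = reference_id,
             strand = strand, ref_start = ref_start, ref_end = ref_end,
             cigar = cigar %||% sprintf("%dM", w), mapq = mapq,
             score_best = score_best, score_second = score_second,
             edit_distance = edit_distance, clipped3_seq = clipped3_seq,
             read_length = read_length %||% (w + nchar(clipped3_seq)),
             sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force uORF scan: every ATG wholly in the 5'UTR, first in-frame stop
# ending within the CDS, length >= 6 nt including the stop
uorf_oracle <- function(seq, cds_start, cds_end) {
  out <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(max(cds_start - 2L, 0L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    j <- s + 3L
    while (j + 2L <= cds_end) {
      if (substr(seq, j, j + 2L) %in% stops) {
        if (j + 2L - s + 1L >= 6L)
          out <- rbind(out, data.frame(start = s - 1L, end = j + 2L,
                                       overlaps_cds = j + 2L > cds_start))
        break
      }
      j <- j + 3L
    }
  }
  out
}
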