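qual_str <- function(q) intToUtf8(q + 33L)

test_that("quality trimming and filtering match a per-base oracle", {
  oracle <- function(seq, q, trim, min_q, min_pct) {
    if (!is.na(trim)) {
      keep <- which(q >= trim)
      n <- if (length(keep)) max(keep) else 0L
      seq <- substr(seq, 1, n); q <- q[seq_len(n)]
    }
    if (!nchar(seq)) return(NULL)
    if (100 * mean(q >= min_q) < min_pct) return(NULL)
    list(seq = seq, q = q)
  }
  set.seed(71)
  reads <- data.frame(id = sprintf("r%02d", 1:50),
                      seq = replicate(50, random_seq(sample(10:30, 1))))
  reads$qual <- vapply(nchar(reads$seq),
                       function(n) qual_str(sample(2:40, n, TRUE)),
                       character(1))
  for (p in list(c(25, 20, 90), c(NA, 30, 80))) {
    got <- quality_filter(reads, p[1], p[2], p[3])
    exp <- lapply(seq_len(nrow(reads)), function(i) {
      oracle(reads$seq[i], utf8ToInt(reads$qual[i]) - 33L, p[1], p[2], p[3])
    })
    keep <- !vapply(exp, is.null, logical(1))
    expect_equal(got$id, reads$id[keep])
    expect_equal(got$seq, vapply(exp[keep], `[[`, "", "seq"))
    ## idempotence
    again <- quality_filter(got, p[1], p[2], p[3])
    expect_equal(again[, c("id", "seq", "qual")],
                 got[, c("id", "seq", "qual")])
  }
})

test_that("quality filter presets keep all-Q40 reads and apply the 80% rule", {
  r40 <- data.frame(id = "a", seq = strrep("ACGT", 5), qual = strrep("I", 20))
  expect_equal(quality_filter(r40, preset = "crac")$seq, r40$seq)
  ## 17/20 = 85% of bases >= Q30 passes the (30, 80) preset
  q <- c(rep(35L, 17), rep(31L, 0), rep(20L, 3))
  r <- data.frame(id = "b", seq = strrep("ACGT", 5), qual = qual_str(q))
  expect_equal(nrow(quality_filter(r, preset = "ribo")), 1L)
  ## 15/20 = 75% fails it
  q2 <- c(rep(35L, 15), rep(20L, 5))
  r2 <- data.frame(id = "c", seq = strrep("ACGT", 5), qual = qual_str(q2))
  expect_equal(nrow(quality_filter(r2, preset = "ribo")), 0L)
})

test_that("demultiplexing matches brute-force prefix matching", {
  bt <- data.frame(sample = c("L5Aa", "L5Ab", "L5Ac"),
                   barcode = c("TAAGC", "GGTTA", "CACTA"))
  set.seed(8)
  inserts <- replicate(60, random_seq(15))
  pick <- sample(c(bt$barcode, "AAAAA"), 60, TRUE)
  reads <- data.frame(id = sprintf("r%02d", 1:60),
                      seq = paste0(replicate(60, random_seq(4)), pick,
                                   inserts))
  reads$qual <- strrep("I", nchar(reads$seq))
  got <- demux_extract_umi(reads, bt)
  exp_sample <- bt$sample[match(pick, bt$barcode)]
  expect_equal(got$id, reads$id[!is.na(exp_sample)])
  expect_equal(got$sample, exp_sample[!is.na(exp_sample)])
  expect_equal(got$umi, substr(reads$seq[!is.na(exp_sample)], 1, 4))
  expect_equal(got$seq, inserts[!is.na(exp_sample)])
  expect_error(demux_extract_umi(reads, rbind(bt, bt[1, ])), "duplicate")
})

test_that("3' low-complexity stripping matches a brute-force suffix scan", {
  expect_equal(strip_low_complexity_3p("ACGTACGTAAAAGAA"), "ACGTACGT")
  expect_equal(strip_low_complexity_3p("ACGTACGT"), "ACGTACGT")
  oracle <- function(s, min_len = 6, dom = 0.8) {
    n <- nchar(s)
    best <- 0L
    for (k in seq_len(n)) {
      if (k < min_len) next
      suf <- strsplit(substr(s, n - k + 1, n), "")[[1]]
      if (max(table(suf)) >= dom * k) best <- k
    }
    substr(s, 1, n - best)
  }
  set.seed(12)
  seqs <- c(replicate(80, random_seq(sample(4:25, 1))),
            paste0(random_seq(10), strrep("T", 8)),
            strrep("A", 12))
  got <- strip_low_complexity_3p(seqs)
  expect_equal(got, vapply(seqs, oracle, "", USE.NAMES = FALSE))
  ## idempotent
  expect_equal(strip_low_complexity_3p(got), got)
})

test_that("UMI deduplication keeps one read per key, deterministically", {
  segs <- rbind(toy_segment("a", umi = "AAAA", ref_start = 0, ref_end = 20),
                toy_segment("b", umi = "AAAA", ref_start = 0, ref_end = 25),
                toy_segment("c", umi = "AAAA", ref_start = 5, ref_end = 25),
                toy_segment("d", umi = "CCCC", ref_start = 0, ref_end = 20),
                toy_segment("e", umi = "AAAA", ref_start = 0, ref_end = 22))
  got <- collapse_duplicates(segs, seed = 1)
  expect_equal(nrow(got), 3L)  # 3 distinct (umi, ref, strand, 5' end) keys
  expect_identical(collapse_duplicates(segs, seed = 1), got)
  ## oracle: survivors count = distinct keys, for random inputs
  set.seed(20)
  rs <- do.call(rbind, lapply(1:100, function(i)
    toy_segment(sprintf("r%03d", i), umi = random_seq(2),
                ref_start = sample(0:3, 1),
                ref_end = sample(10:12, 1))))
  key <- paste(rs$umi, rs$reference_id, rs$strand, rs$ref_start)
  got2 <- collapse_duplicates(rs, seed = 2)
  expect_equal(nrow(got2), length(unique(key)))
  expect_true(all(!duplicated(paste(got2$umi, got2$reference_id,
                                    got2$strand, got2$ref_start))))
})

test_that("unique-mapping filter applies score, MAPQ and 5'-clip rules", {
  keep <- toy_segment("k", score_best = 100, score_second = 79, mapq = 10)
  expect_equal(nrow(filter_unique_alignments(keep)), 1L)
  boundary <- toy_segment("b", score_best = 100, score_second = 80, mapq = 10)
  expect_equal(nrow(filter_unique_alignments(boundary)), 0L)
  lowmapq <- toy_segment("m", mapq = 7)
  expect_equal(nrow(filter_unique_alignments(lowmapq)), 0L)
  clip5 <- toy_segment("c", cigar = "3S17M")
  expect_equal(nrow(filter_unique_alignments(clip5)), 0L)
  ## on the minus strand the 5' clip is the right-hand CIGAR clip
  clip5m <- toy_segment("cm", cigar = "17M3S", strand = "-")
  expect_equal(nrow(filter_unique_alignments(clip5m)), 0L)
  clip3 <- toy_segment("c3", cigar = "17M3S", clipped3_seq = "TTT")
  expect_equal(nrow(filter_unique_alignments(clip3)), 1L)
})

test_that("footprint size selection uses the inclusive class ranges", {
  lens <- c(20, 21, 25, 26, 35, 36, 44, 45, 55, 56, 64, 65, 70, 71)
  x <- data.frame(read_length = lens)
  expect_equal(size_select(x, "monosome")$read_length, c(26, 35))
  expect_equal(size_select(x, "disome")$read_length,
               c(45, 55, 56, 64, 65, 70))
  expect_equal(size_select(x, "disome_quant")$read_length, c(56, 64))
  expect_equal(size_select(x, "totalRNA")$read_length,
               lens[lens >= 21 & lens <= 70])
  expect_error(size_select(x, "nanosome"), "unknown")
})
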