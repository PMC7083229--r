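test_that("window classification follows the fixed priority order", {
  gl <- c(chr1 = 3000)
  ## a window overlapping both a snoRNA and an mRNA exon is ncRNA
  ann <- data.frame(chrom = "chr1",
                    start = c(100, 150), end = c(300, 900),
                    strand = "+", type = c("ncRNA", "exon"))
  w <- tile_and_classify(gl, ann)
  expect_equal(as.character(w$klass[w$start == 0 & w$strand == "+"]),
               "ncRNA")
  ## no overlap -> intergenic
  expect_equal(as.character(w$klass[w$start == 2000 & w$strand == "+"]),
               "intergenic")
  ## lincRNA does not count as ncRNA
  ann2 <- data.frame(chrom = "chr1", start = 100, end = 300, strand = "+",
                     type = "lincRNA")
  w2 <- tile_and_classify(gl, ann2)
  expect_true(all(w2$klass == "intergenic"))
  expect_error(tile_and_classify(gl, transform(ann, chrom = "chrX")),
               "chrX")
})

test_that("classification equals a brute-force priority-overlap oracle", {
  oracle_classify <- function(wins, ann, window = 1000) {
    g <- ann[ann$type == "mrna", , drop = FALSE]
    ups <- if (nrow(g)) data.frame(
      chrom = g$chrom,
      start = ifelse(g$strand == "+", g$start - window, g$end),
      end = ifelse(g$strand == "+", g$start, g$end + window),
      strand = g$strand, type = "upstream") else NULL
    feats <- rbind(ann[ann$type %in% c("ncRNA", "exon", "intron"),
                       c("chrom", "start", "end", "strand", "type")], ups)
    ov <- function(i, type, orient) {
      f <- feats[feats$type == type & feats$chrom == wins$chrom[i], ,
                 drop = FALSE]
      if (!is.null(orient)) {
        want <- if (orient == "sense") wins$strand[i] else
          setdiff(c("+", "-"), wins$strand[i])
        f <- f[f$strand == want, , drop = FALSE]
      }
      any(f$start < wins$end[i] & f$end > wins$start[i])
    }
    vapply(seq_len(nrow(wins)), function(i) {
      if (ov(i, "ncRNA", NULL)) "ncRNA"
      else if (ov(i, "exon", "sense")) "exon_sense"
      else if (ov(i, "intron", "sense")) "intron_sense"
      else if (ov(i, "upstream", "sense")) "upstream_sense"
      else if (ov(i, "exon", "antisense")) "exon_antisense"
      else if (ov(i, "intron", "antisense")) "intron_antisense"
      else if (ov(i, "upstream", "antisense")) "upstream_antisense"
      else "intergenic"
    }, character(1))
  }
  set.seed(9)
  for (rep in 1:25) {
    n_feat <- sample(3:12, 1)
    ann <- data.frame(
      chrom = sample(c("c1", "c2"), n_feat, TRUE),
      start = sample(0:9000, n_feat, TRUE),
      strand = sample(c("+", "-"), n_feat, TRUE),
      type = sample(c("ncRNA", "exon", "intron", "mrna", "lincRNA"),
                    n_feat, TRUE))
    ann$end <- ann$start + sample(50:3000, n_feat, TRUE)
    gl <- c(c1 = 10000, c2 = 8000)
    w <- tile_and_classify(gl, ann)
    expect_equal(as.character(w$klass), oracle_classify(w, ann))
  }
})

test_that("window features: GC, sORFs and the six-frame oracle", {
  genome <- c(chr1 = paste0(strrep("GC", 30), "ATGAAATAA",
                            strrep("AT", 20)))
  w <- data.frame(chrom = "chr1", start = 0,
                  end = nchar(genome), strand = "+", terminal = TRUE)
  feats <- window_features(w, genome)
  expect_equal(feats$windows$gc, (60 + 1) / nchar(genome[[1]]))  # GC + sORF G
  expect_equal(feats$windows$n_sorfs, 1L)
  expect_equal(feats$sorfs$sorf_end - feats$sorfs$sorf_start, 9L)
  ## all-GC window has gc = 1
  g2 <- c(chr1 = strrep("GC", 50))
  w2 <- data.frame(chrom = "chr1", start = 0, end = 100, strand = "+",
                   terminal = FALSE)
  expect_equal(window_features(w2, g2)$windows$gc, 1)
  ## sORF caller equals a brute-force scan on random sequences (both strands)
  sorf_oracle <- function(s) {
    stops <- c("TAA", "TAG", "TGA")
    out <- NULL
    for (i in seq_len(nchar(s) - 5L)) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3L
      while (j + 2L <= nchar(s)) {
        if (substr(s, j, j + 2) %in% stops) {
          out <- rbind(out, c(i - 1L, j + 2L)); break
        }
        j <- j + 3L
      }
    }
    out
  }
  set.seed(14)
  for (rep in 1:20) {
    s <- random_seq(120)
    st <- sample(c("+", "-"), 1)
    g <- c(chrZ = s)
    wr <- data.frame(chrom = "chrZ", start = 0, end = 120, strand = st,
                     terminal = FALSE)
    got <- window_features(wr, g)$sorfs
    eff <- if (st == "+") s else ribostall:::revcomp(s)
    exp <- sorf_oracle(eff)
    expect_equal(nrow(got), NROW(exp))
    if (NROW(exp)) {
      expect_equal(got$sorf_start, exp[, 1])
      expect_equal(got$sorf_end, exp[, 2])
    }
  }
})

test_that("LFC categories, down-centering and rank-sum comparisons", {
  expect_equal(window_lfc(10, 10), 0)
  ## pseudocount-4 LFC is bounded for low counts
  x <- 0:50
  expect_true(all(abs(window_lfc(x, 0)) <= log2((x + 4) / 4) + 1e-12))
  set.seed(25)
  n <- 400
  wt <- rpois(n, 50)
  ko <- rpois(n, 50 * 2^sample(c(-1, 0, 1, 2), n, TRUE))
  cmp_x <- rpois(n, 30); cmp_y <- rpois(n, 30)
  res <- window_lfc_categories(ko, wt,
                               comparisons = list(rna = list(x = cmp_x,
                                                             y = cmp_y)))
  expect_true(all(levels(res$category) ==
                  c("down", "slight_change", "up", "strongly_up")))
  ## after centering, the median of the down category is exactly 0
  centred <- res$comparisons$rna$lfc
  expect_equal(stats::median(centred[res$category == "down"]), 0)
  ## identical distributions between categories: Bonferroni-corrected tests
  ## reject at no more than the nominal familywise rate over replicates
  n_reject <- 0L
  for (r in 1:10) {
    cx <- rpois(n, 30); cy <- rpois(n, 30)
    rr <- window_lfc_categories(ko, wt,
                                comparisons = list(rna = list(x = cx,
                                                              y = cy)))
    n_reject <- n_reject + any(rr$comparisons$rna$tests$p_bonf <= 0.05,
                               na.rm = TRUE)
  }
  expect_lte(n_reject, 2L)
})
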