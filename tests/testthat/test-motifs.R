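test_that("window tiling matches the printed geometry", {
  m <- toy_model(strrep("A", 49), paste0("ATG", strrep("GCA", 38), "TAA"),
                 strrep("C", 10))  # 120-nt CDS, 49-nt 5'UTR
  w <- tile_windows(m)
  expect_equal(sum(w$region == "cds"), (120 - 50) %/% 10 + 1)  # 8 windows
  expect_equal(sum(w$region == "utr5"), 0)                     # 49 nt -> none
  expect_true(all(w$end - w$start == 50))
  expect_equal(w$start[w$region == "cds"], m$cds_start + seq(0, 70, 10))
  ## sequences match their coordinates
  expect_equal(w$sequence,
               substring(m$sequence, w$start + 1, w$end))
})

test_that("the fallback fold pairs hairpins, marks quadruplexes, rejects junk", {
  ## polyA: no pairs, mfe 0 by convention
  f0 <- fold_window(strrep("A", 50))
  expect_equal(f0$mfe, 0)
  expect_equal(f0$dotbracket, strrep(".", 50))
  ## perfect 12-bp GC hairpin with a 4-nt loop: >= 10 contiguous pairs
  stem <- "GGCGGCGGCGGC"
  hp <- paste0(stem, "GAAA", ribostall:::revcomp(stem), strrep("A", 22))
  f <- fold_window(hp)
  paired <- strsplit(structure_alphabet(f$dotbracket), "")[[1]] == "|"
  runs <- rle(paired)
  expect_gte(max(runs$lengths[runs$values]), 10)
  expect_lt(f$mfe, -12)
  ## G-quadruplex run is marked with '+'
  fq <- fold_window(paste0(strrep("A", 5), "GGGAGGGAGGGAGGG", strrep("A", 30)))
  expect_true(grepl("\\+{15}", fq$dotbracket))
  expect_error(fold_window("ACGTNNACGT"), "non-ACGU")
})

test_that("the file adapter reproduces precomputed folds", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">w1", "GGGGAAAACCCC", "((((....)))) ( -5.40)"), path)
  tab <- read_fold_file(path)
  expect_equal(tab$mfe, -5.4)
  f <- fold_window("GGGGAAAACCCC", backend = "file", fold_table = tab)
  expect_equal(f$dotbracket, "((((....))))")
  expect_equal(f$backend, "file")
})

test_that("bound-window selection applies the enrichment and count filters", {
  win <- data.frame(transcript_id = rep(c("t1", "t2", "t3"), c(8, 8, 5)),
                    region = "cds",
                    start = c(seq(0, 70, 10), seq(0, 70, 10), seq(0, 40, 10)))
  win$end <- win$start + 50
  win$sequence <- strrep("A", 50)
  rp <- c(t1 = 20, t2 = 8, t3 = 20)   # t2 fails the >= 10 RPKM filter
  crac <- cbind(fg = rep(1, nrow(win)), bg1 = rep(1, nrow(win)))
  crac[1, "fg"] <- 240   # enrichment 12 on t1
  crac[2, "fg"] <- 300   # enrichment 15 on t1 (higher, same region)
  crac[9, "fg"] <- 240   # on t2: excluded transcript
  crac[17, "fg"] <- 240  # on t3: only 5 windows -> excluded
  sel <- select_bound_windows(win, crac, "fg", rp)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$transcript_id, "t1")
  expect_equal(sel$enrichment, 15)
  ## monotone in the enrichment threshold
  sel_lo <- select_bound_windows(win, crac, "fg", rp, min_enrich = 5)
  expect_true(all(paste(sel$transcript_id, sel$start) %in%
                  paste(sel_lo$transcript_id, sel_lo$start)))
})

test_that("a planted structure motif is flagged and permuted labels are not", {
  set.seed(77)
  n_tx <- 12; wins_per_tx <- 12
  win <- data.frame(
    transcript_id = rep(sprintf("t%02d", 1:n_tx), each = wins_per_tx),
    region = "cds", start = rep(seq(0, by = 10, length.out = wins_per_tx),
                                n_tx))
  win$end <- win$start + 50
  ## random structure strings; plant a fixed 10-mer in one window per transcript
  strs <- replicate(nrow(win), paste(sample(c("|", "."), 50, TRUE),
                                     collapse = ""))
  motif <- "||||||||||"
  strs <- vapply(strs, function(s) {
    ## scrub chance occurrences of the planted motif from the background
    while (grepl(motif, s, fixed = TRUE))
      s <- sub(motif, paste(sample(c("|", "."), 10, TRUE, prob = c(.3, .7)),
                            collapse = ""), s, fixed = TRUE)
    s
  }, "", USE.NAMES = FALSE)
  fg_rows <- which(win$start == 50)
  strs[fg_rows] <- paste0(strrep(".", 20), motif, strrep(".", 20))
  fg <- win[fg_rows, ]
  z <- motif_zscores(fg, win, strs, k = 10, n_bg = 100, seed = 5)
  row <- z[z$motif == motif, ]
  expect_true(row$flagged)
  expect_gt(row$z, 2.5)
  ## foreground drawn from the background distribution: nothing flagged
  fg_null <- win[win$start == 40, ]
  z0 <- motif_zscores(fg_null, win, strs, k = 10, n_bg = 100, seed = 6)
  expect_lte(mean(z0$flagged), 0.05)
  ## degenerate convention: sd 0 and fg equal to bg mean -> z = 0
  same <- rep(paste0(strrep(".", 20), motif, strrep(".", 20)), nrow(win))
  zd <- motif_zscores(fg, win, same, k = 10, n_bg = 10, seed = 7)
  expect_true(all(zd$z == 0))
})

test_that("direct comparison counts motifs in both bound sets", {
  s1 <- c("||||||||||....", "....||||||||||")
  s2 <- c("..............")
  d <- motif_direct_comparison(s1, s2, k = 10)
  row <- d[d$motif == "||||||||||", ]
  expect_equal(row$count1, 2)
  expect_equal(row$count2, 0)
  expect_equal(row$log2_ratio, log2(3))
})

test_that("structured-region profiles select, extend and bin windows", {
  stem <- "GGCGGCGGCGGC"
  hp50 <- paste0(stem, "GAAA", ribostall:::revcomp(stem), strrep("A", 22))
  ## build a transcript whose first CDS window is the hairpin
  cds <- paste0("ATG", strrep("GCA", 49), "TAA")
  cds <- paste0(hp50, substr(cds, 51, nchar(cds)))  # window 1 = hairpin
  m <- toy_model(strrep("C", 100), cds, strrep("C", 100))
  tracks <- list(TX1 = rep(1, m$tx_len))
  tracks$TX1[m$cds_start + 25] <- 50   # spike inside the structured window
  prof <- structured_region_profile(m, tracks)
  expect_gt(nrow(prof), 0)
  ## 242-nt window: 40 full 6-nt bins plus a kept 2-nt partial bin
  expect_equal(nrow(prof), 41L)
  expect_true(attr(prof, "partial_last_bin"))
  expect_equal(sum(prof$value), prof$n_windows[1])
  ## a window with max paired run 9 is rejected even at low mfe
  short_stem <- "GGCGGCGGC"   # 9 bp
  hp9 <- paste0(short_stem, "GAAA", ribostall:::revcomp(short_stem),
                strrep("A", 50 - 22))
  cds2 <- paste0(hp9, substr(paste0("ATG", strrep("GCA", 49), "TAA"), 51, 150))
  m2 <- toy_model(strrep("C", 100), cds2, strrep("C", 100))
  prof2 <- structured_region_profile(m2, list(TX1 = rep(1, m2$tx_len)))
  expect_equal(nrow(prof2), 0L)
})
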