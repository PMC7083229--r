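test_that("hexamer window geometry matches the printed description", {
  m <- toy_model(strrep("A", 10),
                 paste0("ATG", paste(rep("GCA", 332), collapse = ""), "TAA"),
                 strrep("C", 10))  # 1002-nt CDS
  m$cds_len <- 1000L; m$cds_end <- m$cds_start + 1000L  # exact 1000 for count
  m$sequence <- substr(m$sequence, 1, m$cds_start + 1000L + 10L)
  m$tx_len <- nchar(m$sequence)
  w <- hexamer_windows(m)
  expect_equal(nrow(w), 1000 - 204 + 1)
  cds <- substr(m$sequence, m$cds_start + 1, m$cds_end)
  expect_equal(w$hexamer[1], substr(cds, 100, 105))  # window bases [99,105)
  expect_equal(w$frame[w$hex_start == 102][1], 0L)   # CDS+102 -> frame 0
  expect_equal(w$frame, w$hex_start %% 3L)
  ## CDS shorter than a window yields no windows
  short <- toy_model("AA", paste0("ATG", strrep("GCA", 30), "TAA"), "AA")
  expect_equal(nrow(hexamer_windows(short)), 0L)
})

test_that("end profiles drop sparse windows and normalize per window", {
  spec <- synthetic_spec(n_transcripts = 1, utr5_len = 20, cds_len = 300,
                         utr3_len = 20, seed = 41)
  tx <- build_transcriptome(spec)
  m <- tx$models
  ## 4 ends in one window's span -> window dropped at the 5-count threshold
  ends4 <- data.frame(transcript_id = m$transcript_id,
                      pos = m$cds_start + c(10, 50, 100, 150))
  hp4 <- hexamer_end_profiles(ends4, m, min_reads_per_mrna = 1)
  expect_equal(nrow(hp4$keys), 0L)
  ## 5 ends: every window containing all of them is retained and its profile
  ## is the normalized pileup
  ends5 <- data.frame(transcript_id = m$transcript_id,
                      pos = m$cds_start + c(100, 100, 101, 102, 150))
  hp5 <- hexamer_end_profiles(ends5, m, min_reads_per_mrna = 1)
  expect_gt(nrow(hp5$keys), 0L)
  expect_equal(unname(rowSums(hp5$positions)), rep(1, nrow(hp5$positions)))
  ## mRNA below the 5-read filter contributes nothing
  hp_few <- hexamer_end_profiles(ends5[1:4, ], m)
  expect_equal(nrow(hp_few$keys), 0L)
})

test_that("bound hexamer calls require beating all controls and uniformity", {
  mk <- function(hex, frame, central) {
    keys <- data.frame(hexamer = hex, frame = frame, n_windows = 10L,
                       central6_sum = central)
    structure(list(keys = keys, positions = matrix(0, length(hex), 204),
                   window = 204L, center = 99L),
              class = "hexamer_profiles")
  }
  fg <- mk(c("AAGAAG", "CCCGGG", "TTTCCC"), c(0L, 0L, 1L),
           c(0.10, 0.02, 0.05))
  bg1 <- mk(c("AAGAAG", "CCCGGG"), c(0L, 0L), c(0.03, 0.01))
  bg2 <- mk("AAGAAG", 0L, c(0.02))
  calls <- call_bound_hexamers(fg, list(bg1, bg2))
  expect_true(calls$bound[calls$hexamer == "AAGAAG"])       # 0.10 > 0.03 > 6/204
  expect_false(calls$bound[calls$hexamer == "CCCGGG"])      # 0.02 < 6/204
  expect_true(calls$bound[calls$hexamer == "TTTCCC"])       # bg missing -> 0
  ## equality with a control is not bound (strict)
  bg_eq <- mk("AAGAAG", 0L, 0.10)
  expect_false(call_bound_hexamers(fg, list(bg_eq))$bound[1])
})

test_that("amino-acid-pair proportions enumerate contributing hexamers", {
  ## KK is encoded by {AAA, AAG}^2: four hexamers, three bound
  kk <- c("AAAAAA", "AAAAAG", "AAGAAA", "AAGAAG")
  calls <- data.frame(hexamer = c(kk, "GGGGGG", "TAAAAA"),
                      frame = 0L,
                      central6_sum = 0.1, bg_max = 0,
                      bound = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  pp <- aa_pair_proportions(calls, min_hexamers = 4)
  expect_equal(pp$proportion[pp$pair == "KK"], 0.75)
  ## GG has one contributing hexamer -> omitted at the 4-hexamer floor
  expect_false("GG" %in% pp$pair)
  ## stop-codon hexamers are excluded from translation
  expect_equal(attr(pp, "n_stop_excluded"), 1L)
  ## with no bound keys all retained pairs are 0
  calls$bound <- FALSE
  pp0 <- aa_pair_proportions(calls, min_hexamers = 4)
  expect_true(all(pp0$proportion == 0))
})

test_that("in-frame signal exceeds out-of-frame for a planted codon-pair", {
  spec <- synthetic_spec(
    n_transcripts = 8, cds_len = 450,
    planted_stall_hexamers = data.frame(hexamer = "AAGAAG", frame = 0,
                                        multiplier = 60), seed = 47)
  tx <- build_transcriptome(spec)
  cr <- simulate_crac_reads(tx, spec, reads_per_transcript = 400)
  ends <- data.frame(transcript_id = cr$segments$reference_id,
                     pos = three_prime_end(cr$segments))
  fg <- hexamer_end_profiles(ends, tx$models)
  k <- fg$keys
  planted <- k$central6_sum[k$hexamer == "AAGAAG" & k$frame == 0]
  out_of_frame <- k$central6_sum[k$hexamer == "AAGAAG" & k$frame != 0]
  expect_gt(planted, 6 / 204)
  if (length(out_of_frame)) expect_gt(planted, max(out_of_frame))
})

test_that("repeat-tract windows are built, binned and grouped correctly", {
  ## KKKK tract: 12 nt + 2 * 96 flank = 204 nt -> 34 six-nt bins
  cds <- paste0("ATG", strrep("GCA", 40), strrep("AAA", 4),
                strrep("GCA", 40), "TAA")
  m <- toy_model(strrep("C", 100), cds, strrep("C", 100))
  tract_start <- m$cds_start + 3 + 120
  ends <- data.frame(transcript_id = "TX1",
                     pos = rep(tract_start + 6, 30))  # spike at tract centre
  tp <- tract_profiles(ends, m, "aa_repeat", group = "residue")
  expect_equal(unique(tp$group), "K")
  expect_equal(nrow(tp), 34L)
  expect_equal(tp$bin[which.max(tp$value)], (96 + 6) %/% 6)
  ## polypurine rule: 11 A + G, in frame, 12 nt, qualifies
  cds2 <- paste0("ATG", strrep("GCA", 33), "AAAAAAAAAAAG",
                 strrep("GCA", 33), "TAA")
  m2 <- toy_model(strrep("C", 100), cds2, strrep("C", 100))
  tr <- ribostall:::find_tracts(m2, "polypurine")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$end - tr$start, 12L)
  ## a 10-nt purine run does not qualify
  cds3 <- paste0("ATG", strrep("GCA", 33), "AAAAAAAAAG", "CC",
                 strrep("GCA", 33), "TAA")
  m3 <- toy_model(strrep("C", 100), cds3, strrep("C", 100))
  expect_null(ribostall:::find_tracts(m3, "polypurine"))
})
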