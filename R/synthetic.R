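STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

#' Default ERCC spike-in panel
#'
#' A small deterministic panel of 30 spike-ins whose expected counts span
#' roughly 5 to 5000, so that the "mean > 50 counts" eligibility filter used
#' in half-life normalization has both passing and failing members.
#'
#' @return data frame with columns `id`, `abundance` (expected counts).
#' @export
default_ercc_panel <- function() {
  data.frame(id = sprintf("ERCC-%05d", seq_len(30)),
             abundance = round(5 * 2^seq(0, 10, length.out = 30)))
}

#' Specification for the synthetic ground-truth generator
#'
#' Bundles every tunable of the simulated study: transcript architecture,
#' planted stall hexamers, uORFs and structured windows, the non-templated
#' 3'-tail rate, the per-transcript half-life map and the ERCC panel.
#'
#' @param n_transcripts number of (single-isoform) transcripts.
#' @param utr5_len,cds_len,utr3_len length or `c(min, max)` range in nt; CDS
#'   lengths are rounded down to a multiple of 3 (>= 9 nt, ATG...stop).
#' @param planted_stall_hexamers optional data frame with columns `hexamer`
#'   (6-nt), `frame` (0/1/2 relative to the CDS start) and `multiplier`
#'   (fragment 3'-end enrichment over the uniform background; must be >= 1).
#'   Each hexamer is planted once per transcript where space allows.
#' @param planted_uorfs optional data frame with columns `transcript`
#'   (index), `start` (0-based offset in the 5'UTR) and `len` (nt including
#'   the stop codon; multiple of 3, >= 6).
#' @param planted_structured_windows optional data frame with columns
#'   `transcript`, `pos` (0-based transcript coordinate), `stem_len` (bp) and
#'   `gc` (stem GC fraction); a perfect hairpin with a 4-nt loop is written.
#' @param tail_prob probability that a simulated CRAC read carries a
#'   non-templated homopolymeric 3' tail.
#' @param tail_base the tail nucleotide (DNA alphabet; `"T"` represents U).
#' @param halflife_map half-lives in minutes: a single value or a vector
#'   recycled/named over transcripts; must be > 0.
#' @param ercc_panel spike-in panel; defaults to [default_ercc_panel()].
#' @param seed RNG seed making every generator call deterministic.
#' @return a list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_transcripts = 20L,
                           utr5_len = c(60L, 150L),
                           cds_len = c(300L, 900L),
                           utr3_len = c(60L, 200L),
                           planted_stall_hexamers = NULL,
                           planted_uorfs = NULL,
                           planted_structured_windows = NULL,
                           tail_prob = 0, tail_base = "T",
                           halflife_map = 120,
                           ercc_panel = default_ercc_panel(),
                           seed = 1L) {
  if (tail_prob < 0 || tail_prob > 1) .stopf("tail_prob must be in [0, 1]")
  if (!tail_base %in% c("A", "C", "G", "T")) .stopf("tail_base must be A/C/G/T")
  if (any(halflife_map <= 0)) .stopf("half-lives must be > 0")
  if (!is.null(planted_stall_hexamers)) {
    stopifnot(all(nchar(planted_stall_hexamers$hexamer) == 6L),
              all(planted_stall_hexamers$frame %in% 0:2))
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
                 planted_stall_hexamers = planted_stall_hexamers,
                 planted_uorfs = planted_uorfs,
                 planted_structured_windows = planted_structured_windows,
                 tail_prob = tail_prob, tail_base = tail_base,
                 halflife_map = halflife_map, ercc_panel = ercc_panel,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

sample_len <- function(r, n) {
  if (length(r) == 1L) rep(as.integer(r), n)
  else sample(seq.int(r[1], r[2]), n, replace = TRUE)
}

#' Generate a ground-truth transcriptome
#'
#' Builds `n_transcripts` single-isoform transcripts (random UTRs, an
#' ATG...stop CDS of sense codons) and plants the features requested in the
#' spec, recording each as ground truth: uORFs in the 5'UTR, stall hexamers
#' at frame-consistent CDS positions (with >= 99 nt margin so a centred
#' 204-nt window exists) and perfect-hairpin structured windows.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `sequences` (named character), `models` (one
#'   row per transcript: ids, region lengths, 0-based half-open `cds_start`/
#'   `cds_end`, `tx_len`, `sequence`), `annotation` (BED-style region table)
#'   and `truth` (list of tables: `uorfs`, `stall_sites`, `structured`,
#'   `halflife`).
#' @export
build_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_transcripts
    u5 <- sample_len(spec$utr5_len, n)
    cd <- sample_len(spec$cds_len, n)
    cd <- pmax(9L, (cd %/% 3L) * 3L)
    u3 <- sample_len(spec$utr3_len, n)
    ids <- sprintf("TX%04d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(n))
    seqs <- character(n)
    for (i in seq_len(n)) {
      body <- paste(sample(sense_codons(), cd[i] / 3L - 2L, replace = TRUE),
                    collapse = "")
      seqs[i] <- paste0(random_dna(u5[i]), "ATG", body,
                        sample(STOP_CODONS, 1L), random_dna(u3[i]))
    }
    truth_uorfs <- NULL
    if (!is.null(spec$planted_uorfs)) {
      pu <- spec$planted_uorfs
      for (j in seq_len(nrow(pu))) {
        i <- pu$transcript[j]; s <- pu$start[j]; len <- pu$len[j]
        if (len < 6L || len %% 3L != 0L)
          .stopf("uORF length must be a multiple of 3 and >= 6 (transcript %s)", ids[i])
        if (s + len > u5[i])
          .stopf("uORF outside 5'UTR extent for transcript %s", ids[i])
        body <- if (len > 6L)
          paste(sample(sense_codons(), len / 3L - 2L, replace = TRUE), collapse = "")
        else ""
        substr(seqs[i], s + 1L, s + len) <- paste0("ATG", body, "TAA")
        ## scrub upstream in-frame ATG/stops that would shift the planted call
        truth_uorfs <- rbind(truth_uorfs,
                             data.frame(transcript_id = ids[i], start = s,
                                        end = s + len, len = len))
      }
    }
    truth_stalls <- NULL
    if (!is.null(spec$planted_stall_hexamers)) {
      ph <- spec$planted_stall_hexamers
      for (j in seq_len(nrow(ph))) {
        for (i in seq_len(n)) {
          lo <- 99L + (ph$frame[j] - 99L) %% 3L  # smallest offset >= 99 in frame
          if (cd[i] - 105L < lo) next
          cand <- seq.int(lo, cd[i] - 105L, by = 3L)
          if (!length(cand)) next
          h <- sample(cand, 1L)
          substr(seqs[i], u5[i] + h + 1L, u5[i] + h + 6L) <- ph$hexamer[j]
          truth_stalls <- rbind(truth_stalls,
                                data.frame(transcript_id = ids[i],
                                           hexamer = ph$hexamer[j],
                                           frame = ph$frame[j],
                                           cds_offset = h,
                                           tx_pos = u5[i] + h,
                                           multiplier = ph$multiplier[j]))
        }
      }
    }
    truth_struct <- NULL
    if (!is.null(spec$planted_structured_windows)) {
      ps <- spec$planted_structured_windows
      for (j in seq_len(nrow(ps))) {
        i <- ps$transcript[j]
        stem <- ps$stem_len[j]
        ngc <- round(ps$gc[j] * stem)
        left <- paste(sample(c(sample(c("G", "C"), ngc, replace = TRUE),
                               sample(c("A", "T"), stem - ngc, replace = TRUE))),
                      collapse = "")
        hp <- paste0(left, "GAAA", revcomp(left))
        pos <- ps$pos[j]
        if (pos + nchar(hp) > nchar(seqs[i]))
          .stopf("structured window outside transcript %s", ids[i])
        substr(seqs[i], pos + 1L, pos + nchar(hp)) <- hp
        truth_struct <- rbind(truth_struct,
                              data.frame(transcript_id = ids[i], start = pos,
                                         end = pos + nchar(hp),
                                         stem_len = stem, gc = ps$gc[j]))
      }
    }
    th <- spec$halflife_map
    th <- if (!is.null(names(th))) th[ids] else stats::setNames(rep_len(th, n), ids)
    models <- data.frame(transcript_id = ids, gene_id = genes,
                         utr5_len = u5, cds_len = cd, utr3_len = u3,
                         cds_start = u5, cds_end = u5 + cd,
                         tx_len = u5 + cd + u3, sequence = seqs)
    annotation <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(transcript_id = ids[i], gene_id = genes[i],
                 region = c("utr5", "cds", "utr3"),
                 start = c(0L, u5[i], u5[i] + cd[i]),
                 end = c(u5[i], u5[i] + cd[i], u5[i] + cd[i] + u3[i]))
    }))
    annotation <- annotation[annotation$end > annotation$start, ]
    list(sequences = stats::setNames(seqs, ids), models = models,
         annotation = annotation,
         truth = list(uorfs = truth_uorfs, stall_sites = truth_stalls,
                      structured = truth_struct, halflife = th))
  })
}

#' Simulate CRAC reads and their transcriptome alignments
#'
#' Fragment 3' ends are drawn uniformly over each transcript except at
#' planted stall hexamers, whose six positions receive `multiplier`-fold
#' weight.  Each raw read is `4-nt UMI + inline barcode + insert (+ tail)`.
#' With probability `tail_prob` a read gains a homopolymeric non-templated
#' 3' tail; tails are only attached at cleavage positions whose next
#' templated base differs from the tail base, so that a templated-
#' continuation guard can never mistake a planted tail for genomic sequence.
#' Alignments carry MAPQ, best/second-best scores, edit distance and the
#' 3' soft-clipped tail.
#'
#' @param transcriptome result of [build_transcriptome()].
#' @param spec the same [synthetic_spec()].
#' @param reads_per_transcript number of reads per transcript.
#' @param frag_len `c(min, max)` aligned insert length in nt.
#' @param barcode inline sample barcode placed after the UMI.
#' @param sample_name sample label stored on each record.
#' @return list with `raw` (FASTQ-style data frame), `segments` (alignment
#'   data frame) and `truth` (per-read table: 3'-end position, tail status).
#' @export
simulate_crac_reads <- function(transcriptome, spec,
                                reads_per_transcript = 200L,
                                frag_len = c(20L, 40L),
                                barcode = "TAAGC",
                                sample_name = "S1") {
  ph <- spec$planted_stall_hexamers
  if (!is.null(ph) && any(ph$multiplier < 1))
    .stopf("stall enrichment multiplier must be >= 1")
  models <- transcriptome$models
  stalls <- transcriptome$truth$stall_sites
  with_seed(spec$seed + 1L, {
    out <- vector("list", nrow(models))
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      n <- reads_per_transcript
      pmin_ <- frag_len[2] - 1L
      pos <- seq.int(pmin_, m$tx_len - 1L)
      w <- rep(1, length(pos))
      if (!is.null(stalls)) {
        st <- stalls[stalls$transcript_id == m$transcript_id, , drop = FALSE]
        for (j in seq_len(nrow(st))) {
          idx <- which(pos >= st$tx_pos[j] & pos < st$tx_pos[j] + 6L)
          w[idx] <- w[idx] * st$multiplier[j]
        }
      }
      p3 <- sample(pos, n, replace = TRUE, prob = w)
      tailed <- stats::runif(n) < spec$tail_prob
      ## re-draw tailed cleavage sites whose templated continuation matches
      if (any(tailed)) {
        for (k in which(tailed)) {
          tries <- 0L
          while (p3[k] + 1L < m$tx_len &&
                 substr(m$sequence, p3[k] + 2L, p3[k] + 2L) == spec$tail_base &&
                 tries < 100L) {
            p3[k] <- sample(pos, 1L, prob = w)
            tries <- tries + 1L
          }
        }
      }
      len <- sample(seq.int(frag_len[1], frag_len[2]), n, replace = TRUE)
      start <- pmax(p3 - len + 1L, 0L)
      ins_len <- p3 - start + 1L
      tail_len <- ifelse(tailed, 1L + stats::rgeom(n, 0.5), 0L)
      tail <- ifelse(tailed, strrep(spec$tail_base, tail_len), "")
      insert <- substring(m$sequence, start + 1L, p3 + 1L)
      umi <- vapply(seq_len(n), function(z) random_dna(4L), character(1))
      rid <- sprintf("%s_%s_r%04d", sample_name, m$transcript_id, seq_len(n))
      out[[i]] <- data.frame(
        read_id = rid, umi = umi, reference_id = m$transcript_id,
        strand = "+", ref_start = start, ref_end = p3 + 1L,
        cigar = ifelse(tailed, sprintf("%dM%dS", ins_len, tail_len),
                       sprintf("%dM", ins_len)),
        mapq = 42L, score_best = ins_len, score_second = NA_integer_,
        edit_distance = 0L, clipped3_seq = tail,
        read_length = ins_len + tail_len, seq = paste0(insert, tail),
        sample = sample_name,
        raw_seq = paste0(umi, barcode, insert, tail),
        tailed = tailed, tail_len = tail_len, p3 = p3)
    }
    all <- do.call(rbind, out)
    raw <- data.frame(id = all$read_id, seq = all$raw_seq,
                      qual = strrep("I", nchar(all$raw_seq)))
    truth <- data.frame(read_id = all$read_id,
                        transcript_id = all$reference_id,
                        end3 = all$p3, tailed = all$tailed,
                        tail_base = ifelse(all$tailed, spec$tail_base, NA),
                        tail_len = all$tail_len)
    segments <- all[, c("read_id", "umi", "reference_id", "strand",
                        "ref_start", "ref_end", "cigar", "mapq", "score_best",
                        "score_second", "edit_distance", "clipped3_seq",
                        "read_length", "seq", "sample")]
    rownames(segments) <- NULL
    list(raw = raw, segments = segments, truth = truth)
  })
}

#' Simulate monosome/disome footprints and total RNA fragments
#'
#' Planted A-sites are drawn per transcript (uniform over CDS codons unless
#' an `occupancy` weight vector is supplied) and the footprint 5' end placed
#' at `A-site - offset(length, frame)` using the inverted offset tables, so
#' that downstream A-site assignment recovers the planted site exactly.
#'
#' @param transcriptome result of [build_transcriptome()].
#' @param spec the [synthetic_spec()] (used for the seed).
#' @param n_disome,n_monosome,n_totalrna total read numbers per class.
#' @param occupancy optional named list: transcript id -> per-codon weight.
#' @param disome_lengths footprint lengths to draw for disomes; every length
#'   must have an entry in `disome_table` (else a validation error).
#' @param disome_table,monosome_table offset tables, see
#'   [disome_offset_table()] and [default_monosome_offset_table()].
#' @return list with `segments` (alignment data frame with a `read_class`
#'   column: monosome / disome / totalRNA) and `truth` (read id, transcript,
#'   planted A-site and codon; A-site is `NA` for total RNA).
#' @export
simulate_ribo_footprints <- function(transcriptome, spec,
                                     n_disome = 200L, n_monosome = 200L,
                                     n_totalrna = 0L, occupancy = NULL,
                                     disome_lengths = c(58L, 59L, 60L, 62L, 63L),
                                     disome_table = disome_offset_table(),
                                     monosome_table = default_monosome_offset_table()) {
  models <- transcriptome$models
  missing_len <- setdiff(disome_lengths, disome_table$length)
  if (length(missing_len))
    .stopf("no disome offset entry for length(s): %s",
           paste(missing_len, collapse = ", "))
  with_seed(spec$seed + 2L, {
    draw_class <- function(n, lengths, table, class) {
      if (n == 0L) return(NULL)
      ti <- sample(nrow(models), n, replace = TRUE)
      rows <- lapply(seq_len(n), function(k) {
        m <- models[ti[k], ]
        ncod <- m$cds_len / 3L
        wts <- if (!is.null(occupancy) && !is.null(occupancy[[m$transcript_id]]))
          occupancy[[m$transcript_id]] else rep(1, ncod)
        for (try in 1:50) {
          codon <- sample.int(ncod, 1L, prob = wts) - 1L
          a <- m$cds_start + 3L * codon
          L <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
          frame <- sample(0:2, 1L)
          off <- offset_lookup(table, L, frame)
          if (is.na(off)) next
          p5 <- a - off
          if (p5 >= 0L && p5 + L <= m$tx_len)
            return(data.frame(transcript_id = m$transcript_id, a_site = a,
                              codon = codon, p5 = p5, len = L))
        }
        NULL
      })
      rows <- do.call(rbind, rows)
      if (is.null(rows)) return(NULL)
      rows$read_class <- class
      rows
    }
    dis <- draw_class(n_disome, disome_lengths, disome_table, "disome")
    mono <- draw_class(n_monosome, 26:35, monosome_table, "monosome")
    tot <- NULL
    if (n_totalrna > 0L) {
      ti <- sample(nrow(models), n_totalrna, replace = TRUE)
      L <- sample(21:70, n_totalrna, replace = TRUE)
      mx <- models$tx_len[ti]
      L <- pmin(L, mx)
      p5 <- vapply(seq_len(n_totalrna),
                   function(k) sample.int(mx[k] - L[k] + 1L, 1L) - 1L, integer(1))
      tot <- data.frame(transcript_id = models$transcript_id[ti],
                        a_site = NA_integer_, codon = NA_integer_,
                        p5 = p5, len = L, read_class = "totalRNA")
    }
    all <- rbind(dis, mono, tot)
    if (is.null(all))
      all <- data.frame(transcript_id = character(), a_site = integer(),
                        codon = integer(), p5 = integer(), len = integer(),
                        read_class = character())
    rid <- sprintf("FP%06d", seq_len(nrow(all)))
    segments <- data.frame(read_id = rid, umi = NA_character_,
                           reference_id = all$transcript_id, strand = "+",
                           ref_start = all$p5, ref_end = all$p5 + all$len,
                           cigar = sprintf("%dM", all$len), mapq = 255L,
                           score_best = NA_integer_, score_second = NA_integer_,
                           edit_distance = 0L, clipped3_seq = "",
                           read_length = all$len, read_class = all$read_class)
    truth <- data.frame(read_id = rid, transcript_id = all$transcript_id,
                        a_site = all$a_site, codon = all$codon,
                        read_class = all$read_class)
    list(segments = segments, truth = truth)
  })
}

#' Simulate an ERCC-spiked decay time course
#'
#' Expected mRNA counts decay as `N0 * 2^(-t / t_half)`; ERCC rows have
#' time-invariant expectation taken from the spec's panel.  Optional mock
#' samples (no transcription shutoff, collected at the last timepoint) stay
#' at `N0`.  With `depth` set, every library is rescaled to that total count
#' so the matrix is composition-confounded like fixed-depth sequencing.
#'
#' @param transcriptome result of [build_transcriptome()].
#' @param spec the [synthetic_spec()] (half-life map, ERCC panel, seed).
#' @param timepoints minutes after transcription shutoff.
#' @param n_reps replicates per timepoint.
#' @param n0 expected count at t = 0 (scalar or per-transcript); must be > 0.
#' @param noise `"none"` for expected values, `"poisson"` for Poisson counts.
#' @param depth optional total count per library (composition mode).
#' @param mock include `n_reps` mock samples at the final timepoint.
#' @return list with `counts` (matrix, mRNA rows then `ERCC-` rows),
#'   `samples` (sample metadata: timepoint, mock flag) and `truth`
#'   (half-life map).
#' @export
simulate_decay_counts <- function(transcriptome, spec,
                                  timepoints = c(0, 120, 240, 360),
                                  n_reps = 3L, n0 = 1000,
                                  noise = c("none", "poisson"),
                                  depth = NULL, mock = TRUE) {
  noise <- match.arg(noise)
  if (any(n0 <= 0)) .stopf("n0 must be positive")
  models <- transcriptome$models
  th <- transcriptome$truth$halflife
  n0 <- rep_len(n0, nrow(models))
  samples <- data.frame(
    sample = as.vector(t(outer(timepoints, seq_len(n_reps),
                               function(t, r) sprintf("t%03d_r%d", t, r)))),
    timepoint = rep(timepoints, each = n_reps),
    mock = FALSE)
  if (mock) {
    tm <- max(timepoints)
    samples <- rbind(samples,
                     data.frame(sample = sprintf("mock%03d_r%d", tm, seq_len(n_reps)),
                                timepoint = tm, mock = TRUE))
  }
  expected <- sapply(seq_len(nrow(samples)), function(j) {
    if (samples$mock[j]) n0
    else n0 * 2^(-samples$timepoint[j] / th[models$transcript_id])
  })
  ercc <- matrix(spec$ercc_panel$abundance, nrow = nrow(spec$ercc_panel),
                 ncol = nrow(samples))
  counts <- rbind(expected, ercc)
  rownames(counts) <- c(models$transcript_id, spec$ercc_panel$id)
  colnames(counts) <- samples$sample
  if (!is.null(depth))
    counts <- sweep(counts, 2, colSums(counts) / depth, "/")
  if (noise == "poisson")
    counts <- with_seed(spec$seed + 3L, {
      matrix(stats::rpois(length(counts), counts), nrow = nrow(counts),
             dimnames = dimnames(counts))
    })
  list(counts = counts, samples = samples, truth = th)
}

#' Simulate replicated per-bin rRNA coverage counts
#'
#' Negative-binomial (or Poisson, when `dispersion = 0`) counts for a panel
#' of 20-nt rRNA bins in a foreground and a control group, with optional
#' planted fold enrichment in chosen bins of the foreground group.
#'
#' @param n_bins number of bins.
#' @param n_fg,n_ctrl samples per group.
#' @param base_mean expected count per bin.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param enriched_bins indices of foreground-enriched bins.
#' @param fold enrichment factor for those bins.
#' @param seed RNG seed.
#' @return list with `counts` (bins x samples), `group` (factor fg/ctrl) and
#'   `libsize` (column sums).
#' @export
simulate_rrna_bin_counts <- function(n_bins = 40L, n_fg = 5L, n_ctrl = 5L,
                                     base_mean = 100, dispersion = 0.1,
                                     enriched_bins = integer(0), fold = 5,
                                     seed = 1L) {
  with_seed(seed, {
    group <- factor(rep(c("fg", "ctrl"), c(n_fg, n_ctrl)), c("fg", "ctrl"))
    mu <- matrix(base_mean, n_bins, n_fg + n_ctrl)
    if (length(enriched_bins))
      mu[enriched_bins, group == "fg"] <- base_mean * fold
    counts <- if (dispersion > 0)
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_bins, ncol(mu))
    else matrix(stats::rpois(length(mu), mu), n_bins, ncol(mu))
    rownames(counts) <- sprintf("bin%03d", seq_len(n_bins))
    colnames(counts) <- sprintf("%s_%d", group, seq_len(ncol(counts)))
    list(counts = counts, group = group, libsize = colSums(counts))
  })
}
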