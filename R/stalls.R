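#' Sliding hexamer windows across a CDS
#'
#' 204-nt windows at every CDS offset (step 1).  Each window records the
#' hexamer at its centre (window positions `[center, center + 6)`, default
#' 99, i.e. the central 6-mer of an even-length window) and the hexamer's
#' frame relative to the CDS start.
#'
#' @param model one-row transcript model.
#' @param window window length in nt.
#' @param center 0-based window offset of the central hexamer.
#' @return data frame: `transcript_id`, `win_start` (CDS offset),
#'   `hex_start`, `hexamer`, `frame`; empty when the CDS is shorter than
#'   `window`.
#' @export
hexamer_windows <- function(model, window = 204L, center = 99L) {
  cds <- substr(model$sequence, model$cds_start + 1L, model$cds_end)
  n <- nchar(cds)
  if (n < window)
    return(data.frame(transcript_id = character(), win_start = integer(),
                      hex_start = integer(), hexamer = character(),
                      frame = integer()))
  s <- seq.int(0L, n - window)
  hs <- s + center
  data.frame(transcript_id = model$transcript_id, win_start = s,
             hex_start = hs,
             hexamer = substring(cds, hs + 1L, hs + 6L),
             frame = hs %% 3L)
}

#' Hexamer/frame-averaged profiles of fragment 3' ends
#'
#' For every mRNA with at least `min_reads_per_mrna` qualifying reads,
#' fragment 3'-end counts are collected over each sliding CDS window;
#' windows with at least `min_counts_per_window` counts are normalized to
#' their sum, grouped by (central hexamer, frame) and averaged within each
#' group.  Input 3' ends must come from adapter-confirmed reads that were
#' not low-complexity stripped, so each end is a true fragment 3' end.
#'
#' @param ends data frame with `transcript_id` and `pos` (0-based transcript
#'   coordinate of each fragment's last aligned base).
#' @param models transcript model data frame.
#' @param min_reads_per_mrna,min_counts_per_window retention thresholds.
#' @param window,center window geometry (see [hexamer_windows()]).
#' @return object of class `"hexamer_profiles"`: list with `keys` (data
#'   frame: `hexamer`, `frame`, `n_windows`, `central6_sum`), `positions`
#'   (group x window matrix of averaged normalized profiles), `window`,
#'   `center`.
#' @export
hexamer_end_profiles <- function(ends, models, min_reads_per_mrna = 5L,
                                 min_counts_per_window = 5L,
                                 window = 204L, center = 99L) {
  mats <- list(); keys <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    e <- ends[ends$transcript_id == m$transcript_id, , drop = FALSE]
    if (nrow(e) < min_reads_per_mrna) next
    off <- e$pos - m$cds_start
    off <- off[off >= 0L & off < m$cds_len]
    cnt <- tabulate(off + 1L, nbins = m$cds_len)
    w <- hexamer_windows(m, window, center)
    if (!nrow(w)) next
    idx <- outer(w$win_start, seq_len(window) - 1L, "+") + 1L
    mat <- matrix(cnt[idx], nrow(w), window)
    wsum <- rowSums(mat)
    keep <- wsum >= min_counts_per_window
    if (!any(keep)) next
    mats[[length(mats) + 1L]] <- mat[keep, , drop = FALSE] / wsum[keep]
    keys[[length(keys) + 1L]] <- paste(w$hexamer[keep], w$frame[keep])
  }
  if (!length(mats)) {
    out <- list(keys = data.frame(hexamer = character(), frame = integer(),
                                  n_windows = integer(),
                                  central6_sum = numeric()),
                positions = matrix(numeric(), 0L, window),
                window = window, center = center)
    return(structure(out, class = "hexamer_profiles"))
  }
  big <- do.call(rbind, mats)
  key <- unlist(keys)
  summed <- rowsum(big, key)
  nw <- as.vector(table(key)[rownames(summed)])
  avg <- summed / nw
  parts <- strsplit(rownames(summed), " ")
  keys_df <- data.frame(hexamer = vapply(parts, `[`, "", 1L),
                        frame = as.integer(vapply(parts, `[`, "", 2L)),
                        n_windows = nw,
                        central6_sum = rowSums(avg[, center + 1:6, drop = FALSE]))
  structure(list(keys = keys_df, positions = avg, window = window,
                 center = center),
            class = "hexamer_profiles")
}

#' Call bound hexamer/frame combinations
#'
#' A key is bound iff the foreground central-hexamer signal exceeds the
#' corresponding value in every control profile set (strictly) **and**
#' exceeds the value expected if reads were spread evenly over the window
#' (`6 / window`).  Keys absent from a control set contribute a control
#' value of 0 (their number is recorded in the `n_missing_bg` attribute).
#'
#' @param fg foreground [hexamer_end_profiles()] result.
#' @param bg_list list of control `hexamer_profiles` objects.
#' @return data frame: `hexamer`, `frame`, `central6_sum`, `bg_max`,
#'   `bound`.
#' @export
call_bound_hexamers <- function(fg, bg_list) {
  stopifnot(inherits(fg, "hexamer_profiles"))
  k <- fg$keys
  fg_key <- paste(k$hexamer, k$frame)
  bg_max <- rep(0, nrow(k)); n_missing <- 0L
  for (bg in bg_list) {
    bk <- paste(bg$keys$hexamer, bg$keys$frame)
    v <- bg$keys$central6_sum[match(fg_key, bk)]
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    bg_max <- pmax(bg_max, v)
  }
  out <- data.frame(hexamer = k$hexamer, frame = k$frame,
                    central6_sum = k$central6_sum, bg_max = bg_max,
                    bound = k$central6_sum > bg_max &
                            k$central6_sum > 6 / fg$window)
  attr(out, "n_missing_bg") <- n_missing
  out
}

#' Amino-acid-pair proportions of bound hexamers
#'
#' Hexamers are translated directly into amino-acid pairs (e.g. AAAAAG ->
#' KK); hexamers containing a stop codon are excluded.  For each pair the
#' proportion of bound hexamer/frame combinations is computed separately
#' for in-frame (frame 0) and out-of-frame (frames 1 and 2) keys; pairs
#' with fewer than `min_hexamers` contributing combinations are omitted.
#'
#' @param calls result of [call_bound_hexamers()].
#' @param min_hexamers minimum contributing hexamers per pair and frame
#'   class.
#' @return data frame: `pair`, `frame_class`, `n_hexamers`, `n_bound`,
#'   `proportion` (in `[0, 1]`).
#' @export
aa_pair_proportions <- function(calls, min_hexamers = 4L) {
  aa1 <- codons_to_aa(substr(calls$hexamer, 1L, 3L))
  aa2 <- codons_to_aa(substr(calls$hexamer, 4L, 6L))
  ok <- aa1 != "*" & aa2 != "*"
  n_stop <- sum(!ok)
  d <- data.frame(pair = paste0(aa1, aa2)[ok],
                  frame_class = ifelse(calls$frame[ok] == 0L,
                                       "in_frame", "out_frame"),
                  bound = calls$bound[ok])
  agg <- stats::aggregate(bound ~ pair + frame_class, d,
                          function(x) c(n = length(x), b = sum(x)))
  out <- data.frame(pair = agg$pair, frame_class = agg$frame_class,
                    n_hexamers = agg$bound[, "n"], n_bound = agg$bound[, "b"])
  out <- out[out$n_hexamers >= min_hexamers, , drop = FALSE]
  out$proportion <- out$n_bound / out$n_hexamers
  rownames(out) <- NULL
  attr(out, "n_stop_excluded") <- n_stop
  out
}

## in-frame repeat tracts of a transcript model
find_tracts <- function(model, tract_type = c("aa_repeat", "polypurine"),
                        min_run = 3L, max_run = 4L, min_purine = 12L) {
  tract_type <- match.arg(tract_type)
  cds <- substr(model$sequence, model$cds_start + 1L, model$cds_end)
  if (tract_type == "aa_repeat") {
    codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                        seq(3L, nchar(cds), 3L))
    aa <- codons_to_aa(codons)
    r <- rle(aa)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- r$lengths >= min_run & r$lengths <= max_run & r$values != "*"
    if (!any(sel)) return(NULL)
    data.frame(transcript_id = model$transcript_id,
               start = model$cds_start + 3L * (starts[sel] - 1L),
               end = model$cds_start + 3L * ends[sel],
               group = r$values[sel])
  } else {
    m <- gregexpr("[AG]+", cds)[[1]]
    if (m[1] == -1L) return(NULL)
    s <- as.integer(m) - 1L
    e <- s + attr(m, "match.length")
    s2 <- ((s + 2L) %/% 3L) * 3L   # trim to codon boundaries, in frame
    e2 <- (e %/% 3L) * 3L
    sel <- e2 - s2 >= min_purine
    if (!any(sel)) return(NULL)
    seqs <- substring(cds, s2[sel] + 1L, e2[sel])
    data.frame(transcript_id = model$transcript_id,
               start = model$cds_start + s2[sel],
               end = model$cds_start + e2[sel],
               g_frac = vapply(strsplit(seqs, ""),
                               function(x) mean(x == "G"), numeric(1)),
               lys_frac = vapply(seqs, function(q) {
                 cod <- substring(q, seq(1L, nchar(q) - 2L, 3L),
                                  seq(3L, nchar(q), 3L))
                 mean(codons_to_aa(cod) == "K")
               }, numeric(1), USE.NAMES = FALSE))
  }
}

#' Binned 3'-end profiles around repeat tracts
#'
#' Identifies in-frame tracts (runs of 3-4 identical amino acids, or
#' polypurine runs of at least 12 nt trimmed to codon boundaries), extends
#' each by `flank` nt either side, piles fragment 3' ends over the window,
#' normalizes each window (to its maximum for amino-acid repeats, to its
#' sum for polypurine tracts), sums the per-window profiles within groups
#' after `bin`-nt binning.  Windows extending past the transcript are
#' zero-padded and flagged; bins are aligned on the window start (the left
#' flank is constant), and a trailing partial bin is kept.
#'
#' @param ends data frame with `transcript_id`, `pos` (fragment 3' ends).
#' @param models transcript model data frame.
#' @param tract_type `"aa_repeat"` or `"polypurine"`.
#' @param group grouping of windows: `"residue"` (repeat amino acid),
#'   `"ga_content"` (G-rich / A-rich / mixed at 50%), or `"lysine30"`
#'   (encoded lysine fraction > 30% vs other).
#' @param flank,bin window flank and bin size in nt.
#' @param min_run,max_run,min_purine tract definitions.
#' @return data frame: `group`, `bin` (0-based), `value` (summed normalized
#'   signal), `n_windows`; attribute `n_truncated` counts flagged windows.
#' @export
tract_profiles <- function(ends, models,
                           tract_type = c("aa_repeat", "polypurine"),
                           group = c("residue", "ga_content", "lysine30"),
                           flank = 96L, bin = 6L,
                           min_run = 3L, max_run = 4L, min_purine = 12L) {
  tract_type <- match.arg(tract_type)
  group <- match.arg(group)
  acc <- list(); n_trunc <- 0L
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    tr <- find_tracts(m, tract_type, min_run, max_run, min_purine)
    if (is.null(tr)) next
    e <- ends$pos[ends$transcript_id == m$transcript_id]
    for (j in seq_len(nrow(tr))) {
      ws <- tr$start[j] - flank; we <- tr$end[j] + flank
      trunc <- ws < 0L || we > m$tx_len
      n_trunc <- n_trunc + trunc
      inwin <- e[e >= max(ws, 0L) & e < min(we, m$tx_len)]
      v <- tabulate(inwin - ws + 1L, nbins = we - ws)
      tot <- if (tract_type == "aa_repeat") max(v) else sum(v)
      if (tot == 0) next
      v <- v / tot
      binned <- as.vector(tapply(v, (seq_along(v) - 1L) %/% bin, sum))
      g <- switch(group,
        residue = if (tract_type == "aa_repeat") tr$group[j] else "all",
        ga_content = if (tr$g_frac[j] > 0.5) "G-rich"
                     else if (tr$g_frac[j] < 0.5) "A-rich" else "mixed",
        lysine30 = if (tr$lys_frac[j] > 0.3) "K>30%" else "other")
      acc[[length(acc) + 1L]] <- list(g = g, b = binned, truncated = trunc)
    }
  }
  if (!length(acc))
    return(structure(data.frame(group = character(), bin = integer(),
                                value = numeric(), n_windows = integer()),
                     n_truncated = n_trunc))
  groups <- vapply(acc, `[[`, "", "g")
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    bs <- lapply(acc[groups == g], `[[`, "b")
    nb <- max(lengths(bs))
    summed <- rowSums(vapply(bs, function(b) c(b, rep(0, nb - length(b))),
                             numeric(nb)))
    data.frame(group = g, bin = seq_len(nb) - 1L, value = summed,
               n_windows = sum(groups == g))
  }))
  rownames(out) <- NULL
  structure(out, n_truncated = n_trunc)
}
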