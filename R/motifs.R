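#' Tile 50-nt sliding windows over 5'UTRs and CDSes
#'
#' Windows start at offsets 0, `offset`, 2*`offset`, ... within each region;
#' partial tails shorter than `width` are dropped.
#'
#' @param models transcript model data frame.
#' @param width,offset window width and step in nt.
#' @param regions regions to tile (`"utr5"`, `"cds"`).
#' @return data frame: `transcript_id`, `region`, `start`, `end` (0-based,
#'   half-open transcript coordinates), `sequence`.
#' @export
tile_windows <- function(models, width = 50L, offset = 10L,
                         regions = c("utr5", "cds")) {
  out <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    bounds <- list(utr5 = c(0L, m$cds_start), cds = c(m$cds_start, m$cds_end))
    for (r in regions) {
      b <- bounds[[r]]
      if (b[2] - b[1] < width) next
      s <- seq.int(b[1], b[2] - width, by = offset)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = m$transcript_id, region = r, start = s,
        end = s + width,
        sequence = substring(m$sequence, s + 1L, s + width))
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), region = character(),
                      start = integer(), end = integer(),
                      sequence = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## maximum-weight base pairing (Nussinov-style): min loop 3, GU allowed,
## per-pair pseudo-energies.  Returns list(dotbracket, score).
nussinov_fold <- function(seq, min_loop = 3L,
                          weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- chartr("T", "U", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "U")))
    .stopf("sequence contains non-ACGU characters")
  n <- length(ch)
  pw <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = , CG = weights[["GC"]], AU = , UA = weights[["AU"]],
           GU = , UG = weights[["GU"]], 0)
  }
  M <- matrix(0, n, n)
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]               # i unpaired
      if (j - i > min_loop) {
        w <- pw(ch[i], ch[j])
        if (w > 0) {
          inner <- if (j - 1L >= i + 1L) M[i + 1L, j - 1L] else 0
          best <- max(best, inner + w)
        }
      }
      if (j - 1L >= i) best <- max(best, M[i, j - 1L])  # j unpaired
      if (j > i + 1L) for (k in seq.int(i + 1L, j - 1L))
        best <- max(best, M[i, k] + M[k + 1L, j])
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j) next
    if (M[i, j] == M[i + 1L, j]) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    w <- pw(ch[i], ch[j])
    inner <- if (j - 1L >= i + 1L) M[i + 1L, j - 1L] else 0
    if (w > 0 && j - i > min_loop && M[i, j] == inner + w) {
      db[i] <- "("; db[j] <- ")"
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    done <- FALSE
    if (j > i + 1L) for (k in seq.int(i + 1L, j - 1L)) {
      if (M[i, j] == M[i, k] + M[k + 1L, j]) {
        stack[[length(stack) + 1L]] <- c(i, k)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        done <- TRUE; break
      }
    }
    if (!done) next
  }
  list(dotbracket = paste(db, collapse = ""), score = M[1L, n])
}

## mark G-quadruplex runs with '+' over a dot-bracket string
mark_quadruplex <- function(seq, dotbracket) {
  s <- chartr("T", "U", toupper(seq))
  m <- gregexpr("G{3,}([ACGU]{1,7}G{3,}){3}", s)[[1]]
  if (m[1] == -1L) return(dotbracket)
  db <- strsplit(dotbracket, "")[[1]]
  for (k in seq_along(m)) {
    idx <- seq.int(m[k], m[k] + attr(m, "match.length")[k] - 1L)
    db[idx] <- "+"
  }
  paste(db, collapse = "")
}

#' Parse an RNAfold-style output file
#'
#' Records of `>name` / sequence / `dot-bracket (mfe)` lines (the header
#' line is optional).  Used as the external-fold adapter backend of
#' [fold_window()].
#'
#' @param path file of folding results.
#' @return data frame: `name`, `sequence`, `dotbracket`, `mfe`.
#' @export
read_fold_file <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  out <- list(); i <- 1L; k <- 0L
  while (i <= length(x)) {
    nm <- NA_character_
    if (startsWith(x[i], ">")) { nm <- sub("^>\\s*", "", x[i]); i <- i + 1L }
    sq <- x[i]; st <- x[i + 1L]; i <- i + 2L
    mfe <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", st))
    db <- sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", st)
    k <- k + 1L
    out[[k]] <- data.frame(name = nm, sequence = sq, dotbracket = db, mfe = mfe)
  }
  do.call(rbind, out)
}

#' Fold a window sequence (pluggable backend)
#'
#' Backends: `"fallback"`, a maximum base-pairing model (Nussinov-style
#' dynamic program; minimum loop 3, GU pairs allowed) with fixed per-pair
#' pseudo-energies (GC -3, AU -2, GU -1 kcal/mol) — explicitly **not** a
#' thermodynamic model — plus regex G-quadruplex annotation
#' (`G{3,}(N{1,7}G{3,}){3}`, marked `+`); or `"file"`, an adapter that looks
#' the sequence up in a table of precomputed results (see
#' [read_fold_file()]).  The backend used is recorded in the result.
#'
#' @param sequence a 50-nt (or any length) ACGU/ACGT sequence.
#' @param backend `"fallback"` or `"file"`.
#' @param fold_table precomputed results for the file backend.
#' @return list with `dotbracket` (with `+` quadruplex marks), `mfe`
#'   (kcal/mol; 0 for an unpaired fallback fold) and `backend`.
#' @export
fold_window <- function(sequence, backend = c("fallback", "file"),
                        fold_table = NULL) {
  backend <- match.arg(backend)
  if (backend == "file") {
    if (is.null(fold_table)) .stopf("file backend requires fold_table")
    hit <- match(sequence, fold_table$sequence)
    if (is.na(hit)) .stopf("sequence not found in fold_table")
    return(list(dotbracket = mark_quadruplex(sequence,
                                             fold_table$dotbracket[hit]),
                mfe = fold_table$mfe[hit], backend = "file"))
  }
  f <- nussinov_fold(sequence)
  list(dotbracket = mark_quadruplex(sequence, f$dotbracket),
       mfe = -f$score, backend = "fallback")
}

#' Encode a dot-bracket string over the paired/unpaired/quadruplex alphabet
#'
#' `(` and `)` become `|` (paired), `.` stays unpaired, `+` stays
#' quadruplex — the 3-letter alphabet over which structure k-mer motifs are
#' counted.
#'
#' @param dotbracket character vector of annotations.
#' @return encoded character vector.
#' @export
structure_alphabet <- function(dotbracket) {
  chartr("()", "||", dotbracket)
}

#' Select bound foreground windows
#'
#' Enrichment is window CRAC RPKM divided by the transcript's RNA-seq RPKM.
#' Transcripts with RNA-seq RPKM below `min_rpkm` or with fewer than
#' `min_windows` analyzed windows are excluded.  A window is bound when the
#' foreground enrichment exceeds every background enrichment and is at
#' least `min_enrich`; per transcript and region the maximum-enrichment
#' bound window is kept.
#'
#' @param windows window table from [tile_windows()].
#' @param crac_rpkm windows x datasets matrix of CRAC RPKM; `fg` names the
#'   foreground column, the others are backgrounds.
#' @param fg foreground dataset (column) name.
#' @param rnaseq_rpkm named vector of transcript RNA-seq RPKM.
#' @param min_rpkm,min_enrich,min_windows thresholds.
#' @return the selected foreground windows with an `enrichment` column.
#' @export
select_bound_windows <- function(windows, crac_rpkm, fg, rnaseq_rpkm,
                                 min_rpkm = 10, min_enrich = 10,
                                 min_windows = 6L) {
  rp <- unname(rnaseq_rpkm[windows$transcript_id])
  nwin <- table(windows$transcript_id)
  ok_tx <- !is.na(rp) & rp >= min_rpkm &
    as.vector(nwin[windows$transcript_id]) >= min_windows
  enr <- crac_rpkm / rp
  bgmax <- apply(enr[, setdiff(colnames(enr), fg), drop = FALSE], 1, max)
  bound <- ok_tx & enr[, fg] > bgmax & enr[, fg] >= min_enrich
  w <- windows[bound, , drop = FALSE]
  w$enrichment <- enr[bound, fg]
  keys <- paste(w$transcript_id, w$region)
  top <- unlist(lapply(split(seq_len(nrow(w)), keys),
                       function(ix) ix[which.max(w$enrichment[ix])]))
  out <- w[sort(unname(top)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

window_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Motif z-scores against resampled background window sets
#'
#' For each foreground window, `n_bg` background draws sample one window
#' from the same transcript within `max_dist` nt of it, excluding the
#' foreground set (foreground windows with no eligible neighbour are
#' omitted and counted).  For every k-mer the number of windows containing
#' it is compared between foreground and backgrounds:
#' `z = (fg - mean(bg)) / sd(bg)` (0 when the sd is 0 and the counts agree,
#' signed infinite otherwise).  A motif is flagged when `|z| > 2.5` and its
#' total occurrence (fg + mean bg) reaches `occurrence_floor`.
#'
#' @param fg_windows selected foreground windows (rows of `windows`).
#' @param windows the full window table the foreground was selected from.
#' @param motif_strings character vector aligned to `windows` rows: the
#'   encoded structure annotation (see [structure_alphabet()]) or the
#'   sequence, whichever motif space is being tested.
#' @param k motif length (10 for structure, 6 for sequence).
#' @param n_bg number of background sets.
#' @param max_dist maximum start-to-start distance for background windows.
#' @param occurrence_floor minimum total occurrence for flagging.
#' @param seed RNG seed for the resampling.
#' @return data frame: `motif`, `fg_count`, `bg_mean`, `bg_sd`, `z`,
#'   `total_occurrence`, `flagged`; attribute `n_omitted` counts foreground
#'   windows without eligible background.
#' @export
motif_zscores <- function(fg_windows, windows, motif_strings, k = 10L,
                          n_bg = 100L, max_dist = 400L,
                          occurrence_floor = 10, seed = 1L) {
  stopifnot(nrow(windows) == length(motif_strings), nrow(fg_windows) > 0L)
  fg_key <- paste(fg_windows$transcript_id, fg_windows$start)
  all_key <- paste(windows$transcript_id, windows$start)
  is_fg <- all_key %in% fg_key
  elig <- lapply(seq_len(nrow(fg_windows)), function(i) {
    which(windows$transcript_id == fg_windows$transcript_id[i] & !is_fg &
          abs(windows$start - fg_windows$start[i]) <= max_dist)
  })
  n_omitted <- sum(lengths(elig) == 0L)
  elig <- elig[lengths(elig) > 0L]
  kmers <- lapply(motif_strings, window_kmers, k = k)
  fg_idx <- which(is_fg)
  count_set <- function(ix) {
    km <- unlist(kmers[ix])
    tab <- table(km)
    tab
  }
  fg_tab <- count_set(fg_idx)
  bg_tabs <- with_seed(seed, {
    lapply(seq_len(n_bg), function(b) {
      ix <- vapply(elig, function(e) if (length(e) == 1L) e
                   else sample(e, 1L), integer(1))
      count_set(ix)
    })
  })
  motifs <- sort(unique(c(names(fg_tab), unlist(lapply(bg_tabs, names)))))
  fgc <- as.numeric(fg_tab[motifs]); fgc[is.na(fgc)] <- 0
  bgm <- vapply(bg_tabs, function(tb) {
    v <- as.numeric(tb[motifs]); v[is.na(v)] <- 0; v
  }, numeric(length(motifs)))
  bgm <- matrix(bgm, nrow = length(motifs))
  bg_mean <- rowMeans(bgm)
  bg_sd <- apply(bgm, 1, stats::sd)
  z <- ifelse(bg_sd > 0, (fgc - bg_mean) / bg_sd,
              ifelse(fgc == bg_mean, 0, sign(fgc - bg_mean) * Inf))
  total <- fgc + bg_mean
  out <- data.frame(motif = motifs, fg_count = fgc, bg_mean = bg_mean,
                    bg_sd = bg_sd, z = z, total_occurrence = total,
                    flagged = abs(z) > 2.5 & total >= occurrence_floor)
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Compare motif occurrence between two bound window sets directly
#'
#' The direct-comparison mode used when contrasting the bound windows of
#' two conditions (e.g. wild-type versus knockout): per k-mer window
#' occurrence counts in both sets and their log2 ratio (with a +1
#' pseudocount).
#'
#' @param set1_strings,set2_strings encoded annotations (or sequences) of
#'   the two bound window sets.
#' @param k motif length.
#' @return data frame: `motif`, `count1`, `count2`, `log2_ratio`.
#' @export
motif_direct_comparison <- function(set1_strings, set2_strings, k = 10L) {
  t1 <- table(unlist(lapply(set1_strings, window_kmers, k = k)))
  t2 <- table(unlist(lapply(set2_strings, window_kmers, k = k)))
  motifs <- sort(unique(c(names(t1), names(t2))))
  c1 <- as.numeric(t1[motifs]); c1[is.na(c1)] <- 0
  c2 <- as.numeric(t2[motifs]); c2[is.na(c2)] <- 0
  data.frame(motif = motifs, count1 = c1, count2 = c2,
             log2_ratio = log2((c1 + 1) / (c2 + 1)))
}

#' Summed binned coverage over structured windows
#'
#' Non-overlapping 50-nt windows across the 5'UTR + CDS are folded; windows
#' with minimum free energy below `mfe_cut` and a continuous run of at
#' least `min_paired_run` paired nucleotides are extended by `flank` nt
#' either side (242 nt total), the per-position coverage is normalized to
#' the window sum, binned into `bin`-nt bins (the trailing 2-nt partial bin
#' is kept and flagged) and summed across windows.
#'
#' @param models transcript model data frame.
#' @param tracks named list: transcript id -> per-position coverage vector
#'   (e.g. from [transcript_pileup()]).
#' @param mfe_cut,min_paired_run structure selection thresholds.
#' @param width,flank,bin window geometry.
#' @param backend,fold_table folding backend (see [fold_window()]).
#' @return data frame `bin`, `value`, `n_windows`; attributes
#'   `n_truncated` (windows extending past a transcript, zero-padded) and
#'   `partial_last_bin`.
#' @export
structured_region_profile <- function(models, tracks, mfe_cut = -12,
                                      min_paired_run = 10L, width = 50L,
                                      flank = 96L, bin = 6L,
                                      backend = "fallback",
                                      fold_table = NULL) {
  win <- tile_windows(models, width = width, offset = width,
                      regions = c("utr5", "cds"))
  acc <- NULL; nw <- 0L; n_trunc <- 0L
  for (i in seq_len(nrow(win))) {
    f <- fold_window(win$sequence[i], backend = backend,
                     fold_table = fold_table)
    paired <- strsplit(structure_alphabet(f$dotbracket), "")[[1]] == "|"
    runs <- rle(paired)
    if (f$mfe >= mfe_cut || !any(runs$lengths[runs$values] >= min_paired_run))
      next
    m <- models[models$transcript_id == win$transcript_id[i], ]
    ws <- win$start[i] - flank; we <- win$end[i] + flank
    trunc <- ws < 0L || we > m$tx_len
    n_trunc <- n_trunc + trunc
    tr <- tracks[[m$transcript_id]]
    v <- numeric(we - ws)
    lo <- max(ws, 0L); hi <- min(we, m$tx_len)
    v[(lo - ws + 1L):(hi - ws)] <- tr[(lo + 1L):hi]
    if (sum(v) == 0) next
    v <- v / sum(v)
    binned <- as.vector(tapply(v, (seq_along(v) - 1L) %/% bin, sum))
    if (is.null(acc)) acc <- numeric(length(binned))
    acc <- acc + binned
    nw <- nw + 1L
  }
  if (is.null(acc))
    return(structure(data.frame(bin = integer(), value = numeric(),
                                n_windows = integer()),
                     n_truncated = n_trunc, partial_last_bin = FALSE))
  structure(data.frame(bin = seq_along(acc) - 1L, value = acc,
                       n_windows = nw),
            n_truncated = n_trunc,
            partial_last_bin = (width + 2L * flank) %% bin != 0L)
}
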