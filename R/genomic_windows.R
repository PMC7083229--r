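## any-overlap of [ws, we) windows with a set of [fs, fe) features
any_overlap <- function(ws, we, fs, fe) {
  if (!length(fs)) return(rep(FALSE, length(ws)))
  o <- order(fs)
  fs <- fs[o]; fe <- cummax(fe[o])
  k <- findInterval(we - 1L, fs)
  k >= 1L & fe[pmax(k, 1L)] > ws
}

WINDOW_CLASSES <- c("ncRNA", "exon_sense", "intron_sense", "upstream_sense",
                    "exon_antisense", "intron_antisense",
                    "upstream_antisense", "intergenic")

#' Tile the genome into stranded 1-kb windows and classify them
#'
#' Windows are generated in both orientations and classified by the
#' highest-priority overlapping feature: abundant ncRNA (either strand),
#' mRNA exon (sense), mRNA intron (sense), 1-kb region upstream of an mRNA
#' (sense), then the same three antisense, else intergenic.  lincRNA
#' features are ignored (they do not count as abundant ncRNA).  Terminal
#' windows shorter than the window size are emitted but flagged.
#'
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param annotation data frame with `chrom`, `start`, `end`, `strand` and
#'   `type` in `ncRNA` / `exon` / `intron` / `mrna` (gene spans, used to
#'   derive upstream regions) / `lincRNA` (ignored).
#' @param window window size in nt.
#' @return data frame: `chrom`, `start`, `end`, `strand`, `klass`,
#'   `terminal`.
#' @export
tile_and_classify <- function(genome_lengths, annotation, window = 1000L) {
  bad <- setdiff(unique(annotation$chrom), names(genome_lengths))
  if (length(bad))
    .stopf("chromosome(s) absent from genome_lengths: %s",
           paste(bad, collapse = ", "))
  ## derive upstream intervals from mRNA gene spans
  g <- annotation[annotation$type == "mrna", , drop = FALSE]
  ups <- if (nrow(g)) data.frame(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start - window, g$end),
    end = ifelse(g$strand == "+", g$start, g$end + window),
    strand = g$strand, type = "upstream") else NULL
  feats <- rbind(annotation[annotation$type %in% c("ncRNA", "exon", "intron"),
                            c("chrom", "start", "end", "strand", "type")],
                 ups)
  wins <- do.call(rbind, lapply(names(genome_lengths), function(ch) {
    len <- genome_lengths[[ch]]
    s <- seq.int(0L, len - 1L, by = window)
    data.frame(chrom = ch, start = rep(s, 2L),
               end = rep(pmin(s + window, len), 2L),
               strand = rep(c("+", "-"), each = length(s)))
  }))
  wins$terminal <- wins$end - wins$start < window
  klass <- rep("intergenic", nrow(wins))
  check <- function(type, orientation = NULL) {
    hit <- rep(FALSE, nrow(wins))
    for (ch in unique(wins$chrom)) {
      wi <- wins$chrom == ch
      f <- feats[feats$chrom == ch & feats$type == type, , drop = FALSE]
      if (is.null(orientation)) {
        hit[wi] <- any_overlap(wins$start[wi], wins$end[wi], f$start, f$end)
      } else {
        for (st in c("+", "-")) {
          wj <- wi & wins$strand == st
          fst <- if (orientation == "sense") st else setdiff(c("+", "-"), st)
          fj <- f[f$strand == fst, , drop = FALSE]
          hit[wj] <- any_overlap(wins$start[wj], wins$end[wj],
                                 fj$start, fj$end)
        }
      }
    }
    hit
  }
  rules <- list(list("ncRNA", "ncRNA", NULL),
                list("exon_sense", "exon", "sense"),
                list("intron_sense", "intron", "sense"),
                list("upstream_sense", "upstream", "sense"),
                list("exon_antisense", "exon", "antisense"),
                list("intron_antisense", "intron", "antisense"),
                list("upstream_antisense", "upstream", "antisense"))
  unset <- rep(TRUE, nrow(wins))
  for (r in rules) {
    hit <- check(r[[2]], r[[3]]) & unset
    klass[hit] <- r[[1]]
    unset <- unset & !hit
  }
  wins$klass <- factor(klass, WINDOW_CLASSES)
  rownames(wins) <- NULL
  wins
}

## all ATG..in-frame-stop spans in a sequence (0-based, half-open)
find_sorfs <- function(seq) {
  m <- gregexpr("ATG", seq)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  out <- list()
  n <- nchar(seq)
  for (s in as.integer(m)) {
    j <- s + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- data.frame(start = s - 1L, end = j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Sequence features of genomic windows
#'
#' Adds GC fraction, (optionally) a predicted minimum free energy and the
#' small ORFs of each window.  Sequences are strand-aware (reverse
#' complemented for minus-strand windows); sORF coordinates are relative to
#' the window on its own strand.  The MFE of a 1-kb window is the sum over
#' its non-overlapping 50-nt tiles of the folding backend's MFE.
#'
#' @param windows window table from [tile_and_classify()].
#' @param genome named character vector of chromosome sequences.
#' @param fold compute MFE (can be slow with the fallback backend).
#' @param backend,fold_table folding backend (see [fold_window()]).
#' @return list with `windows` (plus `gc`, `mfe`, `n_sorfs`) and `sorfs`
#'   (one row per sORF with its window's coordinates).
#' @export
window_features <- function(windows, genome, fold = FALSE,
                            backend = "fallback", fold_table = NULL) {
  n <- nrow(windows)
  gc <- numeric(n); mfe <- rep(NA_real_, n); nsorf <- integer(n)
  sorfs <- list()
  for (i in seq_len(n)) {
    s <- substr(genome[[windows$chrom[i]]], windows$start[i] + 1L,
                windows$end[i])
    if (windows$strand[i] == "-") s <- revcomp(s)
    ch <- strsplit(s, "")[[1]]
    gc[i] <- mean(ch %in% c("G", "C"))
    if (fold) {
      tiles <- seq.int(1L, max(nchar(s) - 49L, 1L), by = 50L)
      mfe[i] <- sum(vapply(tiles, function(t0) {
        fold_window(substr(s, t0, min(t0 + 49L, nchar(s))),
                    backend = backend, fold_table = fold_table)$mfe
      }, numeric(1)))
    }
    so <- find_sorfs(s)
    nsorf[i] <- nrow(so)
    if (nrow(so))
      sorfs[[length(sorfs) + 1L]] <-
        data.frame(chrom = windows$chrom[i], win_start = windows$start[i],
                   strand = windows$strand[i], sorf_start = so$start,
                   sorf_end = so$end)
  }
  windows$gc <- gc; windows$mfe <- mfe; windows$n_sorfs <- nsorf
  list(windows = windows,
       sorfs = if (length(sorfs)) do.call(rbind, sorfs)
               else data.frame(chrom = character(), win_start = integer(),
                               strand = character(), sorf_start = integer(),
                               sorf_end = integer()))
}

#' Normalize a window count matrix
#'
#' `"median_ratios"` uses DESeq2's `estimateSizeFactorsForMatrix` (RNA-seq
#' and ribosome profiling); `"min_libsize"` scales every column to the
#' smallest library size (CRAC).
#'
#' @param counts windows x samples count matrix.
#' @param method normalization method.
#' @return normalized matrix.
#' @export
normalize_window_counts <- function(counts,
                                    method = c("median_ratios",
                                               "min_libsize")) {
  method <- match.arg(method)
  if (method == "median_ratios") {
    sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
    sweep(counts, 2, sf, "/")
  } else {
    sweep(counts, 2, colSums(counts) / min(colSums(counts)), "/")
  }
}

#' Log2 fold change with a pseudocount
#'
#' @param x,y normalized counts (e.g. knockout vs wild type).
#' @param pseudo pseudocount (default 4).
#' @return `log2(x + pseudo) - log2(y + pseudo)`.
#' @export
window_lfc <- function(x, y, pseudo = 4) {
  log2(x + pseudo) - log2(y + pseudo)
}

#' Categorize windows by fold change and compare other data types
#'
#' The classifying contrast (e.g. SKIV2L CRAC, knockout vs wild type)
#' assigns each window to `down` (LFC <= cuts[1]), `slight_change`,
#' `up` or `strongly_up` (LFC > cuts[3]).  Each additional comparison's
#' LFCs are median-centred on the `down` category (its median becomes
#' exactly 0) and all category pairs are compared by two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests with Bonferroni correction
#' across the pairs.
#'
#' @param class_x,class_y normalized classifying counts per window
#'   (numerator and denominator condition).
#' @param comparisons named list; each element a list with `x` and `y`
#'   normalized count vectors.
#' @param pseudo pseudocount for all LFCs.
#' @param cuts the three LFC cut points.
#' @return list with `lfc`, `category`, and per comparison the centred
#'   LFCs and the pairwise test table.
#' @export
window_lfc_categories <- function(class_x, class_y, comparisons = NULL,
                                  pseudo = 4, cuts = c(-0.5, 0.5, 1.5)) {
  lfc <- window_lfc(class_x, class_y, pseudo)
  category <- cut(lfc, breaks = c(-Inf, cuts, Inf),
                  labels = c("down", "slight_change", "up", "strongly_up"))
  cmp <- lapply(comparisons, function(co) {
    cl <- window_lfc(co$x, co$y, pseudo)
    centred <- cl - stats::median(cl[category == "down"])
    pairs <- utils::combn(levels(category), 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- centred[category == pairs[1, j]]
      b <- centred[category == pairs[2, j]]
      p <- if (length(a) && length(b))
        suppressWarnings(stats::wilcox.test(a, b)$p.value) else NA_real_
      data.frame(cat_a = pairs[1, j], cat_b = pairs[2, j], p = p)
    }))
    tests$p_bonf <- pmin(stats::p.adjust(tests$p, method = "bonferroni"), 1)
    list(lfc = centred, tests = tests)
  })
  list(lfc = lfc, category = category, comparisons = cmp)
}
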