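#' ERCC-anchored size factors for a decay time course
#'
#' Counts are first normalized within each timepoint by median-of-ratios
#' (DESeq2's `estimateSizeFactorsForMatrix`), equalizing replicates.  The
#' per-sample ratio of total mRNA counts to total spike-in counts — over the
#' set of ERCCs with a mean of more than `ercc_min_mean` raw counts across
#' all samples — is then summarized by its median within each timepoint and
#' rescaled so the factor at t = 0 is exactly 1.  These factors estimate the
#' globally remaining mRNA fraction at each timepoint (0.5 at t = 120 under
#' a uniform 2-fold decay with constant spike-ins).
#'
#' For the returned normalized counts each sample is anchored on its total
#' qualifying-ERCC counts (divided by the ratio of its ERCC total to the
#' mean ERCC total of the t = 0 samples).  This makes normalized mRNA counts
#' proportional to absolute abundance whether or not the libraries were
#' sequenced to a fixed depth; for fixed-depth libraries it coincides with
#' scaling each timepoint by its size factor.
#'
#' @param counts matrix with mRNA rows and spike-in rows (rownames prefixed
#'   `"ERCC-"`); columns are time-course samples.
#' @param timepoints numeric vector of minutes, one per column (mock
#'   samples should be excluded by the caller; they are not part of fits).
#' @param ercc_min_mean ERCC eligibility threshold on mean raw counts.
#' @return list with `factors` (named per timepoint, t = 0 scaled to 1),
#'   `ratios` (per-sample mRNA/ERCC ratio), `normalized` (mRNA rows only,
#'   ERCC-anchored) and `ercc_used` (eligible spike-in ids).
#' @export
ercc_size_factors <- function(counts, timepoints, ercc_min_mean = 50) {
  stopifnot(ncol(counts) == length(timepoints))
  is_ercc <- grepl("^ERCC-", rownames(counts))
  if (!any(is_ercc)) .stopf("no ERCC- rows in counts")
  ercc_ok <- is_ercc & rowMeans(counts) > ercc_min_mean
  if (!any(ercc_ok)) .stopf("no ERCC passes the mean > %g filter", ercc_min_mean)
  norm <- counts
  for (t in unique(timepoints)) {
    cols <- which(timepoints == t)
    if (length(cols) >= 2L) {
      sf <- DESeq2::estimateSizeFactorsForMatrix(counts[, cols, drop = FALSE])
      norm[, cols] <- sweep(counts[, cols, drop = FALSE], 2, sf, "/")
    }
  }
  mrna_tot <- colSums(norm[!is_ercc, , drop = FALSE])
  ercc_tot <- colSums(norm[ercc_ok, , drop = FALSE])
  ratios <- mrna_tot / ercc_tot
  tps <- sort(unique(timepoints))
  fac <- vapply(tps, function(t) stats::median(ratios[timepoints == t]),
                numeric(1))
  t0 <- if (0 %in% tps) which(tps == 0) else 1L
  fac <- fac / fac[t0]
  names(fac) <- tps
  ref_ercc <- mean(ercc_tot[timepoints == tps[t0]])
  normalized <- sweep(norm[!is_ercc, , drop = FALSE], 2,
                      ercc_tot / ref_ercc, "/")
  list(factors = fac, ratios = ratios, normalized = normalized,
       ercc_used = rownames(counts)[ercc_ok])
}

#' Fit per-transcript half-lives in semi-log space
#'
#' Ordinary least squares of `ln(normalized counts + 1)` on time; the decay
#' rate `k` is the time coefficient and `t_half = -ln(2) / k` when `k < 0`
#' (reported as `Inf` otherwise).  The residual standard error measures
#' goodness of fit.  Transcripts with fewer than 3 finite points get an
#' `NA` fit.
#'
#' @param normalized transcripts x samples matrix of normalized counts.
#' @param timepoints numeric vector of minutes, one per column.
#' @return data frame: `transcript_id`, `k` (per minute), `t_half`
#'   (minutes), `resid_se`, `n_points`.
#' @export
fit_half_life <- function(normalized, timepoints) {
  normalized <- rbind(normalized)
  y <- log(normalized + 1)
  fit_one <- function(yi) {
    ok <- is.finite(yi)
    if (sum(ok) < 3L)
      return(c(k = NA_real_, se = NA_real_, n = sum(ok)))
    f <- stats::lm.fit(cbind(1, timepoints[ok]), yi[ok])
    rse <- sqrt(sum(f$residuals^2) / (sum(ok) - 2L))
    c(k = unname(f$coefficients[2]), se = rse, n = sum(ok))
  }
  r <- t(apply(y, 1L, fit_one))
  k <- r[, "k"]
  data.frame(transcript_id = rownames(normalized) %||%
               as.character(seq_len(nrow(normalized))),
             k = k,
             t_half = ifelse(is.na(k), NA_real_,
                             ifelse(k < 0, -log(2) / k, Inf)),
             resid_se = r[, "se"], n_points = as.integer(r[, "n"]),
             row.names = NULL)
}
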