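`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG state
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' that package functions taking an explicit `seed` do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## translate a character vector of codons to one-letter amino acids
codons_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op  = sub("^[0-9]+", "", toks))
}

## reference width consumed by a CIGAR string (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## read width consumed by a CIGAR string (M/I/S/=/X)
cigar_read_width <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' 5' end positions of alignment records
#'
#' @param segments alignment data frame with `strand`, `ref_start`, `ref_end`.
#' @return integer vector of 0-based positions of each read's 5' end on the
#'   reference (for minus-strand alignments this is `ref_end - 1`).
#' @export
five_prime_end <- function(segments) {
  ifelse(segments$strand == "-", segments$ref_end - 1L, segments$ref_start)
}

#' 3' end positions of alignment records
#'
#' @inheritParams five_prime_end
#' @return integer vector of 0-based positions of the last aligned base at
#'   each read's 3' end.
#' @export
three_prime_end <- function(segments) {
  ifelse(segments$strand == "-", segments$ref_start, segments$ref_end - 1L)
}

## running coverage from [start, end) intervals over 1..len (0-based input)
interval_coverage <- function(start, end, len) {
  d <- numeric(len + 1L)
  s <- pmax(start, 0L)
  e <- pmin(end, len)
  ok <- s < e
  if (any(ok)) {
    add <- tabulate(s[ok] + 1L, nbins = len + 1L)
    sub <- tabulate(e[ok] + 1L, nbins = len + 1L)
    d <- add - sub
  }
  cumsum(d)[seq_len(len)]
}

## modal-base count of every string in x (vector)
modal_base_count <- function(x) {
  vapply(strsplit(x, ""), function(ch) if (length(ch)) max(table(ch)) else 0L,
         integer(1))
}

is_homopolymer <- function(x) {
  nchar(x) >= 1L & vapply(strsplit(x, ""), function(ch) length(unique(ch)) == 1L,
                          logical(1))
}
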