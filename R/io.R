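#' Write sequences to FASTA
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write raw reads to FASTQ (Phred+33)
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  stopifnot(length(x) %% 4 == 0)
  data.frame(id = sub("^@", "", x[seq(1, length(x), 4)]),
             seq = x[seq(2, length(x), 4)],
             qual = x[seq(4, length(x), 4)])
}

#' Write alignment records to SAM
#'
#' Converts the package's 0-based alignment records to 1-based SAM.  The
#' optional tags `AS` (best score), `XS` (second-best score), `NM` (edit
#' distance) and `RX` (UMI) are emitted where the columns are populated.
#'
#' @param segments alignment data frame (see [simulate_crac_reads()]).
#' @param ref_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(segments, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  n <- nrow(segments)
  flag <- ifelse(segments$strand == "-", 16L, 0L)
  seq <- if ("seq" %in% names(segments)) segments$seq else strrep("N", segments$read_length)
  lines <- paste(segments$read_id, flag, segments$reference_id,
                 segments$ref_start + 1L, segments$mapq, segments$cigar,
                 "*", 0L, 0L, seq, strrep("I", nchar(seq)), sep = "\t")
  add_tag <- function(lines, val, tag, type = "i") {
    has <- !is.na(val)
    lines[has] <- paste0(lines[has], sprintf("\t%s:%s:%s", tag, type, val[has]))
    lines
  }
  lines <- add_tag(lines, segments$score_best, "AS")
  lines <- add_tag(lines, segments$score_second, "XS")
  lines <- add_tag(lines, segments$edit_distance, "NM")
  if ("umi" %in% names(segments))
    lines <- add_tag(lines, segments$umi, "RX", "Z")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into an alignment data frame
#'
#' Uses Rsamtools to parse the records; coordinates are converted to the
#' package's 0-based, half-open convention and the 3' soft-clipped sequence
#' is reconstructed from the CIGAR and read sequence.
#'
#' @param path SAM file.
#' @return alignment data frame with one row per mapped record.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"),
                               tag = c("AS", "XS", "NM", "RX"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  tagv <- function(tg, default = NA_integer_) {
    v <- x$tag[[tg]]
    if (is.null(v)) rep(default, n) else v
  }
  cigar <- as.character(x$cigar)
  seq <- as.character(x$seq)
  strand <- ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+")
  ref_start <- x$pos - 1L
  ref_end <- ref_start + cigar_ref_width(cigar)
  clip3 <- vapply(seq_len(n), function(i) {
    p <- parse_cigar(cigar[i])
    k <- length(p$op)
    has <- if (strand[i] == "-") p$op[1] == "S" else p$op[k] == "S"
    if (!has) return("")
    cl <- if (strand[i] == "-") p$len[1] else p$len[k]
    if (strand[i] == "-") revcomp(substr(seq[i], 1L, cl))
    else substr(seq[i], nchar(seq[i]) - cl + 1L, nchar(seq[i]))
  }, character(1))
  data.frame(read_id = x$qname, umi = as.character(tagv("RX", NA_character_)),
             reference_id = as.character(x$rname), strand = strand,
             ref_start = ref_start, ref_end = ref_end, cigar = cigar,
             mapq = x$mapq, score_best = tagv("AS"), score_second = tagv("XS"),
             edit_distance = tagv("NM"), clipped3_seq = clip3,
             read_length = cigar_read_width(cigar), seq = seq)
}

#' Write transcript annotation as BED6
#'
#' One row per transcript region (`utr5`, `cds`, `utr3`); the name field is
#' `gene_id:region` so that transcript models round-trip through
#' [read_annotation()] and [models_from_annotation()].
#'
#' @param annotation annotation data frame from [build_transcriptome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(
    data.frame(annotation$transcript_id, annotation$start, annotation$end,
               paste0(annotation$gene_id, ":", annotation$region), 0L, "+"),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 transcript annotation written by [write_annotation()]
#' @param path BED file.
#' @return annotation data frame.
#' @export
read_annotation <- function(path) {
  x <- utils::read.table(path, sep = "\t",
                         col.names = c("transcript_id", "start", "end",
                                       "name", "score", "strand"))
  data.frame(transcript_id = x$transcript_id,
             gene_id = sub(":[^:]+$", "", x$name),
             region = sub("^.*:", "", x$name),
             start = x$start, end = x$end)
}

#' Rebuild transcript models from an annotation table
#'
#' @param annotation annotation data frame (from [read_annotation()]).
#' @param sequences optional named character vector of transcript sequences.
#' @return transcript model data frame (see [build_transcriptome()]).
#' @export
models_from_annotation <- function(annotation, sequences = NULL) {
  sp <- split(annotation, annotation$transcript_id)
  rows <- lapply(sp, function(a) {
    reg <- function(r) a[a$region == r, , drop = FALSE]
    u5 <- reg("utr5"); cds <- reg("cds"); u3 <- reg("utr3")
    data.frame(transcript_id = a$transcript_id[1], gene_id = a$gene_id[1],
               utr5_len = if (nrow(u5)) u5$end - u5$start else 0L,
               cds_len = cds$end - cds$start,
               utr3_len = if (nrow(u3)) u3$end - u3$start else 0L,
               cds_start = cds$start, cds_end = cds$end,
               tx_len = max(a$end))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  m <- m[order(m$transcript_id), , drop = FALSE]
  if (!is.null(sequences)) m$sequence <- unname(sequences[m$transcript_id])
  m
}
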