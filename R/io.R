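# Standard-format readers/writers (FASTA/FASTQ via Biostrings, alignment
# TSV and a minimal SAM dialect, CSV cross/qPCR tables) and small helpers.

#' Read a FASTA file into a reference set
#'
#' @param path FASTA file (multi-line records accepted).
#' @param role role assigned to every entry (`"TE"` or `"miRNA"`), or a
#'   vector per entry.
#' @return a [reference_set()].
#' @export
read_fasta <- function(path, role = "TE") {
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e)
                  stop("FASTA parse error in ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  reference_set(names(x), as.character(x), rep(role, length.out = length(x)))
}

#' Write sequences to FASTA
#'
#' @param x a [reference_set()] or named character vector.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(x, path, width = 60) {
  seqs <- if (is.data.frame(x))
    stats::setNames(x$sequence, x$name) else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Tolerates `+` separator lines with or without a repeated identifier.
#' A record whose quality string length differs from its sequence length
#' is a parse error.
#'
#' @param path FASTQ file.
#' @return a `read_set` data frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  out <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- S4Vectors::mcols(x)$qualities
    if (!is.null(quals) && any(nchar(as.character(quals)) !=
                                 Biostrings::width(x)))
      stop("sequence and quality lengths differ")
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as.character(x), stringsAsFactors = FALSE)
  }, error = function(e)
    stop("FASTQ parse error in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write reads to FASTQ
#'
#' Qualities are constant (`I`); the pipeline ignores qualities throughout.
#'
#' @param reads `read_set` data frame or named character vector.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  df <- as_read_df(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(df$sequence, df$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(df$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write / read alignment tables as TSV
#'
#' Columns: `read_id`, `family`, `strand`, `start`, `end`, `mismatches`,
#' `read_length` (plus `library` when present). Coordinates are 0-based,
#' half-open.
#'
#' @param alignments alignment data frame.
#' @param path file path.
#' @return `read_alignments_tsv` returns the alignment data frame.
#' @export
write_alignments_tsv <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write alignments as minimal SAM
#'
#' FLAG 0/16, 1-based POS, CIGAR `<L>M`, `NM:i:` mismatch tag; `@SQ`
#' headers from the reference set. Sequences are emitted when `reads` is
#' supplied (minus-strand records are reverse-complemented, per the SAM
#' standard), `*` otherwise.
#'
#' @param alignments alignment data frame.
#' @param refs the [reference_set()] mapped against (TE entries).
#' @param path output file.
#' @param reads optional read sequences (`read_set` or named vector).
#' @export
write_sam <- function(alignments, refs, path, reads = NULL) {
  te <- refs[refs$role == "TE", , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", te$name, nchar(te$sequence)))
  seqs <- rep("*", nrow(alignments))
  if (!is.null(reads)) {
    df <- as_read_df(reads)
    seqs <- df$sequence[match(alignments$read_id, df$read_id)]
    minus <- alignments$strand == "-"
    seqs[minus] <- revcomp(seqs[minus])
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                 alignments$read_id,
                 ifelse(alignments$strand == "-", 16L, 0L),
                 alignments$family,
                 alignments$start + 1L,
                 alignments$read_length,
                 seqs,
                 alignments$mismatches)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write the simulation truth sidecar
#'
#' TSV with `read_id`, `family`, `strand`, `start`, `class`, `partner_id`.
#'
#' @param reads a simulated `read_set`.
#' @param path output file.
#' @export
write_truth_tsv <- function(reads, path) {
  utils::write.table(
    data.frame(read_id = reads$read_id, family = reads$true_family,
               strand = reads$true_strand, start = reads$true_start,
               class = reads$class, partner_id = reads$partner_id,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read cross count and qPCR tables as CSV
#'
#' @param x data frame (cross count table or long qPCR Ct table).
#' @param path file path.
#' @return the readers return the data frame.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
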