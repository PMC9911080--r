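# Read processing: 3' adapter trimming, length filtering, ungapped
# mismatch-tolerant mapping to TE references at tiered stringency, and
# miRNA subtraction. The mapping model is deliberately gap-free: the
# original pipelines that this mirrors discard indel alignments, so a
# Hamming-distance scan over every placement is the effective search space.

as_read_df <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    reads
  } else {
    data.frame(read_id = if (is.null(names(reads)))
                 sprintf("r%06d", seq_along(reads)) else names(reads),
               sequence = as.character(reads), stringsAsFactors = FALSE)
  }
}

#' Trim 3' adapters
#'
#' For each read, finds the longest read suffix of length `L`
#' (`min_overlap <= L <= nchar(adapter)`) that matches the length-`L`
#' adapter prefix with at most `floor(max_error_rate * L)` mismatches, and
#' returns the read prefix preceding it. Reads with no qualifying occurrence
#' are returned unchanged.
#'
#' @param reads character vector of read sequences, or a `read_set` data
#'   frame with a `sequence` column.
#' @param adapter non-empty adapter sequence.
#' @param min_overlap minimum adapter prefix length considered (>= 1).
#' @param max_error_rate allowed mismatch proportion per matched length.
#' @return the input with trimmed sequences (same type as `reads`).
#' @examples
#' trim_adapter("ACGTACGTTGGAATTC", "TGGAATTCTCGG")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3,
                         max_error_rate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  stopifnot(min_overlap >= 1)
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  keep <- .trim_core(seqs, adapter, as.integer(min_overlap), max_error_rate)
  trimmed <- substr(seqs, 1L, keep)
  if (is.data.frame(reads)) {
    reads$sequence <- trimmed
    reads
  } else {
    stats::setNames(trimmed, names(reads))
  }
}

#' Filter reads by minimum length
#'
#' @param reads character vector or `read_set` data frame.
#' @param min_len minimum length kept (reads shorter than `min_len` are
#'   discarded; order preserved).
#' @return the surviving reads, same type as the input.
#' @export
filter_by_length <- function(reads, min_len = 5) {
  stopifnot(min_len >= 0)
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  keep <- nchar(seqs) >= min_len
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Map reads to TE references (ungapped, best hit)
#'
#' Considers every ungapped placement of each read (plus strand) and of its
#' reverse complement (minus strand) at every offset of every TE reference.
#' Among placements with Hamming distance `<= max_mismatches` the
#' minimum-distance one is reported; ties are broken deterministically by
#' (family name lexicographic, `+` before `-`, smallest start). A read `N`
#' never matches (it counts as a mismatch at any position). Reads with no
#' qualifying placement are unreported; reads longer than every reference
#' are tallied in the `n_too_long` attribute.
#'
#' Coordinates are 0-based, half-open `[start, end)`. Minus-strand records
#' store the leftmost reference coordinate in `start`; the 5' end of a
#' minus-strand read is at `end - 1`.
#'
#' @param reads character vector or `read_set` data frame.
#' @param refs a [reference_set()]; entries with role `"TE"` are used.
#' @param max_mismatches maximum Hamming distance (tiers 3 and 6 in the
#'   standard workflow).
#' @return data frame of alignment records (`read_id`, `family`, `strand`,
#'   `start`, `end`, `mismatches`, `read_length`), at most one per read,
#'   with attribute `n_too_long`.
#' @export
align_reads <- function(reads, refs, max_mismatches = 3) {
  stopifnot(max_mismatches >= 0)
  te <- refs[refs$role == "TE", , drop = FALSE]
  if (nrow(te) == 0) stop("reference set has no TE entries")
  te <- te[order(te$name, method = "radix"), , drop = FALSE]
  df <- as_read_df(reads)
  if (nrow(df) == 0) {
    out <- empty_alignments()
    attr(out, "n_too_long") <- 0L
    return(out)
  }
  # identical sequences share one scan
  uniq <- unique(df$sequence)
  hit <- .align_core(uniq, te$sequence, as.integer(max_mismatches))
  idx <- match(df$sequence, uniq)
  ref_i <- hit$ref[idx]
  mapped <- !is.na(ref_i)
  w <- nchar(df$sequence)
  out <- data.frame(
    read_id = df$read_id[mapped],
    family = te$name[ref_i[mapped]],
    strand = c("+", "-")[hit$strand[idx][mapped] + 1L],
    start = hit$start[idx][mapped],
    end = hit$start[idx][mapped] + w[mapped],
    mismatches = hit$mismatches[idx][mapped],
    read_length = w[mapped],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_too_long") <- sum(hit$too_long[idx])
  out
}

#' Remove miRNA-matching reads
#'
#' Drops every read that has any ungapped placement (either strand) on any
#' miRNA reference with Hamming distance `<= max_mismatches`; the
#' complement is returned.
#'
#' @param reads character vector or `read_set` data frame.
#' @param mirna_refs a [reference_set()]; entries with role `"miRNA"` are
#'   used.
#' @param max_mismatches mismatch threshold for a read to count as
#'   miRNA-derived (default 1).
#' @return the reads that did not match any miRNA, same type as the input.
#' @export
filter_mirna <- function(reads, mirna_refs, max_mismatches = 1) {
  mir <- mirna_refs[mirna_refs$role == "miRNA", , drop = FALSE]
  if (nrow(mir) == 0) return(reads)
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) == 0) return(reads)
  uniq <- unique(seqs)
  hit <- .align_core(uniq, mir$sequence, as.integer(max_mismatches))
  matched <- !is.na(hit$ref)[match(seqs, uniq)]
  if (is.data.frame(reads)) reads[!matched, , drop = FALSE] else
    reads[!matched]
}
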