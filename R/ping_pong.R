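# Ping-pong signature: sense/antisense 5'-overlap histograms, a z-score for
# the 10-nt overlap, and 1U/10A nucleotide-bias fractions. The 5'-end
# convention follows the alignment module: plus-strand 5' = start,
# minus-strand 5' = end - 1 (0-based).

#' Sense/antisense 5'-overlap histogram for one family
#'
#' For each plus-strand alignment with 5' end `s` and each minus-strand
#' alignment with 5' end `e`, the overlap is `o = e - s + 1`. Every pair
#' with `1 <= o <= o_max` contributes weight 1 under `"read-pairs"`
#' weighting (reads counted with multiplicity) or weight 1 per distinct
#' `(s, e)` position pair under `"position-pairs"` weighting.
#'
#' @param alignments alignment data frame for a single family (piRNA-length
#'   pre-filtering is the caller's responsibility).
#' @param o_max largest overlap tabulated (default 20).
#' @param weighting `"read-pairs"` or `"position-pairs"`.
#' @return an `overlap_histogram`: data frame with columns `o` (1..o_max)
#'   and `weight`, with attributes `family` and `weighting`.
#' @export
overlap_histogram <- function(alignments, o_max = 20,
                              weighting = c("read-pairs", "position-pairs")) {
  weighting <- match.arg(weighting)
  stopifnot(o_max >= 1)
  fam <- unique(alignments$family)
  if (length(fam) > 1)
    stop("overlap_histogram expects alignments from a single family")
  s <- alignments$start[alignments$strand == "+"]
  e <- alignments$end[alignments$strand == "-"] - 1L
  w <- numeric(o_max)
  if (length(s) && length(e)) {
    off <- min(s, e)
    npos <- max(s, e) - off + 1L
    a <- tabulate(s - off + 1L, nbins = npos)
    b <- tabulate(e - off + 1L, nbins = npos)
    if (weighting == "position-pairs") {
      a <- as.numeric(a > 0)
      b <- as.numeric(b > 0)
    }
    for (o in seq_len(o_max)) {
      # pairs with e = s + o - 1: cross-correlation at lag o - 1
      if (o <= npos)
        w[o] <- sum(a[seq_len(npos - o + 1L)] * b[o:npos])
    }
  }
  out <- data.frame(o = seq_len(o_max), weight = w)
  attr(out, "family") <- if (length(fam)) fam else NA_character_
  attr(out, "weighting") <- weighting
  class(out) <- c("overlap_histogram", "data.frame")
  out
}

#' Ping-pong z-score
#'
#' `z = (c_focal - mean(B)) / sd(B)` where `B` is the set of bin weights at
#' overlaps other than the focal one and `sd` is the sample standard
#' deviation. Returns `NA` (the undefined flag) when `sd(B) = 0`.
#'
#' @param hist an [overlap_histogram()] (or a data frame with columns `o`,
#'   `weight`).
#' @param focal the focal overlap (default 10, the ping-pong signature).
#' @return a single numeric z-score, or `NA` when the background is
#'   degenerate.
#' @export
pingpong_zscore <- function(hist, focal = 10) {
  stopifnot(max(hist$o) >= focal, max(hist$o) >= 3)
  cf <- hist$weight[hist$o == focal]
  bg <- hist$weight[hist$o != focal]
  s <- sd(bg)
  if (is.na(s) || s == 0) return(NA_real_)
  (cf - mean(bg)) / s
}

#' 1U / 10A nucleotide-bias fractions
#'
#' `u1` is the fraction of antisense-aligned reads whose first sequenced
#' base is `T` (U in RNA); `a10` is the fraction of sense-aligned reads with
#' `A` at sequenced position 10. Both are computed from the read sequences
#' (mismatches included), since the biogenesis biases act on the piRNA
#' molecule rather than the reference. Reads shorter than 10 nt are
#' excluded. A zero denominator yields `NA` for that fraction.
#'
#' @param alignments alignment data frame for one family.
#' @param reads `read_set` data frame (or named character vector) supplying
#'   the sequences by `read_id`.
#' @return list with `u1_fraction`, `a10_fraction`, `n_antisense`,
#'   `n_sense`.
#' @export
nucleotide_bias <- function(alignments, reads) {
  df <- as_read_df(reads)
  seqs <- df$sequence[match(alignments$read_id, df$read_id)]
  if (anyNA(seqs)) stop("alignments reference read_ids absent from reads")
  ok <- nchar(seqs) >= 10
  anti <- ok & alignments$strand == "-"
  sens <- ok & alignments$strand == "+"
  list(
    u1_fraction = if (any(anti))
      mean(substr(seqs[anti], 1, 1) == "T") else NA_real_,
    a10_fraction = if (any(sens))
      mean(substr(seqs[sens], 10, 10) == "A") else NA_real_,
    n_antisense = sum(anti),
    n_sense = sum(sens))
}

#' Per-family, per-library ping-pong report
#'
#' Computes the overlap histogram, the focal z-score, the total pair weight
#' and (when read sequences are supplied) the 1U/10A fractions for every
#' (library, family) combination, after restricting alignments to the piRNA
#' length window.
#'
#' @param alignments alignment data frame; a `library` column groups
#'   libraries (a single implicit library is assumed if absent).
#' @param reads optional read sequences for the bias fractions.
#' @param min_len,max_len piRNA length window applied to `read_length`.
#' @param o_max largest overlap tabulated.
#' @param weighting histogram weighting (see [overlap_histogram()]).
#' @param focal focal overlap for the z-score.
#' @param min_pairs reporting floor: rows with `n_pairs` below this are
#'   flagged `low_coverage`.
#' @return data frame `library`, `family`, `n_pairs`, `z10`, `u1_fraction`,
#'   `a10_fraction`, `low_coverage`, ordered by library then family.
#' @export
pingpong_report <- function(alignments, reads = NULL, min_len = 23,
                            max_len = 31, o_max = 20,
                            weighting = c("read-pairs", "position-pairs"),
                            focal = 10, min_pairs = 10) {
  weighting <- match.arg(weighting)
  aln <- alignments
  if (nrow(aln) == 0)
    return(data.frame(library = character(0), family = character(0),
                      n_pairs = numeric(0), z10 = numeric(0),
                      u1_fraction = numeric(0), a10_fraction = numeric(0),
                      low_coverage = logical(0), stringsAsFactors = FALSE))
  if (is.null(aln$library)) aln$library <- "lib1"
  aln <- aln[aln$read_length >= min_len & aln$read_length <= max_len, ,
             drop = FALSE]
  groups <- unique(aln[, c("library", "family")])
  groups <- groups[order(groups$library, groups$family, method = "radix"), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- aln[aln$library == groups$library[i] &
               aln$family == groups$family[i], , drop = FALSE]
    h <- overlap_histogram(g, o_max = o_max, weighting = weighting)
    bias <- if (!is.null(reads)) nucleotide_bias(g, reads) else
      list(u1_fraction = NA_real_, a10_fraction = NA_real_)
    data.frame(library = groups$library[i], family = groups$family[i],
               n_pairs = sum(h$weight),
               z10 = pingpong_zscore(h, focal = focal),
               u1_fraction = bias$u1_fraction,
               a10_fraction = bias$a10_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$low_coverage <- out$n_pairs < min_pairs
  rownames(out) <- NULL
  out
}
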