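# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: the aligner oracle is a plain R double loop,
# the trimming oracle enumerates suffix alignments, and the Fisher oracle
# enumerates tables with explicit binomial coefficients.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# brute-force best ungapped placement: scan every offset of every reference
# on both strands, count Hamming mismatches (read N never matches), keep the
# first minimum in (family lexicographic, + before -, start ascending) order.
oracle_align <- function(read, refs, max_mm) {
  best <- NULL
  rc <- oracle_revcomp(read)
  for (fam in sort(names(refs), method = "radix")) {
    ref <- strsplit(refs[[fam]], "")[[1]]
    L <- length(ref)
    for (strand in c("+", "-")) {
      rd <- strsplit(if (strand == "+") read else rc, "")[[1]]
      w <- length(rd)
      if (w == 0 || w > L) next
      for (s in 0:(L - w)) {
        mm <- sum(rd != ref[(s + 1):(s + w)] | rd == "N")
        if (mm <= max_mm && (is.null(best) || mm < best$mm))
          best <- list(family = fam, strand = strand, start = s, mm = mm)
      }
    }
  }
  best
}

# brute-force adapter trim: enumerate every suffix length L, qualify it
# against the adapter prefix, return the longest qualifying cut point.
oracle_trim <- function(read, adapter, min_overlap = 3, rate = 0.1) {
  nr <- nchar(read)
  na <- nchar(adapter)
  for (L in rev(seq_len(min(nr, na)))) {
    if (L < min_overlap) break
    p <- nr - L
    mm <- sum(strsplit(substr(read, p + 1, nr), "")[[1]] !=
                strsplit(substr(adapter, 1, L), "")[[1]])
    if (mm <= floor(rate * L)) return(substr(read, 1, p))
  }
  read
}

# exhaustive hypergeometric enumeration with explicit binomial coefficients
# (probability-ordering two-sided rule).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; s <- a + c
  if (m + n == 0) return(1)
  k <- max(0, s - n):min(s, m)
  prob <- choose(m, k) * choose(n, s - k) / choose(m + n, s)
  pobs <- choose(m, a) * choose(n, s - a) / choose(m + n, s)
  min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
}

# random (read, reference) aligner test instance: half the reads are planted
# reference substrings with a chosen number of substitutions (either
# strand), half are unrelated random sequences.
make_align_instance <- function(ref_len = NULL, planted = NULL) {
  if (is.null(ref_len)) ref_len <- sample(200:2000, 1)
  refs <- c(A = rand_dna(ref_len), B = rand_dna(sample(200:1000, 1)))
  w <- sample(15:31, 1)
  if (is.null(planted)) planted <- runif(1) < 0.5
  if (planted) {
    fam <- sample(names(refs), 1)
    s <- sample.int(nchar(refs[[fam]]) - w + 1, 1)
    read <- substr(refs[[fam]], s, s + w - 1)
    nmut <- sample(0:7, 1)
    if (nmut > 0) {
      ch <- strsplit(read, "")[[1]]
      pos <- sample.int(w, min(nmut, w))
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      read <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) read <- oracle_revcomp(read)
  } else {
    read <- rand_dna(w)
  }
  list(read = read, refs = refs)
}

as_refset <- function(refs, role = "TE") {
  reference_set(names(refs), unname(refs), rep(role, length(refs)))
}
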