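# Synthetic data generators: reference sets, small-RNA libraries with known
# ping-pong structure, dysgenesis cross count tables and qPCR Ct tables.
# Every generator is deterministic for a fixed seed and records full ground
# truth so that downstream recovery can be tested.

#' Construct a reference set
#'
#' A reference set holds named nucleotide sequences playing the role of
#' transposable-element (TE) consensus families and miRNA sequences.
#'
#' @param name character vector of unique identifiers.
#' @param sequence character vector of upper-case DNA (`A/C/G/T`).
#' @param role one of `"TE"` or `"miRNA"` per entry.
#' @return a `reference_set` data frame with columns `name`, `sequence`,
#'   `role`.
#' @export
reference_set <- function(name, sequence, role) {
  stopifnot(length(name) == length(sequence), length(name) == length(role))
  if (anyDuplicated(name)) stop("reference names must be unique")
  if (any(!nzchar(sequence))) stop("reference sequences must be non-empty")
  if (!all(role %in% c("TE", "miRNA"))) stop("role must be 'TE' or 'miRNA'")
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) stop("reference sequences must be over {A,C,G,T}")
  te_short <- role == "TE" & nchar(sequence) < 100
  if (any(te_short)) stop("TE sequences must be at least 100 nt")
  mir_len <- nchar(sequence[role == "miRNA"])
  if (length(mir_len) && any(mir_len < 18 | mir_len > 30))
    stop("miRNA sequences must be 18-30 nt")
  out <- data.frame(name = as.character(name),
                    sequence = as.character(sequence),
                    role = as.character(role), stringsAsFactors = FALSE)
  class(out) <- c("reference_set", "data.frame")
  out
}

random_dna <- function(n, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate random TE and miRNA reference sequences
#'
#' Draws `n_te` TE consensus sequences and `n_mirna` miRNA sequences of
#' uniform random composition. miRNA sequences are rejected (and redrawn)
#' if they occur as a substring of any TE sequence on either strand, so a
#' read can never be simultaneously TE-derived and miRNA-identical.
#'
#' @param n_te number of TE families (>= 1).
#' @param te_length length range `c(lo, hi)` for TE sequences (lo >= 100).
#' @param n_mirna number of miRNA entries.
#' @param mirna_length length range for miRNAs (within 18-30).
#' @param seed integer seed; fixed seed gives identical output.
#' @return a [reference_set()].
#' @examples
#' refs <- generate_references(3, c(500, 1000), 5, c(21, 23), seed = 1)
#' table(refs$role)
#' @export
generate_references <- function(n_te, te_length = c(500, 2000),
                                n_mirna = 5, mirna_length = c(21, 23),
                                seed = NULL) {
  stopifnot(n_te >= 1, n_mirna >= 0)
  if (length(te_length) != 2 || te_length[1] > te_length[2] ||
      te_length[1] < 100)
    stop("invalid te_length range (need 100 <= lo <= hi)")
  if (length(mirna_length) != 2 || mirna_length[1] > mirna_length[2] ||
      mirna_length[1] < 18 || mirna_length[2] > 30)
    stop("invalid mirna_length range (need 18 <= lo <= hi <= 30)")
  with_seed(seed, {
    te_len <- sample(seq(te_length[1], te_length[2]), n_te, replace = TRUE)
    te_seq <- random_dna(n_te, te_len)
    te_rc <- revcomp(te_seq)
    mir_seq <- character(n_mirna)
    for (i in seq_len(n_mirna)) {
      repeat {
        s <- random_dna(1, sample(seq(mirna_length[1], mirna_length[2]), 1))
        hit <- any(vapply(seq_along(te_seq), function(k)
          grepl(s, te_seq[k], fixed = TRUE) ||
            grepl(s, te_rc[k], fixed = TRUE), logical(1)))
        if (!hit) { mir_seq[i] <- s; break }
      }
    }
    reference_set(
      name = c(sprintf("TE%02d", seq_len(n_te)),
               if (n_mirna) sprintf("mir-%02d", seq_len(n_mirna))),
      sequence = c(te_seq, mir_seq),
      role = c(rep("TE", n_te), rep("miRNA", n_mirna)))
  })
}

#' Configuration for a simulated small-RNA library
#'
#' @param n_reads total number of reads to emit.
#' @param family_weights named non-negative proportions over TE families
#'   (normalized internally); `NULL` = uniform over the TE families in the
#'   reference set.
#' @param pingpong_fraction proportion of piRNA reads emitted as ping-pong
#'   pairs with exact 10-nt 5' overlaps; either a single value or a named
#'   vector per TE family.
#' @param u1_bias probability that an antisense piRNA read has `T` as its
#'   first sequenced base (implemented by biased genomic site selection, so
#'   error-free reads remain exact genome matches). `NA` disables the bias
#'   entirely (placements are purely uniform) — note that any non-`NA`
#'   value, even 0.25, couples sense and antisense site selection at the
#'   10-nt overlap, so `NA` is the correct null for overlap statistics.
#' @param a10_bias probability that a paired sense piRNA read has `A` at
#'   sequenced position 10. For a ping-pong pair the sense 10A site and the
#'   antisense 1U site are the same reference base, so a single probability
#'   governs pair placement: `u1_bias` when set, else `a10_bias`. Unpaired
#'   sense reads carry no positional bias (the 10A signature belongs to
#'   ping-pong responder piRNAs, not to primary piRNAs), which keeps
#'   pair-free families free of spurious 10-nt overlap signal.
#' @param length_dist list of discrete length distributions per class:
#'   each of `siRNA` and `piRNA` is a named numeric vector
#'   (names = lengths, values = probabilities). miRNA reads are emitted as
#'   full miRNA reference sequences, so their length follows the reference
#'   set.
#' @param class_mix proportions of read classes, named
#'   `c(miRNA=, siRNA=, piRNA=)`, summing to 1.
#' @param error_rate per-base substitution probability.
#' @param adapter 3' adapter sequence.
#' @param adapter_fraction proportion of reads carrying the 3' adapter.
#' @param read_budget sequencer read length; insert + adapter is truncated
#'   to this many bases (reads are never padded).
#' @param seed integer seed.
#' @return a `library_config` list.
#' @export
library_config <- function(n_reads,
                           family_weights = NULL,
                           pingpong_fraction = 0.2,
                           u1_bias = 0.8,
                           a10_bias = 0.8,
                           length_dist = NULL,
                           class_mix = c(miRNA = 0.15, siRNA = 0.15,
                                         piRNA = 0.70),
                           error_rate = 0.001,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           adapter_fraction = 0.1,
                           read_budget = 50L,
                           seed = NULL) {
  stopifnot(n_reads >= 1)
  props <- c(pingpong_fraction, u1_bias, a10_bias, error_rate,
             adapter_fraction, class_mix)
  if (any(props < 0 | props > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (is.null(length_dist)) length_dist <- list()
  if (is.null(length_dist$siRNA))
    length_dist$siRNA <- c("20" = 0.15, "21" = 0.70, "22" = 0.15)
  if (is.null(length_dist$piRNA)) {
    w <- exp(-((23:31) - 26)^2 / 8)      # unimodal, peak at 26 nt
    length_dist$piRNA <- stats::setNames(w / sum(w), 23:31)
  }
  for (cls in c("siRNA", "piRNA")) {
    d <- length_dist[[cls]]
    if (is.null(names(d)) || any(d < 0) || sum(d) <= 0)
      stop("length_dist$", cls, " must be a named non-negative vector")
    length_dist[[cls]] <- d / sum(d)
  }
  if (!is.null(family_weights)) {
    if (any(family_weights < 0)) stop("family_weights must be non-negative")
    if (sum(family_weights) <= 0) stop("family_weights must not be all zero")
    family_weights <- family_weights / sum(family_weights)
  }
  structure(list(n_reads = as.integer(n_reads),
                 family_weights = family_weights,
                 pingpong_fraction = pingpong_fraction,
                 u1_bias = u1_bias, a10_bias = a10_bias,
                 length_dist = length_dist,
                 class_mix = class_mix[c("miRNA", "siRNA", "piRNA")],
                 error_rate = error_rate, adapter = adapter,
                 adapter_fraction = adapter_fraction,
                 read_budget = as.integer(read_budget), seed = seed),
            class = "library_config")
}

# sample positions with a biased base at a target offset: with probability
# `bias` the reference base at (start + offset) equals `base`, otherwise it
# does not. Vectorized rejection sampling with a bounded number of rounds;
# leftover draws are accepted as-is (only matters for extreme compositions).
sample_biased_start <- function(chars, lo, hi, offset, base, bias) {
  m <- length(lo)
  s <- lo + floor(runif(m) * (hi - lo + 1))
  if (is.na(bias)) return(s)
  want <- runif(m) < bias
  for (round in 1:40) {
    ok <- (chars[s + offset + 1L] == base) == want
    if (all(ok)) break
    redo <- which(!ok)
    s[redo] <- lo[redo] + floor(runif(length(redo)) * (hi[redo] - lo[redo] + 1))
  }
  s
}

#' Simulate an ovarian small-RNA library
#'
#' Emits `n_reads` reads across three classes (miRNA, siRNA, piRNA) with the
#' configured mixture. piRNA reads are drawn from TE positions on either
#' strand; a fraction `pingpong_fraction` of them is emitted as sense /
#' antisense pairs whose 5' ends overlap by exactly 10 nt, with 1U/10A
#' nucleotide biases applied through biased site selection. A 3' adapter is
#' appended to `adapter_fraction` of reads before per-base substitution
#' errors are injected, and reads are truncated at `read_budget` bases.
#' Ground truth (family, strand, 0-based start, class, ping-pong partner)
#' is recorded per read.
#'
#' @param refs a [reference_set()] with at least one TE entry (and miRNA
#'   entries if `class_mix["miRNA"] > 0`).
#' @param config a [library_config()].
#' @return a `read_set` data frame with columns `read_id`, `sequence`, and
#'   truth columns `class`, `true_family`, `true_strand`, `true_start`,
#'   `partner_id`, `has_adapter`, `n_errors`.
#' @export
simulate_small_rna_library <- function(refs, config) {
  stopifnot(inherits(config, "library_config"))
  te <- refs[refs$role == "TE", , drop = FALSE]
  mir <- refs[refs$role == "miRNA", , drop = FALSE]
  if (nrow(te) == 0) stop("reference set has no TE entries")
  fw <- config$family_weights
  if (is.null(fw)) fw <- stats::setNames(rep(1 / nrow(te), nrow(te)), te$name)
  if (!all(names(fw) %in% te$name))
    stop("family_weights names unknown TE families: ",
         paste(setdiff(names(fw), te$name), collapse = ", "))
  fpp <- config$pingpong_fraction
  if (!is.null(names(fpp)) && !all(names(fpp) %in% te$name))
    stop("pingpong_fraction names unknown TE families")
  te_chars <- lapply(te$sequence, function(s) strsplit(s, "")[[1]])
  names(te_chars) <- te$name
  te_len <- stats::setNames(nchar(te$sequence), te$name)

  draw_len <- function(cls, m) {
    d <- config$length_dist[[cls]]
    as.integer(sample(names(d), m, replace = TRUE, prob = d))
  }

  with_seed(config$seed, {
    n_class <- round_counts(config$n_reads, config$class_mix)
    rows <- list()

    ## miRNA class: full reference sequences
    if (n_class[["miRNA"]] > 0) {
      if (nrow(mir) == 0) stop("class_mix requests miRNA reads but the ",
                               "reference set has no miRNA entries")
      pick <- sample.int(nrow(mir), n_class[["miRNA"]], replace = TRUE)
      rows$mir <- data.frame(sequence = mir$sequence[pick], class = "miRNA",
                             true_family = mir$name[pick], true_strand = "+",
                             true_start = 0L, pair = NA_integer_,
                             stringsAsFactors = FALSE)
    }

    ## siRNA class: unbiased TE fragments
    if (n_class[["siRNA"]] > 0) {
      m <- n_class[["siRNA"]]
      fam <- sample(names(fw), m, replace = TRUE, prob = fw)
      w <- draw_len("siRNA", m)
      L <- te_len[fam]
      if (any(w > L)) stop("siRNA length exceeds a TE reference length")
      s <- floor(runif(m) * (L - w + 1))
      strand <- sample(c("+", "-"), m, replace = TRUE)
      seqs <- substring(te$sequence[match(fam, te$name)], s + 1, s + w)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      rows$sir <- data.frame(sequence = seqs, class = "siRNA",
                             true_family = fam, true_strand = strand,
                             true_start = as.integer(s), pair = NA_integer_,
                             stringsAsFactors = FALSE)
    }

    ## piRNA class: per family, ping-pong pairs + unpaired reads
    if (n_class[["piRNA"]] > 0) {
      fam_counts <- round_counts(n_class[["piRNA"]], fw)
      pair_counter <- 0L
      pi_rows <- list()
      for (fam in names(fam_counts)) {
        nf <- fam_counts[[fam]]
        if (nf == 0) next
        f <- if (is.null(names(fpp))) fpp else
          if (fam %in% names(fpp)) fpp[[fam]] else 0
        n_pairs <- floor(round(nf * f) / 2)
        n_unpaired <- nf - 2L * n_pairs
        ref <- te$sequence[te$name == fam]
        chars <- te_chars[[fam]]
        L <- te_len[[fam]]

        if (n_pairs > 0) {
          w_s <- draw_len("piRNA", n_pairs)
          w_a <- draw_len("piRNA", n_pairs)
          lo <- pmax(0L, w_a - 10L)
          hi <- L - w_s
          if (any(hi < lo)) stop("TE reference too short for ping-pong pairs")
          # pair anchored at sense start s, antisense 5' end at s + 9;
          # the shared 1U/10A bias site is the reference base at s + 9.
          p_pair <- if (!is.na(config$u1_bias)) config$u1_bias else
            config$a10_bias
          s <- sample_biased_start(chars, lo, hi, 9L, "A", p_pair)
          e <- s + 9L
          a_start <- e - w_a + 1L
          sense_seq <- substring(ref, s + 1, s + w_s)
          anti_seq <- revcomp(substring(ref, a_start + 1, e + 1))
          pid <- pair_counter + seq_len(n_pairs)
          pair_counter <- pair_counter + n_pairs
          pi_rows[[paste0(fam, ".p")]] <- data.frame(
            sequence = c(sense_seq, anti_seq), class = "piRNA",
            true_family = fam,
            true_strand = rep(c("+", "-"), each = n_pairs),
            true_start = as.integer(c(s, a_start)),
            pair = c(pid, pid), stringsAsFactors = FALSE)
        }

        if (n_unpaired > 0) {
          w <- draw_len("piRNA", n_unpaired)
          strand <- sample(c("+", "-"), n_unpaired, replace = TRUE)
          s <- integer(n_unpaired)
          ip <- strand == "+"
          if (any(ip)) {
            # unpaired sense reads: uniform placement, no positional bias
            wp <- w[ip]
            s[ip] <- floor(runif(sum(ip)) * (L - wp + 1))
          }
          if (any(!ip)) {
            # antisense: first sequenced base is the complement of the
            # reference base at the 5' end e = start + w - 1; it reads T
            # when the reference base is A.
            wm <- w[!ip]
            e <- sample_biased_start(chars, wm - 1L, rep(L - 1L, sum(!ip)),
                                     0L, "A", config$u1_bias)
            s[!ip] <- e - wm + 1L
          }
          seqs <- substring(ref, s + 1, s + w)
          seqs[!ip] <- revcomp(seqs[!ip])
          pi_rows[[paste0(fam, ".u")]] <- data.frame(
            sequence = seqs, class = "piRNA", true_family = fam,
            true_strand = strand, true_start = as.integer(s),
            pair = NA_integer_, stringsAsFactors = FALSE)
        }
      }
      rows$pi <- do.call(rbind, pi_rows)
    }

    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    n <- nrow(out)
    out$read_id <- sprintf("r%06d", seq_len(n))
    out$partner_id <- NA_character_
    paired <- !is.na(out$pair)
    if (any(paired)) {
      ids_by_pair <- split(out$read_id[paired], out$pair[paired])
      partner <- lapply(ids_by_pair, rev)
      out$partner_id[paired] <- unsplit(partner, out$pair[paired])
    }
    out$pair <- NULL

    ## adapter contamination, then substitution errors, then truncation
    n_adapt <- round(n * config$adapter_fraction)
    out$has_adapter <- FALSE
    if (n_adapt > 0 && nzchar(config$adapter)) {
      idx <- sample.int(n, n_adapt)
      out$has_adapter[idx] <- TRUE
      out$sequence[idx] <- paste0(out$sequence[idx], config$adapter)
    }
    out$n_errors <- 0L
    if (config$error_rate > 0) {
      ne <- rbinom(n, nchar(out$sequence), config$error_rate)
      for (i in which(ne > 0)) {
        ch <- strsplit(out$sequence[i], "")[[1]]
        pos <- sample.int(length(ch), ne[i])
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        out$sequence[i] <- paste(ch, collapse = "")
        out$n_errors[i] <- ne[i]
      }
    }
    out$sequence <- substr(out$sequence, 1, config$read_budget)

    out <- out[sample.int(n), c("read_id", "sequence", "class", "true_family",
                                "true_strand", "true_start", "partner_id",
                                "has_adapter", "n_errors")]
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Ground-truth alignments of a simulated read set
#'
#' Converts the truth tags of a simulated library into an alignment table in
#' the same layout as [align_reads()] (0 mismatches, truth coordinates).
#' Useful for studying the null and signal behaviour of downstream
#' statistics (overlap histograms, count matrices) free of mapping noise.
#'
#' @param reads a `read_set` from [simulate_small_rna_library()].
#' @param library optional library identifier added as a `library` column.
#' @param classes which truth classes to keep (default piRNA only).
#' @return an alignment data frame.
#' @export
alignments_from_truth <- function(reads, library = NULL, classes = "piRNA") {
  keep <- reads$class %in% classes
  r <- reads[keep, , drop = FALSE]
  len <- nchar(r$sequence)
  out <- data.frame(read_id = r$read_id, family = r$true_family,
                    strand = r$true_strand, start = r$true_start,
                    end = r$true_start + len, mismatches = 0L,
                    read_length = len, stringsAsFactors = FALSE)
  if (!is.null(library)) out$library <- library
  rownames(out) <- NULL
  out
}

#' Design of a hybrid dysgenesis cross experiment
#'
#' @param lines named numeric vector: per-line logit-scale dysgenesis
#'   propensity (logit of the expected dysgenic proportion in the dysgenic
#'   direction).
#' @param tester_sublines named numeric vector of logit offsets for the
#'   inbred tester sublines (default a single subline with offset 0).
#' @param n_f1_per_cross number of F1 females scored per cross (>= 1).
#' @param directions subset of `c("dysgenic", "reciprocal")`.
#' @param reciprocal_logit logit of the dysgenic proportion in the
#'   reciprocal (control) direction, common to all lines.
#' @param temperature rearing temperature in degrees C (recorded per row).
#' @param tester_name name of the P-type tester line.
#' @param seed integer seed.
#' @return a `cross_design` list.
#' @export
cross_design <- function(lines,
                         tester_sublines = c(S1 = 0),
                         n_f1_per_cross = 100L,
                         directions = c("dysgenic", "reciprocal"),
                         reciprocal_logit = qlogis(0.02),
                         temperature = 29,
                         tester_name = "Ptype",
                         seed = NULL) {
  if (is.null(names(lines)) || anyDuplicated(names(lines)))
    stop("lines must be a named vector with unique names")
  stopifnot(n_f1_per_cross >= 1,
            all(directions %in% c("dysgenic", "reciprocal")))
  structure(list(lines = lines, tester_sublines = tester_sublines,
                 n_f1_per_cross = as.integer(n_f1_per_cross),
                 directions = directions,
                 reciprocal_logit = reciprocal_logit,
                 temperature = temperature, tester_name = tester_name,
                 seed = seed),
            class = "cross_design")
}

#' Simulate dysgenesis cross count tables
#'
#' One row per (line x tester subline x direction). In the dysgenic
#' direction (naive mother x P-type father) the number of dysgenic F1
#' females is Binomial(n, plogis(line logit + subline offset)); in the
#' reciprocal direction the success probability is
#' `plogis(reciprocal_logit)` for every cross.
#'
#' @param design a [cross_design()].
#' @return a data frame with columns `maternal_line`, `paternal_line`,
#'   `tester_subline`, `direction`, `temperature`, `n_dysgenic`, `n_normal`.
#' @export
simulate_cross_counts <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  with_seed(design$seed, {
    grid <- expand.grid(line = names(design$lines),
                        subline = names(design$tester_sublines),
                        direction = design$directions,
                        stringsAsFactors = FALSE)
    p <- ifelse(grid$direction == "dysgenic",
                plogis(design$lines[grid$line] +
                         design$tester_sublines[grid$subline]),
                plogis(design$reciprocal_logit))
    n_dys <- rbinom(nrow(grid), design$n_f1_per_cross, p)
    data.frame(
      maternal_line = ifelse(grid$direction == "dysgenic", grid$line,
                             design$tester_name),
      paternal_line = ifelse(grid$direction == "dysgenic", design$tester_name,
                             grid$line),
      line = grid$line,
      tester_subline = grid$subline,
      direction = grid$direction,
      temperature = design$temperature,
      n_dysgenic = n_dys,
      n_normal = design$n_f1_per_cross - n_dys,
      stringsAsFactors = FALSE)
  })
}

#' Design of a qPCR expression / splicing experiment
#'
#' Effects are on the delta-Ct scale (cycles): a positive effect lowers the
#' Ct of the target (more template). The reference gene is unaffected by
#' condition effects.
#'
#' @param lines character vector of line names.
#' @param directions subset of `c("dysgenic", "reciprocal")`.
#' @param temperatures rearing temperatures (degrees C).
#' @param baseline_ct named baseline Ct per target
#'   (`spliced`, `total`, `reference`).
#' @param direction_effect named per-target (spliced, total) Ct decrease in
#'   the dysgenic direction.
#' @param temperature_effect named per-target Ct decrease at the higher
#'   temperature.
#' @param line_effects optional list with elements `spliced` and `total`,
#'   each a named per-line Ct decrease (default all 0).
#' @param replicate_sd replicate Ct standard deviation (> 0 for simulation;
#'   0 allowed for deterministic checks).
#' @param n_replicates replicates per condition cell (>= 2).
#' @param seed integer seed.
#' @return a `qpcr_design` list.
#' @export
qpcr_design <- function(lines,
                        directions = c("dysgenic", "reciprocal"),
                        temperatures = c(25, 29),
                        baseline_ct = c(spliced = 28, total = 26,
                                        reference = 18),
                        direction_effect = c(spliced = 1.5, total = 1.0),
                        temperature_effect = c(spliced = 1.0, total = 0.5),
                        line_effects = NULL,
                        replicate_sd = 0.3,
                        n_replicates = 3L,
                        seed = NULL) {
  stopifnot(n_replicates >= 2, replicate_sd >= 0)
  if (is.null(line_effects))
    line_effects <- list(
      spliced = stats::setNames(rep(0, length(lines)), lines),
      total = stats::setNames(rep(0, length(lines)), lines))
  structure(list(lines = lines, directions = directions,
                 temperatures = temperatures, baseline_ct = baseline_ct,
                 direction_effect = direction_effect,
                 temperature_effect = temperature_effect,
                 line_effects = line_effects, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "qpcr_design")
}

#' Simulate a qPCR Ct table
#'
#' `Ct = baseline - (direction + temperature + line effects) + N(0, sd)` for
#' the `spliced` and `total` targets; the reference gene receives baseline
#' plus noise only.
#'
#' @param design a [qpcr_design()].
#' @return long data frame: `line`, `direction`, `temperature`, `replicate`,
#'   `target`, `ct`.
#' @export
simulate_qpcr <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  with_seed(design$seed, {
    grid <- expand.grid(line = design$lines, direction = design$directions,
                        temperature = design$temperatures,
                        replicate = seq_len(design$n_replicates),
                        target = c("spliced", "total", "reference"),
                        stringsAsFactors = FALSE)
    eff <- numeric(nrow(grid))
    for (tg in c("spliced", "total")) {
      i <- grid$target == tg
      eff[i] <- design$direction_effect[[tg]] *
          (grid$direction[i] == "dysgenic") +
        design$temperature_effect[[tg]] *
          (grid$temperature[i] == max(design$temperatures)) +
        design$line_effects[[tg]][grid$line[i]]
    }
    grid$ct <- design$baseline_ct[grid$target] - eff +
      rnorm(nrow(grid), 0, design$replicate_sd)
    rownames(grid) <- NULL
    grid
  })
}

#' Simulate a per-family count matrix with planted covariate effects
#'
#' Generates TE-family counts directly on the log2-CPM scale:
#' `log2cpm = baseline + effect * covariate + N(0, resid_sd)`, converted to
#' integer counts at the given library size. Used for calibration and power
#' studies of the differential-abundance model without simulating reads.
#'
#' @param n_families number of TE families.
#' @param covariate per-library numeric covariate (its length fixes the
#'   number of libraries).
#' @param effects named or positional log2-units-per-covariate-unit effect
#'   per family (default 0 for all: a global null).
#' @param baseline_logcpm range from which per-family baseline log2-CPM
#'   values are drawn.
#' @param resid_sd residual standard deviation on the log2 scale.
#' @param library_size common library size.
#' @param seed integer seed.
#' @return a [count_matrix()] with metadata column `resistance` holding the
#'   covariate.
#' @export
simulate_count_matrix <- function(n_families = 20,
                                  covariate,
                                  effects = NULL,
                                  baseline_logcpm = c(5, 10),
                                  resid_sd = 0.5,
                                  library_size = 1e6,
                                  seed = NULL) {
  n_lib <- length(covariate)
  if (is.null(effects)) effects <- rep(0, n_families)
  stopifnot(length(effects) == n_families)
  with_seed(seed, {
    fam <- sprintf("TE%02d", seq_len(n_families))
    mu <- runif(n_families, baseline_logcpm[1], baseline_logcpm[2])
    lc <- outer(mu, rep(1, n_lib)) + outer(effects, covariate) +
      matrix(rnorm(n_families * n_lib, 0, resid_sd), n_families, n_lib)
    counts <- matrix(pmax(0L, as.integer(round(2^lc / 1e6 * library_size))),
                     n_families, n_lib,
                     dimnames = list(fam, sprintf("lib%02d", seq_len(n_lib))))
    meta <- data.frame(library = colnames(counts),
                       line = colnames(counts), replicate = 1L,
                       resistance = covariate, stringsAsFactors = FALSE)
    count_matrix(counts,
                 library_sizes = stats::setNames(rep(library_size, n_lib),
                                                 colnames(counts)),
                 meta = meta, length_window = c(0, Inf),
                 class_label = "simulated")
  })
}
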