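test_that("generate_references respects cardinalities, determinism and the
           miRNA/TE exclusion", {
  refs <- generate_references(3, c(500, 1000), 5, c(21, 23), seed = 1)
  expect_equal(nrow(refs), 8)
  expect_equal(sum(refs$role == "TE"), 3)
  expect_true(all(nchar(refs$sequence[refs$role == "TE"]) >= 500))
  expect_true(all(nchar(refs$sequence[refs$role == "miRNA"]) %in% 21:23))

  again <- generate_references(3, c(500, 1000), 5, c(21, 23), seed = 1)
  expect_identical(refs, again)
  other <- generate_references(3, c(500, 1000), 5, c(21, 23), seed = 2)
  expect_false(identical(refs$sequence, other$sequence))

  te <- refs$sequence[refs$role == "TE"]
  for (m in refs$sequence[refs$role == "miRNA"]) {
    expect_false(any(grepl(m, te, fixed = TRUE)))
    expect_false(any(grepl(m, revcomp(te), fixed = TRUE)))
  }
  expect_error(generate_references(3, c(1000, 500)), "range")
  expect_error(generate_references(1, c(500, 600), 2, c(10, 12)), "range")
})

test_that("library simulation honours class mix, determinism and ping-pong
           truth bookkeeping", {
  refs <- generate_references(3, c(600, 1200), 4, c(21, 23), seed = 5)
  cfg <- library_config(n_reads = 3000, pingpong_fraction = 0.4,
                        error_rate = 0, adapter_fraction = 0, seed = 11)
  rs <- simulate_small_rna_library(refs, cfg)
  expect_equal(nrow(rs), 3000)
  expect_false(anyDuplicated(rs$read_id) > 0)
  # conservation: emitted per-class counts match class_mix within rounding
  cls <- table(rs$class)[c("miRNA", "siRNA", "piRNA")]
  expect_equal(as.integer(cls), c(450L, 450L, 2100L))

  rs2 <- simulate_small_rna_library(refs, cfg)
  expect_identical(rs, rs2)

  # every ping-pong pair has an exact 10-nt 5' overlap in truth coordinates
  paired <- rs[!is.na(rs$partner_id), ]
  sense <- paired[paired$true_strand == "+", ]
  anti <- paired[match(sense$partner_id, paired$read_id), ]
  e5 <- anti$true_start + nchar(anti$sequence) - 1
  expect_true(all(e5 - sense$true_start + 1 == 10))
  # symmetric partner links
  expect_identical(paired$partner_id[match(sense$partner_id,
                                           paired$read_id)],
                   sense$read_id)

  # pingpong_fraction = 0 leaves no partner links
  cfg0 <- library_config(n_reads = 500, pingpong_fraction = 0,
                         class_mix = c(miRNA = 0, siRNA = 0, piRNA = 1),
                         error_rate = 0, adapter_fraction = 0, seed = 3)
  rs0 <- simulate_small_rna_library(refs, cfg0)
  expect_true(all(is.na(rs0$partner_id)))
})

test_that("forced 1U with certainty and empirical bias recovery", {
  refs <- generate_references(2, c(800, 1200), 0, seed = 9)
  cfg1 <- library_config(n_reads = 400, pingpong_fraction = 1,
                         u1_bias = 1, error_rate = 0, adapter_fraction = 0,
                         class_mix = c(miRNA = 0, siRNA = 0, piRNA = 1),
                         seed = 2)
  rs1 <- simulate_small_rna_library(refs, cfg1)
  anti <- rs1[rs1$true_strand == "-", ]
  expect_gt(nrow(anti), 100)
  expect_true(all(substr(anti$sequence, 1, 1) == "T"))

  cfg <- library_config(n_reads = 2000, pingpong_fraction = 0.5,
                        u1_bias = 0.8, a10_bias = 0.8, error_rate = 0,
                        adapter_fraction = 0,
                        class_mix = c(miRNA = 0, siRNA = 0, piRNA = 1),
                        seed = 21)
  rs <- simulate_small_rna_library(refs, cfg)
  anti <- rs[rs$true_strand == "-", ]
  expect_gt(nrow(anti), 800)
  expect_lt(abs(mean(substr(anti$sequence, 1, 1) == "T") - 0.8), 0.05)
})

test_that("error-free reads are exact genomic substrings at their truth
           coordinates", {
  refs <- generate_references(2, c(500, 900), 3, c(21, 23), seed = 13)
  cfg <- library_config(n_reads = 600, pingpong_fraction = 0.3,
                        error_rate = 0, adapter_fraction = 0, seed = 8)
  rs <- simulate_small_rna_library(refs, cfg)
  seqs <- setNames(refs$sequence, refs$name)
  for (i in seq_len(nrow(rs))) {
    ref <- seqs[[rs$true_family[i]]]
    frag <- substr(ref, rs$true_start[i] + 1,
                   rs$true_start[i] + nchar(rs$sequence[i]))
    expected <- if (rs$true_strand[i] == "+") frag else oracle_revcomp(frag)
    expect_identical(rs$sequence[i], expected)
  }
})

test_that("adapter contamination and substitution errors are tracked", {
  refs <- generate_references(2, c(500, 900), 2, c(21, 23), seed = 4)
  cfg <- library_config(n_reads = 1000, pingpong_fraction = 0,
                        error_rate = 0.01, adapter_fraction = 0.3,
                        adapter = "TGGAATTCTCGGGTGCCAAGG", seed = 6)
  rs <- simulate_small_rna_library(refs, cfg)
  expect_equal(sum(rs$has_adapter), 300)
  # error-free adapter-bearing reads contain an adapter prefix
  with_ad <- rs[rs$has_adapter & rs$n_errors == 0 & rs$class == "piRNA", ]
  expect_true(all(grepl("TGGAATTC", with_ad$sequence, fixed = TRUE)))
  expect_true(all(nchar(rs$sequence) <= 50))
  expect_gt(sum(rs$n_errors), 0)
})

test_that("cross count simulation conserves totals and follows the planted
           logits", {
  des <- cross_design(lines = c(L1 = 0, L2 = 0), n_f1_per_cross = 10000,
                      seed = 1)
  cc <- simulate_cross_counts(des)
  expect_true(all(cc$n_dysgenic + cc$n_normal == 10000))
  dys <- cc[cc$direction == "dysgenic", ]
  expect_true(all(abs(dysgenic_proportion(dys$n_dysgenic, dys$n_normal) -
                        0.5) < 0.02))
  # reciprocal direction has maternal tester line
  rec <- cc[cc$direction == "reciprocal", ]
  expect_true(all(rec$maternal_line == "Ptype"))

  # planted spread covering the observed 0.10 / 0.90 propensity range
  des2 <- cross_design(lines = c(weak = -2.2, strong = 2.2),
                       n_f1_per_cross = 5000, seed = 2)
  cc2 <- simulate_cross_counts(des2)
  d2 <- cc2[cc2$direction == "dysgenic", ]
  p2 <- setNames(dysgenic_proportion(d2$n_dysgenic, d2$n_normal), d2$line)
  expect_lt(p2[["weak"]], p2[["strong"]])
  expect_lt(abs(p2[["weak"]] - 0.10), 0.03)
  expect_lt(abs(p2[["strong"]] - 0.90), 0.03)

  expect_identical(simulate_cross_counts(des), cc)
})

test_that("qPCR simulation: flat delta-Ct without effects, doubled expression
           per planted cycle", {
  des <- qpcr_design(lines = c("A", "B"), replicate_sd = 0,
                     direction_effect = c(spliced = 0, total = 0),
                     temperature_effect = c(spliced = 0, total = 0),
                     n_replicates = 2, seed = 1)
  q <- simulate_qpcr(des)
  expr <- relative_expression(q)
  expect_equal(length(unique(round(expr$spliced_expr, 10))), 1)
  expect_equal(length(unique(round(expr$splicing_efficiency, 10))), 1)

  des2 <- qpcr_design(lines = "A", replicate_sd = 0,
                      direction_effect = c(spliced = 1, total = 0),
                      temperature_effect = c(spliced = 0, total = 0),
                      temperatures = 29, n_replicates = 2, seed = 1)
  e2 <- relative_expression(simulate_qpcr(des2))
  dys <- e2$spliced_expr[e2$direction == "dysgenic"][1]
  rec <- e2$spliced_expr[e2$direction == "reciprocal"][1]
  expect_equal(dys / rec, 2)
})
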