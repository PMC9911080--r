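---
title: "Models and methods in pirnaHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pirnaHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnaHD)
```

`pirnaHD` studies the relationship between hybrid dysgenesis (HD)
resistance and piRNA-mediated transposon silencing with a fully simulated,
ground-truth-aware pipeline. This vignette is the package's account of its
models: what each stage assumes, which parameters matter, what the
synthetic data do and do not emulate, and where genuinely open design
choices were resolved.

## The synthetic-data model

### Small-RNA libraries

`simulate_small_rna_library()` emits a fixed number of reads split across
three classes by `class_mix` (default 15% miRNA, 15% siRNA, 70% piRNA —
ovarian small-RNA libraries are piRNA-dominated after rRNA depletion).
Class counts are apportioned by largest-remainder rounding so they match
the mixture exactly, not in expectation. Defaults for the length
distributions are conventional rather than fitted: siRNAs center on 21 nt,
piRNAs follow a discrete unimodal distribution on 23–31 nt peaking at
26 nt, and miRNA-class reads are emitted as entire miRNA reference
sequences (21–23 nt), so their length follows the reference set rather
than a separate draw.

piRNA reads are genomic fragments of TE consensus sequences on either
strand. A fraction `pingpong_fraction` (settable per family) is emitted as
ping-pong pairs: the sense 5′ start *s* is drawn uniformly and the
antisense 5′ end is placed at *s* + 9, which guarantees an exact 10-nt 5′
overlap in truth coordinates.

**Nucleotide biases are implemented as biased site selection, not base
forcing.** With probability `u1_bias` an antisense read is placed so that
its first sequenced base is T (equivalently, the reference base at its 5′
end is A); otherwise it is placed at a non-T-starting site. The empirical
1U fraction therefore equals `u1_bias` exactly in expectation, and —
crucially — error-free reads remain exact genome matches, so re-aligning
them recovers the truth placement with zero mismatches. Forcing the base
instead would make every biased read a 1-mismatch alignment and break that
closure property.

For a ping-pong pair the sense 10A site and the antisense 1U site are the
*same* reference base (position *s* + 9), which is the classic 1U/10A
complementarity; a single probability (`u1_bias`, falling back to
`a10_bias` when `u1_bias` is `NA`) governs pair placement. Unpaired sense
reads carry **no** positional bias: the 10A signature belongs to ping-pong
responder piRNAs, and — as we verified during development — selecting 10A
sites for unpaired sense reads couples sense and antisense site choices at
precisely the 10-nt overlap, manufacturing a large spurious z-score for
families with no pairs at all. Setting `u1_bias = NA` disables all
positional bias, giving the exact independent-uniform null used in the
calibration studies.

Adapter contamination appends the 3′ adapter to a fixed fraction of reads
before per-base substitution errors are injected; the sequenced read is
truncated at `read_budget` (50 nt, a 1×50 run) and never padded. Truth
tags record class, family, strand, 0-based start and partner identity for
every read.

What the simulator does **not** emulate: genomic piRNA clusters and their
promoter structure, transposition dynamics, copy-number variation among
lines, indel sequencing errors (the pipeline discards gapped alignments by
construction), quality-score variation (qualities are constant `I` and
ignored), and cross-mapping between related TE families beyond what random
sequence similarity produces. Passing tests on these simulations therefore
demonstrate the correctness and calibration of the *computations*, not
that real libraries satisfy the generative assumptions.

### Crosses and qPCR

`simulate_cross_counts()` draws the number of dysgenic F1 females per
cross from Binomial(*n*, logit⁻¹(line effect + tester subline offset)) in
the dysgenic direction and logit⁻¹(`reciprocal_logit`) (default 2%) in the
reciprocal control. Line logits of ±2.2 reproduce the 0.10–0.90 range of
dysgenic proportions seen in real screens. `simulate_qpcr()` models Ct
values as a per-target baseline minus additive direction, temperature and
line effects (in cycles) plus Normal replicate noise; the reference gene
receives baseline and noise only.

## Read processing

Adapter occurrences are read suffixes matching an adapter prefix of length
L ≥ 3 with at most ⌊0.1 L⌋ mismatches, mirroring common trimmer defaults;
the longest qualifying suffix is removed. Reads shorter than 5 nt are then
discarded.

The aligner considers every ungapped placement of the read and of its
reverse complement at every offset of every TE reference and reports the
minimum-Hamming-distance placement within the stringency tier (3, then 6
mismatches). The original tooling this mirrors used a seeded gapped
aligner followed by removal of indel alignments; an exhaustive gap-free
scan is the effective model of that combination and, unlike heuristic
seeding, is exactly checkable against a brute-force oracle. Ties are
broken deterministically — family name (C-locale lexicographic), `+`
before `−`, smallest start — replacing the pseudo-random multi-hit choice
of read mappers so that identical inputs always give identical outputs. A
read `N` never matches, even against a reference `N`. Coordinates are
0-based half-open; the 5′ end of a minus-strand alignment is `end − 1`.
miRNA subtraction removes reads with any placement on a miRNA reference at
≤ 1 mismatch, before TE mapping, making the stage order (trim → length →
miRNA → TE) explicit.

## Quantification and the precision-weighted model

Counts are tabulated per family and library within a read-length window.
The piRNA window defaults to 23–31 nt: published analyses variously use
23–31, 23–32 and ">22", so the window is an explicit, configurable
parameter rather than a constant. RPM normalization divides by the library
size (reads surviving trimming, the length floor and miRNA subtraction —
configurable) and multiplies by 10⁶; replicate averaging (mean of
replicate RPMs per line) is available for presentation.

The differential-abundance model is a deliberately simplified voom:
log2-CPM is `log₂((count + 0.5)/(N + 1) × 10⁶)`; a per-family linear model
on the covariate yields residual standard deviations; `lowess` (span 0.5)
smooths √sd against mean log-CPM; each observation's weight is the trend
prediction at its fitted log-CPM raised to the −4 power, floored at a
small positive constant so weights stay finite when a family fits
perfectly. Inference uses ordinary (not empirical-Bayes-moderated)
t-statistics from weighted least squares, with Benjamini–Hochberg
adjustment across families — the multiple-testing method is fixed by
convention here since "adjusted P" alone does not identify one. The
simulation studies (type-I rate 0.03–0.07 under a permuted covariate;
power ≥ 0.8 for a 2-log2-unit effect at 12 libraries) validate this
combination directly rather than by comparison to any external
implementation. Resistance enters as a continuous covariate, defined as
1 − mean dysgenic proportion across a line's replicate crosses in the
dysgenic direction; a log-transformed variant and extreme-group contrasts
are available through `classify_extremes()`.

## The ping-pong signature

For one family, every (plus, minus) alignment pair with 5′ ends *s* and
*e* contributes to overlap *o* = *e* − *s* + 1 for 1 ≤ *o* ≤ 20. The
default weighting counts read pairs with multiplicity; position-pair
weighting (one count per distinct (*s*, *e*)) is offered because
collapsed-read inputs are common in small-RNA work, and is never larger
bin-wise. The signature statistic is

z₁₀ = (c₁₀ − mean(B)) / sd(B),

with B the 19 non-focal bins and sd the sample standard deviation; a
degenerate background (sd = 0) yields an undefined flag rather than a
number. Published work reports ping-pong presence qualitatively; the z > 3
reporting convention used in the calibration studies is a documented
choice, calibrated on simulations (≤ 5% of independent-uniform libraries
exceed it), not a literature value. 1U/10A fractions are computed from the
sequenced read bases, mismatches included, because the biogenesis biases
act on the piRNA molecule rather than on the reference.

## Cross and qPCR statistics

The reciprocal-cross comparison uses Fisher's exact test with the
probability-ordering two-sided rule (all tables at the observed margins
with probability ≤ the observed, within relative tolerance 10⁻⁷),
computed from log-scale hypergeometric densities; the doubling convention
is noted but not used. The line-effect test is a binomial GLM (IRLS,
deviance tolerance 10⁻⁸, ≤ 50 iterations, first line as reference level)
compared to a tester-subline-only null by likelihood ratio;
|coefficient| > 15 flags (quasi-)separation while still reporting the
p-value. Screen concordance uses the Pearson t transform
t = r√((n−2)/(1−r²)).

qPCR expression is reported relative to the reference gene per replicate,
`expr = E^−(Ct_target − Ct_ref)` with amplification efficiency E = 2.0 per
cycle (no standard curves are modelled; E is configurable), which is
sufficient for ratios and ANOVA without choosing a ΔΔCt baseline
condition. Splicing efficiency is the spliced/total expression ratio.
Box–Cox selects λ on the grid [−2, 2] step 0.01 by profile log-likelihood
−n/2·log σ̂²(λ) + (λ−1)Σlog x. The ANOVA uses sequential (type-I) sums of
squares in the fixed order direction + temperature + line; with a
degenerate constant response the residual mean square is zero and F is
undefined, so the meaningful statement is that all factor sums of squares
vanish.

## Numerical and engineering choices

- The aligner core is C++ (exhaustive scan with early abandonment);
  identical read sequences share one scan. Its contract is enforced by an
  independent pure-R brute-force oracle in the test suite.
- All randomness flows through explicit seeds; the pipeline fans a master
  seed out to per-library child seeds (`seed × 1000 + library index`) so
  stages can be re-run in isolation. Identical seed and configuration give
  byte-identical outputs and manifest checksums.
- Name ordering anywhere it affects results (tie-breaking, extreme-line
  ties) uses C-locale (radix) sorting, so results do not depend on the
  session locale.
- Serialized coordinates are 0-based half-open in TSV and 1-based in the
  SAM dialect, per the SAM standard.

## Problem sizes in the validation studies

The shipped studies use sizes chosen to make the Monte-Carlo error small
relative to the bands being checked while staying desk-scale: 500 random
aligner instances (references ≤ 2 kb) at both tiers; every 2×2 table with
total ≤ 40 (135,750 tables); 200 null and 100 signal ping-pong libraries
(2,000 and 5,000 piRNA reads); 200 null and 200 power simulations of
20-family, 12-library count matrices; 500 null cross simulations for the
GLM; and one end-to-end run of 12 lines × 2 replicates × 2,500 reads with
one planted abundance family and one planted ping-pong family.

## Known limitations

- The mean–variance trend needs several families to be estimable; with
  fewer than four families, per-family standard deviations are used
  directly.
- The aligner is exhaustive, not heuristic: right for consensus-sized
  references (kb), not a general-purpose genome mapper.
- Multi-mapping reads are assigned to a single deterministic best hit; no
  apportioning is attempted, so closely related families would share reads
  in a way the simulator does not model.
- The qPCR model assumes perfect doubling and no well effects; the cross
  model assumes exchangeable F1 females within a cross.
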