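---
title: "Profiling and filtering sequencing errors in CDR3 amplicon repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and filtering sequencing errors in CDR3 amplicon repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3err)
```

## The problem

In TCR repertoire sequencing every distinct CDR3 nucleotide sequence is
treated as a clonotype, so every miscalled base that survives quality control
manufactures a spurious clone. With per-base error rates of order 10^-3 and a
30–36 nt CDR3, a few percent of reads carry at least one substitution; in a
data set of millions of reads this produces thousands of unique phantom
clonotypes, concentrated around genuinely abundant sequences at Hamming
distance 1. `cdr3err` implements the standard audit for this situation: a
monoclonal sample (one known CDR3) makes every deviant read an identified
error, from which the error process can be profiled and filtering rules
tuned; a simulator with ground truth plays the role of the monoclonal
control so the whole pipeline is verifiable end to end.

## Extraction criteria and their order

A read is accepted as a CDR3 observation only if, in some orientation,

1. it contains the V-side and then the J-side mapping segment with **100%
   identity** (an `N` inside a flank therefore fails);
2. the inter-flank span is in frame (length divisible by 3), free of `N`,
   and translates without a stop codon;
3. the conserved cysteine sits immediately V-proximal and an FGXG, FAXG or
   HGXG motif immediately J-proximal.

The default flank specifications carry the conserved C and F/H codons at
their ends, so criterion 3 is enforced structurally by flank identity; a
`check_motif = FALSE` flank spec instead triggers an explicit translated
check of the flank-adjacent codons. Rejection reasons are evaluated in the
fixed order *no flank match → out of frame → contains N → stop codon →
motif*, and the first failure is reported, so rejection tallies are
reproducible. Multiple flank matches are resolved leftmost-first; at 25–30 nt
of exact sequence, collisions are vanishingly rare.

Orientation is not encoded in read identifiers: the extractor infers it by
trying the forward strand first, then the reverse complement, as one must
with real data. Reverse-orientation records are reported in reference
coordinates (sequence reverse-complemented back, qualities reversed), so all
downstream position indices share one coordinate system. Positions are
0-based and the CDR3 window is half-open.

Phred filtering is a minimum-over-window rule: a record passes cutoff *q*
iff every base of its CDR3 has quality ≥ *q*; *q* = 0 passes everything.
Qualities are decoded as phred+33 by default with a `phred_offset` switch
for legacy phred+64 data.

## The simulator

`simulate_reads()` draws reads from one or more amplicon templates
(`pad | V flank | CDR3 | J flank | pad`, 125 nt by default) and injects:

* **substitutions** — per read, per template position, per alternative base,
  as independent Bernoulli events with probability
  `sub_rate[position, to] × lane multiplier × direction multiplier`.
  Rates are defined over the whole amplicon: errors landing in a flank make
  the read fail the 100%-identity criterion, exactly as in real data.
* **orientation** — forward with probability `p_forward` (default 0.5);
  reverse reads are emitted reverse-complemented with reversed qualities.
* **lane and sample structure** — `preset_study_design()` reproduces a
  trifurcated design: 3 preparations × 3 ligations × 3 lanes = 27 reactions,
  with a rate multiplier attached to the lane factor only (default
  `c(1, 1.6, 0.6)`), so lane effects dominate sample-preparation effects.
* **qualities** — error bases draw phred scores uniformly from 2–25; correct
  bases draw from 30–40 with probability 0.94 and from 2–29 otherwise. This
  is the minimal model that yields the empirically central property that
  phred filtering removes erroneous sequences selectively.
* **indels** — per-read probabilities (default 10^-4 each) of a single-base
  deletion or duplication inside the CDR3 window, keeping non-correct-length
  errors below 1% of all injected errors. A 1 nt indel breaks the reading
  frame, so such reads are typically rejected at extraction — also as in
  real data.
* **bursts** — with probability `burst_prob` (default 0) a read's
  substitution rates are inflated `burst_factor`-fold (default 50). This
  correlates errors within reads and produces an excess of
  multi-substitution reads over the independence expectation; the default
  keeps errors fully independent so both regimes are testable.

Defaults for the heterogeneous rate matrix (`random_sub_matrix()`) are
log-uniform per-cell rates over [10^-5, 5×10^-3], giving a several-hundred-fold
spread between the hottest and coldest position/substitution cells, with an
optional multiplier on the four transitions (C→T, G→A, A→G, T→C) so they
dominate the spectrum. (Note these four changes are *transitions* in
standard nomenclature, and the package labels them so.)

Every read gets a ground-truth row: template, orientation, lane, sample, and
the injected error list in 0-based template coordinates. Identical seeds and
configurations give byte-identical output; one root seed is expanded per
stage in the pipeline drivers.

**What the simulator does not emulate**: cluster-formation chemistry,
PCR-cycle error genealogy, barcode demultiplexing, quality-score drift along
the read, and the empirical error magnitudes of any particular instrument
run. Passing tests on simulated data therefore demonstrate that the
*machinery* (extraction, tallies, models, culling) is correct under a known
error process — not that any specific real data set has these error rates.

## Analytic models

**Multi-error independence expectation.** Under independent per-position
errors at single-error rate SER, the expected frequency of reads with
exactly M substitutions in an N nt CDR3 is `C(N, M)·SER^M` with
`C(N, M) = N!/(M!(N−M)!)`, computed in log space. SER here is a
*per-position* rate; when estimated from data it is taken as (fraction of
reads with exactly one substitution)/N, the reading that makes the formula
dimensionally consistent. The survival factor `(1−SER)^(N−M)` is omitted by
default — the formula is then an upper approximation whose relative error is
`1/(1−SER)^(N−M) − 1` (about 3.4% at SER = 10^-3, N = 36); passing
`include_survival = TRUE` yields the exact binomial probability. Observed/
expected ratios near 1 indicate independent errors; ratios above 1 an error
"complementation" excess, as produced by the simulator's burst mode.

**Read-direction boundaries.** For a clonotype observed n times, forward
read counts of direction-neutral sequences follow Binomial(n, p_fwd), with
p_fwd estimated from the dominant (or known true) clonotype. The boundaries
are the integer bounds such that the probability of more forward reads than
`upper`, or fewer than `lower`, is each *strictly* below 1% — computed from
the exact CDF with no normal approximation, ties broken toward wider
intervals. At least 98% of neutral clonotypes then fall inside. Clonotypes
with at least 20 reads are screened by default.

**Low-count culling thresholds.** If an index clonotype is seen
`index_count` times and the cull cutoff is a fraction `cutoff` of it, the
naive threshold is `index_count × cutoff` reads. Because a sequence whose
true frequency equals the cutoff fluctuates binomially, the adjusted
threshold is the smallest integer k with
`P(X ≤ k) ≥ confidence, X ~ Binomial(index_count, cutoff)`; culling
everything at or below k then eliminates, with at least the stated
confidence, any sequence at or below the cutoff frequency. At
(200, 0.5%, 95%) this gives k = 3 versus the naive 1.

## Culling semantics

Two deliberately different comparison rules are used, following the
conventions the analyses are defined by:

* **monoclonal mode** (`cull_monoclonal()`): a distance-1 clonotype is culled
  when its count is **at or below** `cutoff × index count`; cutoff 0 removes
  nothing and cutoff 1 removes every distance-1 clonotype at or below the
  index's own count.
* **polyclonal mode** (`cull_polyclonal()`): neighbor tallies count
  distance-1, strictly-lower-count clonotypes **strictly below**
  `cutoff × index count`.

"Lower frequency" in the neighbor relation is strict, so equal-count pairs
are mutually non-neighbors and the relation stays antisymmetric. The
polyclonal tallies take the 20 most frequent clonotypes as indexes (ties
broken lexicographically — a repository convention, since no canonical
tie-break exists), process them in descending count order, and never count a
clonotype for more than one index. Neighbor search uses single-position
wildcard keys, which finds each Hamming-1 pair exactly once; an all-pairs
scan serves as its oracle in the tests. The index or true sequence is never
culled.

## ACE richness

`ace()` implements the classic bias-corrected abundance-based coverage
estimator with rare/abundant cutoff 10 (the conventional setting):
clonotypes with count ≤ 10 form the rare group, sample coverage is
`C_ace = 1 − F1/N_rare`, the rare-group squared CV is
`γ² = max(S_rare/C_ace · Σ i(i−1)F_i / (N_rare(N_rare−1)) − 1, 0)`, and
`ACE = S_abund + S_rare/C_ace + (F1/C_ace)·γ²`. When every rare clonotype is
a singleton the coverage is 0 and the estimator is undefined; the Chao1
estimate `S_obs + F1(F1−1)/2` is returned with a fallback flag. With
coverage in (0, 1] the estimate is bounded below by the observed richness.
The implementation is cross-checked against the community-ecology reference
implementation (`vegan::estimateR`) in the test suite. Point estimates only;
no variance or rarefaction is computed.

## Numerical and degenerate-input conventions

* Per-cell lane ANOVA is a one-way fixed-effects F-test on raw per-sample
  rates (no transform); cells with no variance at all get p = 1 by
  convention. No multiple-testing correction is applied to the reported
  fraction of cells with p < 0.05.
* Lane CVs (sd/mean of per-sample rates) exclude zero-mean cells from the
  composite, with the exclusion count reported.
* Empty record sets yield empty tables and flagged NA percentages rather
  than errors; an empty abundance vector is an error.
* `expected_multi_error_rate()` warns when the expectation exceeds 1 (the
  approximation has broken down for that SER).
* The substitution matrix enumerates all 3 × length cells in every stratum,
  including zero counts, so downstream CV/ANOVA grids are complete.

## Problem sizes in the test suite

The shipped tests run the simulator at 10^5 reads for matrix-recovery checks
(3-binomial-SE per-cell agreement for injected rates ≥ 10^-3), 2×10^4–5×10^4
reads for filtering and direction-skew properties, and 27 × a few hundred
reads for the study-design checks — sizes at which binomial sampling error
is small relative to the tolerances being asserted, while the suite stays
fast. One caveat discovered by the recovery analysis is intrinsic to the
extraction criteria: a substitution that by itself creates a stop codon
removes its own read from the accepted set, so such cells cannot be
recovered from accepted sequences by any estimator; the recovery tests
exclude them and verify all remaining cells.

## Known limitations

* Flank matching is exact-only by design (the 100%-identity criterion);
  there is no mismatch-tolerant or Smith–Waterman mode, and no paired-end
  merging.
* Indels are length-classified only; no attempt is made to locate them.
* Clustering at Hamming distance 2–3 is out of scope (single-mismatch
  culling only).
* The simulator's quality model is a two-component caricature sufficient to
  make phred filtering selective; it does not reproduce real per-cycle
  quality profiles.
* Stop-codon-creating substitutions are invisible to monoclonal error
  profiling, as discussed above; their rates are not estimable from
  accepted reads.
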