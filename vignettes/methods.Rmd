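---
title: "Models and methods behind bcrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the scientific models inside `bcrsim`, the
parameters that matter, and the design decisions taken where the design
was genuinely open. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## The germline model

The package ships a *toy* murine immunoglobulin germline: random
coding-like DNA with implanted junction anchors, not IMGT sequences. The
statistics of interest (gene usage, isotype shares, pairing, editing
signatures) are carried by *gene identity*, not by sequence content, so
biological sequence realism is deliberately out of scope. What is modelled
faithfully is the locus *architecture*:

* **Igh**: by default 20 V, 10 D and 4 J segments. Real loci carry well
  over 100 V genes; 20 is enough to measure usage vectors without
  inflating alignment time. The functional D count is reported as a range
  in the literature (8–12); we fix 10 and record it in the run
  configuration.
* **Igk**: 15 V segments and five named J segments `Igkj1..Igkj5`, with
  `Igkj3` flagged as a pseudogene and excluded from simulation draws and
  usage denominators — preserving the four functional J genes and, more
  importantly, the semantics of `Igkj5` as the downstream-most editing
  target.
* **Igl**: exactly the two-cassette architecture — cassette 1 holds
  {`Iglv2`, `Iglv3`} upstream of `Iglj2–Iglc2` (family λ2); cassette 2
  holds `Iglv1` upstream of `Iglj3–Iglc3` (λ3) and `Iglj1–Iglc1` (λ1).
  V–J recombination is only ever generated within a cassette, and
  `cassette_of()` / the pairing matrix measure any violation downstream.

Every V segment is 120 nt in frame 0 with its conserved cysteine codon at
offset 111 (0-based) followed by a 6-nt trimmable tail; every J segment is
39 nt with a 6-nt trimmable head before its `[FW]G.G` anchor motif. These
two 6-nt buffers equal the trimming cap, which guarantees that exonuclease
trimming never destroys an anchor — a deliberate simplification that makes
"junction not locatable" a structural impossibility on simulator output.
All offsets are 0-based and intervals half-open. Segment terminal 24-mers
are kept unique (regenerated deterministically on collision) so that seed
lookup during annotation is unambiguous.

## The simulator

### Empirical mode

Empirical presets encode per-genotype frequency tables: the κ share, the
λ-family weights, the Igk-J weights, and per-locus unproductive read
fractions. Junctional diversity is geometric trimming (success probability
0.25 per nt, capped at 6 nt per end; 0 disables trimming) plus Poisson
N-additions (mean 4 for heavy junctions split over N1/N2, mean 1 for light
junctions) — conventional orders of magnitude for murine junctions; all
are preset fields.

Two definitions deserve emphasis:

* **`kappa_fraction` is the κ share among cells with a *productive* light
  chain** — that is what a sorted-BCR⁺ isotype measurement reports. The
  simulator back-solves the raw locus probability from the per-locus
  unproductive fractions, so the measured κ share is unbiased even when κ
  and λ unproductive rates differ. Had the locus been drawn directly with
  `kappa_fraction`, unequal unproductive rates would bias the measured
  share by more than the acceptance tolerance.
* **Productivity is forced, not emergent**: each read's failure mode is
  drawn first (Bernoulli on the preset's unproductive fraction, then an
  even split between out-of-frame and premature-stop), and the junction is
  post-edited to realise it — N-length adjusted to set the frame, stop
  codons rewritten (first base → C) or injected (TAA at a random interior
  codon). This makes classifier recovery a clean binomial experiment with
  known truth.

The built-in presets store published wild-type and knockout frequencies
(κ share 0.83 vs 0.98; Igkj5 share 0.10 vs 0.142; heavy-chain unproductive
fraction 0.92 vs 0.93). The λ-family weights are derived from the printed
per-gene figures under the cassette map: family weights (λ1, λ2, λ3)
determine J usage directly (λk ↔ Igljk) and V usage as
Iglv1 = λ1 + λ3. For the control genotype, (0.44, 0.41, 0.15) reproduces
both the printed Iglj1 share (44%) and the printed Iglv1 share (59%);
for the knockout, (0.69, 0.12, 0.19) reproduces Iglj1 = 69% and
Iglv1 = 88% and preserves the reported Iglj3 > Iglj2 preference. Within
λ2 the Iglv2:Iglv3 split is not published; we fix 0.4:0.6 (keeping the
reported Iglv1 > Iglv3 > Iglv2 ordering) and expose it as a preset field.
The light-locus unproductive fractions are likewise not published as
absolute numbers, only as knockout/control ratios (1.2× for Igk, 2× for
Igl); we set the control values to 0.10 for both light loci, giving 0.12
and 0.20 in the knockout.

### Mechanistic mode

The mechanistic simulator is a per-cell state machine embodying the three
determinants of λ-chain generation: (i) whether and when the *Igl* locus
opens (`p_igl_open`, drawn once per cell), (ii) the life-span of the
precursor (`survival_halflife`, the number of rearrangement attempts at
which survival probability is 50%; each attempt applies the derived
per-attempt hazard), and (iii) the efficiency of editing
(`p_igk_productive`, `p_autoreactive_kappa`, `max_edit_attempts`). Two κ
alleles are tried sequentially, J segments in ascending functional order —
so `n_edit_rounds` is higher among cells that ended on `Igkj5` than on
`Igkj1` by construction, which the tests assert — followed by RS-deletion
and the λ attempt. `kappa_silenced` models a silenced *Igk* locus (every
surviving cell is λ); `kappa_forced_autoreactive` models a ubiquitous
anti-κ self-antigen (no κ survivor).

No quantitative rates for editing, death or locus opening are published
for this system, so mechanistic mode is validated **only by orderings and
limits**: the surviving-cell λ fraction must be non-decreasing in
`p_igl_open` and `survival_halflife` and non-increasing in
`p_igk_productive`, doubling the half-life must never lower the λ
fraction, and the two knockout presets must reach their deterministic
limits. Printed frequencies are never asserted against mechanistic output.

### What the generator does and does not emulate

It emulates: paired heavy/light architecture, junctional diversity,
locus- and genotype-dependent frequency skews, controlled unproductive
fractions, decoy non-Ig reads, clonal expansions with a forced V gene, and
per-cell reproducible randomness (sub-streams derived from the master seed
and cell index, so enlarging a run never reshuffles earlier cells). It
does **not** emulate sequencing error, UMIs, somatic hypermutation,
class-switch recombination or transcript abundance. Green recovery tests
therefore demonstrate that the *analysis* is correct and unbiased on
error-free reads with known truth — not that it is robust to platform
noise.

## Annotation

Candidate genes are found by exact terminal 24-mer lookup — the read's 5'
prefix indexes V segments, its 3' suffix indexes J segments — and every
candidate is then verified by affine-gap local (Smith–Waterman) alignment
(match 2, mismatch −1, gap open −3, gap extend −1), ties broken by the
lexicographically smallest name. Seed lookup is lossless on simulator
output because rearrangement never touches the V 5' or J 3' terminus; for
external reads `full_scan = TRUE` additionally aligns seed-less reads
against every segment. This replaces an exhaustive scan of all candidates
for every read, which at 20,000 reads per run would dominate runtime for
no accuracy gain.

The junction runs from the V anchor-cysteine codon through the J anchor
codon (IMGT convention); the CDR3 is the junction minus both anchors. Two
mapping details matter numerically: the V anchor position is mapped from
the alignment's **left** end and the J anchor from its **right** end,
because any indel the local aligner picks up sits in the junction-facing
extension, never between a segment terminus and its anchor. A junction
whose anchors fall outside the aligned intervals is treated as non-Ig.

Productivity classification is a fixed decision order, so it is total and
deterministic: (1) *non_ig* if either gene call is missing or scores below
the identity threshold, or the V and J calls disagree on the locus;
(2) *out_of_frame* if the junction length is not a multiple of 3;
(3) *stop_codon* if the translation from the V coding start through the J
anchor contains a stop; (4) otherwise productive. The identity threshold
is a fraction (default 0.6) of the maximum attainable local score
2·min(read length, segment length). A fixed constant cannot work here:
measured random-DNA local scores against the V pool reach the size of a
legitimate short-J score, so the threshold must scale with the aligned
segment. The default separates the two regimes with a wide margin, and the
tests verify by simulation that random 300-nt DNA is classified non-Ig.

D genes are called only when an exact match of at least 5 nt of a D core
lies in the V–J gap, and are absent otherwise; D usage feeds no statistic.

## Statistics

Preprocessing keeps productive records with a CDR3 of ≥ 4 amino acids
occurring ≥ 2 times within its chain (both thresholds exposed; the length
cutoff is a judgement call — 4 aa is the smallest biologically sensible
CDR3 — since no published value was recoverable). Occurrence counts use
duplicate-collapsed records weighted by `duplicate_count`. The filter is
idempotent, which the tests assert.

Frequency denominators follow the measurement being emulated: isotype and
λ-family shares are per *cell* with a productive light chain (λ family
assigned from `j_call` via the J–C linkage, since constant regions are not
in the reads); gene usage is per productive *record* within the locus;
productivity fractions are per raw read, bucketed by called locus with
non-Ig reads in their own bucket so that every read is counted exactly
once. Pearson correlation between usage vectors is the standard two-tailed
test on union-aligned label sets (zeros for absent labels), undefined
below three labels. CDR3 net charge counts R and K as +1 and D and E as −1
with histidine neutral (pH-7 approximation; `include_his` switches it to
+1).

## Similarity networks

Edges connect unique CDR3 amino-acid strings at Levenshtein distance
exactly 1. We implement true Levenshtein — including length ±1 indels —
because that is the metric named for the analysis; a substitutions-only
Hamming mode is available behind a flag. Construction is by
deletion-neighborhood hashing: every string is keyed by itself and its
single-deletion variants; a candidate pair must share a key and is then
verified by the exact DP distance (the bounded early-exit variant agrees
with the full DP whenever the distance is ≤ 1). Runtime scales with total
neighborhood size rather than all pairs, and the tests require exact
agreement with a brute-force O(n²) oracle on ~1,000 strings. Components
come from union-find-style connected components (via igraph); components
with ≥ 3 nodes are flagged as candidate clonal expansions — the cluster
threshold has no published value and is never asserted, only exposed.
Networks are built per chain on preprocessed unique CDR3s, following the
preprocessing-before-analysis order.

## Problem sizes and reproducibility

The recovery checks simulate 10,000 cells per genotype (and a 5,000-read
heavy-chain pool), matching the scale of the single-cell experiments the
presets encode; each end-to-end run (simulate + annotate + measure) takes
on the order of half a minute on one core. Unit and property tests use
1,000–5,000 cells, which keeps every binomial tolerance (3 standard
errors) meaningful while the full suite stays fast. All randomness flows
from explicit integer seeds; per-cell sub-streams make outputs
byte-reproducible, which the tests assert at file level.

## Known limitations

* The germline is synthetic; alignment scores and junction statistics are
  not comparable to real IgBLAST output, and allele-level calling is out
  of scope.
* Mechanistic mode supports ordering-level inference only; its rates are
  not calibrated to any measured kinetics.
* Light-locus unproductive fractions and the λ2-internal V split are
  package choices (documented above), constrained but not determined by
  published numbers.
* No sequencing-error model: recovery results bound pipeline bias, not
  robustness to noisy base calls.
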