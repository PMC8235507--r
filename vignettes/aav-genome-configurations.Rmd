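---
title: "Recovering AAV genome configurations from single-molecule long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering AAV genome configurations from single-molecule long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapback)
library(dplyr)
```

## The problem

Adeno-associated virus (AAV) packages a ~4.7 kb single-stranded DNA genome
flanked by GC-rich palindromic inverted terminal repeats (ITRs). Virion
populations are heterogeneous: besides canonical full-length genomes, capsids
carry several classes of aberrant, subgenomic molecules:

* **Snapback genomes (SBG)** — fold-back molecules in which one strand
  covalently continues into the reverse complement of an overlapping genome
  moiety, so the molecule reanneals onto itself into a duplex. 5'-SBGs carry
  the left moiety (P5 promoter, partial *rep*); 3'-SBGs carry the right
  moiety (*cap* region, with P40 nearby). Arms of near-equal length make a
  *symmetric* SBG; unequal arms leave a single-stranded loop (*asymmetric*).
* **Incomplete genomes (ICG)** — truncations that retain one intact terminal
  ITR (the packaging-anchored 3' end) and never reach the opposite ITR.
* **Genome deletion mutants (GDM)** — both ITRs present, an internal region
  missing.
* **Other** — particles carrying foreign (host/helper) DNA.

High-accuracy single-molecule consensus reads sequence each packaged
molecule end-to-end, so every read is one virion genome and its
configuration can be recovered computationally. This package implements
that analysis as a tested pipeline over *synthetic* populations with known
truth labels: a reference builder, a population simulator, read QC, an
iterative local-alignment segmentation engine, a configuration classifier,
and population-level statistics.

## The reference model

`build_reference()` constructs a 4700 nt genome whose termini are perfect
palindromes of 144 nt (so `revcomp(ITR) == ITR` exactly, and the right ITR —
the reverse complement of the left — is the identical sequence). The
interior is uniform-random DNA. Promoters P5/P19/P40 are placed at fractions
0.055 / 0.19 / 0.38 of the genome and the rep/cap ORF intervals at
[0.06, 0.48) and [0.45, 0.95): what matters for the analysis is the
*operative geometry* — P5 and *rep* in the left moiety, P40 and *cap* in
the right moiety — not any particular natural isolate's annotation. Real
ITRs are ~145 nt imperfect hairpins with flip/flop orientations; modelling
them as perfect even-length palindromes keeps the palindrome property exact
and is sufficient for the coverage logic the classifier uses. All
coordinates are 0-based half-open; the plus strand carries the rep/cap
sense.

```{r}
ref <- build_reference(ref_config(seed = 1))
ref
```

## What the simulator emulates — and what it does not

`simulate_population()` draws a mixed population with, by default, category
proportions CANONICAL 0.40, SBG_5 0.15, SBG_3 0.10, ICG 0.20, GDM 0.10,
OTHER 0.05. Real populations are not quantified to this precision anywhere;
these defaults are chosen only so that every class is well represented, and
no conclusion in this package depends on them.

Per category the error-free payloads are exact string constructions:

* canonical: the full reference (or its reverse complement — both strands
  package equally, drawn 50/50);
* 5'-SBG: `ref[0:arm_a] ++ revcomp(ref[0:arm_b])` (arms are genome
  prefixes; the fold junction sits at read position `arm_a`); 3'-SBG is the
  mirror construction on suffixes. Arms are drawn uniformly on
  [300, L/2] nt — the upper bound keeps each SBG inside one genome moiety.
  Half the SBGs are drawn near-symmetric (|Δarm| from a folded normal, sd
  25 nt, capped at 100); the rest get a geometric loop of mean 300 nt. The
  truth subtype label is always recomputed from the realized arms against
  the 100 nt threshold, so generator branch and label cannot disagree. The
  asymmetric loop is modelled purely as arm-length inequality; no
  non-templated loop sequence is inserted.
* ICG: `ref[breakpoint:L]`, breakpoint uniform over the non-ITR interior —
  the uniform draw is itself the "no hot spot" null that the chi-square
  machinery tests;
* GDM: `ref[0:del_start] ++ ref[del_end:L]`, deletion length at least
  200 nt and at least 200 nt clear of each ITR, so both flanking blocks
  remain confidently alignable;
* OTHER: uniform-random DNA of 500–4000 nt.

A residual error model (substitution 0.3%, insertion 0.1%, deletion 0.1%
per base) emulates what is left *after* a 0.99 predicted-accuracy consensus
gate; consensus generation itself (polymerase passes, subreads) is not
simulated — reads carry `n_passes` / `predicted_accuracy` metadata instead,
sampled so a configurable fraction (default 10%) fails QC. The simulator
does not model encapsidation biophysics, chimeric host-genome junction
structure, or ITR secondary structure; a perfect score on these synthetic
populations therefore demonstrates that the *recovery logic* is correct,
not that real AAV preparations are this clean.

## Read QC

`qc_filter()` keeps reads with `n_passes >= 3` and
`predicted_accuracy >= 0.99`, both inclusive ("min" semantics — boundary
reads are kept). `bin_reads_by_length()` stratifies by read length into
half-open bins (default 500 nt steps); binning always partitions the input.

## The segmentation engine

`segment_read()` is the categorization core: align the whole read locally
to the reference; record the best qualifying segment; then realign the
unmatched left and right flanks *in isolation*, recursing until no
qualifying hit remains, a flank is shorter than `min_segment_len` (50 nt),
or depth 6 is reached. Because flanks are disjoint, segments never overlap
on the read, and together with the uncovered intervals they tile it.

The aligner is an affine-gap Smith–Waterman (match 2, mismatch −4, gap
open −4, gap extend −2 — megablast-like defaults; a length-g gap costs
`open + g·extend`), run over both strands (the minus strand aligns the
reverse complement with coordinates mapped back). Implementation choices
that matter:

* **Determinism.** Best-hit ties break by highest score, then longest
  aligned span, then smallest `ref_start`, then plus before minus — a total
  order. Inside a perfect-palindrome ITR the two strands score identically;
  the tie resolves to plus, and classification never depends on strand
  calls made inside ITR intervals.
* **Gap splitting.** One optimal alignment may bridge an internal deletion
  shorter than its flanking arms (the gap penalty is linear, the match gain
  is not). Alignments are therefore split into segments at any single gap
  run of 30 nt or more — the per-HSP behaviour of a seeded aligner — so a
  GDM junction always yields two collinear segments. 30 nt sits above any
  plausible residual-error indel and below the 50 nt minimum deletion the
  classifier calls.
* **Banding.** Exact-substring hits short-circuit the DP; otherwise exact
  13-mer seeds are clustered by diagonal and each cluster is scored by a
  banded DP (±32 nt padding — an order of magnitude above the indel drift
  expected at 0.1% + 0.1% indel rates on a 4.7 kb read). Seedless queries
  fall back to the full DP, preceded by a score-only prescreen: a
  reportable segment (≥ 50 nt at ≥ 85% identity) must reach score ≈ 55, so
  a seedless query whose best score stays under 70% of that bound cannot
  contain one. A ≥ 50 nt segment at ≥ 85% identity without a single exact
  13-mer is not meaningfully attainable, so the heuristic does not change
  results on this problem; the full-DP path remains available
  (`force_full = TRUE`) and the test suite checks the engine's scores
  against an independent reference aligner.
* Non-ACGT characters are normalized to N and never match. Minimum
  reportable identity is 0.85 over ≥ 50 read nt; both are user-tunable,
  and identity filtering is applied after alignment, so lowering the
  threshold can only add segments (coverage is monotone in it).

## The classifier

`classify_read()` walks a fixed decision tree; the first matching rule
wins. More specific evidence pre-empts weaker patterns: full-length
coverage first, then an explicit fold point, then the single-ITR and
deletion patterns.

1. no segments → OTHER;
2. one collinear same-strand walk (reference gaps < 50 nt treated as
   alignment noise) covering ≥ 95% of the genome including both ITRs
   (≥ 90% of each ITR interval) → CANONICAL;
3. a fold point — two adjacent segments on opposite strands, read gap
   ≤ 50 nt, both reference intervals reaching the *same* terminus within
   50 nt → SBG_5 or SBG_3 by terminus; subtype SYMMETRIC iff
   |arm_a − arm_b| ≤ 100 nt; the fold coordinate is the junction midpoint;
4. a collinear walk with exactly one terminal ITR intact → ICG, breakpoint
   at the interior end of the covered interval (plus-strand coordinates);
5. a collinear walk with both ITRs and an internal reference gap ≥ 50 nt →
   GDM; with several gaps, the widest is the deletion and the rest are
   reported via `n_gaps`;
6. otherwise OTHER.

Three normalizations deserve a note. First, ICG calls report
`itr3_intact = TRUE, itr5_intact = FALSE` for whichever terminal ITR the
read retains: packaging initiates at a 3' ITR, so a retained terminal ITR
*is* the molecule's 3' end regardless of which genome terminus it maps to
or which strand was packaged. This makes the defining ICG invariant — an
intact 3' ITR and no 5' ITR — hold by construction for every ICG call, and
the test suite asserts it over every simulated and adversarial input.
Second, SBG calls carry `strand = NA`: the reverse complement of a
fold-back read is the same molecule with its arms swapped, so a covalent
orientation is not observable. Third, all reported reference coordinates
are plus-strand 0-based half-open, whatever the read orientation. Reads
that show a fold *and* an internal deletion (conceivable chimeras) classify
as SBG — the fold is the stronger evidence — and are flagged in `note`.
None of these cutoffs (0.9 ITR coverage, 0.95 genome coverage, 50 nt
anchor/junction/deletion tolerances, 100 nt symmetry threshold) are
prescribed by the underlying category definitions, which are qualitative;
they are package defaults, exposed in `classify_params()`.

The regulatory annotation is a pure rule lookup on dimer geometry: a
5'-SBG whose covered interval contains P5 forms, after replication, a
tail-to-tail dimer whose opposing read-through transcripts can anneal into
dsRNA — the predicted Rep78 down-regulator; a 3'-SBG containing P40 forms
a head-to-head dimer with two P40 promoters sharing a central enhancer
neighbourhood — the predicted cap booster. A promoter counts as contained
when at least half its 50 nt interval is covered (an arm ending inside a
promoter should not flip the label). No expression is modelled.

```{r}
reads <- simulate_population(ref, sim_config(n_reads = 60, seed = 7))
kept <- qc_filter(reads)
calls <- classify_reads(kept, ref)
count(calls, category, subtype)
```

## Population statistics

`summarize_population()` aggregates calls into counts/fractions per
category, per-category length quartiles, the ICG/SBG ratio (reported in the
"ICG vs SBG" orientation together with both raw counts, since the ratio
alone is orientation-ambiguous), the symmetric fraction among SBGs, merged
per-run read accounting, and the breakpoint-uniformity statistic.

`breakpoint_uniformity_test()` formalizes the claim that incomplete
packaging is a random event: ICG breakpoints are binned into 20 equal-width
bins over the non-ITR interior and compared with the uniform expectation by
Pearson chi-square (df = bins − 1). Twenty bins keep expected counts ≥ 5
for n ≥ 100; bins that still fall under 5 expected are merged with a
neighbour, and fewer than two usable bins is an error rather than a
statistic. The test suite calibrates the type-I rate by Monte-Carlo under
the uniform null (500 replicates) and cross-checks the chi-square p against
a likelihood-ratio G-test.

```{r}
s <- summarize_population(calls, run_totals = c(run1 = 220645, run2 = 189274),
                          ref = ref)
s
glance(s)
```

`autoplot(s)`, `plot_breakpoints(calls, ref)` and
`plot_arm_symmetry(calls)` draw the composition bar chart, the breakpoint
histogram, and the arm-asymmetry histogram.

## Problem sizes and verification

The test suite verifies, among others: exact payload reconstruction of
every simulated class; binomial calibration of the error model; QC
idempotence and boundary semantics; alignment-score agreement with an
independent reference aligner on mutated fragments; equivalence of
`segment_read()` with an exhaustive exact-match decomposition on a 300 nt
toy reference (under harsh mismatch/gap scores that make the optimal local
alignment of an error-free read exactly its maximal exact match); 100%
category recovery on an error-free 1000-read quota population and ≥ 95% /
≥ 90% category/subtype recovery at default error rates (in practice both
are 100% at these sizes); and zero ICG-invariant violations across more
than 10,000 classified mixed reads. These sizes were chosen to give stable
statistics while keeping the default test run desk-fast; the acceptance
script (`scripts/acceptance.R`) recomputes the headline numbers from
scratch at 1000 reads per condition.

## Known limitations

* The ITR model is a perfect palindrome: flip/flop orientations, hairpin
  secondary structure, and rep-binding motifs are out of scope, and any
  strand assignment *within* an ITR is a tie resolved by convention.
* Category proportions, arm/loop/deletion distributions and the QC-failure
  mix are illustrative defaults, not estimates of any real preparation.
* OTHER is a bucket: host/helper chimeras are simulated as pure random DNA
  and not sub-classified; real foreign-DNA particles can carry AAV-homology
  junctions that would land elsewhere in the tree.
* The banded heuristic can in principle miss a segment with no exact
  13-mer match to the reference; at the error rates this package targets
  such segments do not occur, and `force_full = TRUE` disables the
  heuristic.
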