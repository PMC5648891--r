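---
title: "Digital counting with random-base molecular barcodes: methods and design notes"
author: "barquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital counting with random-base molecular barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barquant)
```

## The problem

When a pool of DNA or RNA molecules is amplified and sequenced, read counts
do not measure molecule counts: amplification bias and sequencing depth
distort the proportions by orders of magnitude.  Digital counting fixes
this by tagging every original molecule with a molecular barcode (a unique
molecular identifier, UMI) before amplification and counting *distinct
barcodes* instead of reads.  With random-base barcodes, a barcode of $k$
random positions provides $4^k$ possible labels — $4^{24} \approx 2.8
\times 10^{14}$ for the short design bundled here — at the cost of a new
failure mode: every substitution or indel introduced by the polymerase or
the sequencer creates a *new* barcode sequence, which inflates the count.

Accurate digital counting requires two certificates:

1. **Variety**: the barcode space must be large enough that distinct
   molecules essentially never draw the same barcode.  Operationally, the
   measured count must be invariant to the number of random bases used
   (a plateau in the random-base sweep).
2. **Depth**: every molecule's barcode must be sequenced at least once.
   Operationally, the measured count must be invariant to further
   sequencing depth (a plateau in the coverage sweep).

`barquant` implements the counting pipeline, the error-correction steps
that make the plateaus appear, both saturation sweeps, and a fully seeded
read simulator so every stage can be validated against known ground truth.

## The barcode model

A `barcode_design` declares the barcode region at the 5' end of the read:
which positions carry random bases and which carry designed **fixed
bases**, plus the read coordinates of the target sequence and the accepted
read-length window.  Two designs are bundled:

* `short_template`: 30-base barcode = 24 random + 6 fixed, 8-base target,
  read window 34–39;
* `long_template`: 50-base barcode = 38 random + 12 fixed, 50-base
  target, reads ≥ 90 bases.

The fixed bases exist to catch indels.  A single insertion or deletion
upstream of a fixed position slides the rest of the read out of its
reading frame, so the fixed position shows an effectively random base; it
then matches its expected base with probability about 1/4.  Filtering on
$k$ fixed positions downstream of an indel therefore removes the read with
probability about $1 - (1/4)^k$ (≈ 99.6% for $k = 4$).  The filter
default is the four fixed bases *furthest* from the sequencing primer —
positions 16, 21, 24 and 28 of the short barcode — because a distal
anchor catches indels anywhere upstream of it.

The identities and exact placement of the fixed bases in the bundled
designs are a synthetic layout with the published geometry (the original
oligo table is vendor-supplied); they are shipped as editable YAML under
`inst/extdata/`, not hard-coded, and `load_design()` accepts any layout
satisfying the invariants (random and fixed positions disjoint, together
covering the barcode exactly).  The bundled target sequences are likewise
synthetic stand-ins, drawn once with wide pairwise Hamming separation and
frozen, and are replaceable through `template_set()` or a reference FASTA.

## Clustering: bounded single-linkage under *Distance*

Errors are collapsed by clustering barcodes: two barcodes whose compared
positions differ at no more than *Distance* bases are merged, and merging
continues until no merge is possible.  The result is the set of connected
components of the "within *Distance*" relation — single linkage, so
members of a cluster need only be *chained* together, not mutually close.
*Distance* = 0 recovers plain distinct-barcode counting.  The default
*Distance* = 2 follows the observation that the cluster count is already
essentially constant there: a per-base substitution rate of ~0.25% on a
24–38-base compared region leaves the vast majority of erroneous reads
within 2 mismatches of their parent.

Only the random positions are compared (fixed positions carry no
molecule-specific information and are filtered upstream), and the
comparison set can be truncated to the first $k$ random positions for the
variety sweep.

The implementation deduplicates barcodes over the compared positions, then
generates candidate pairs by **pigeonhole partitioning**: the compared
positions are split into *Distance* + 1 contiguous segments, and any pair
within the bound must agree exactly on at least one segment.  Candidates
are verified with the exact masked Hamming distance and components are
taken over the verified edges.  This is exact — no heuristics — and
near-linear at realistic error rates; a quadratic all-pairs method
(`method = "naive"`) is retained and the test suite additionally checks
both against an independent union-find oracle.  Cluster identifiers are
the lexicographically smallest member barcode, making reports
deterministic and order-invariant.  Reads with `N` among the compared
positions are removed before clustering.

## Counting and resolution

`count_per_category()` clusters each (template, sample index) group
separately; the cluster count is the molecule count, and `coverage` =
reads/molecules.  Two stronger modes exploit the fact that two independent
samples (or two templates) essentially never share a barcode:

* `resolve_index_contamination()` pools all indices per template before
  clustering.  A cluster containing reads of both indices betrays
  contamination (primer carry-over, index sequencing errors, or index
  switching on the flow cell).  The cluster counts 1 toward the index
  with the majority of its reads; an exact tie splits 0.5 / 0.5.
* `resolve_misidentification()` pools everything — all templates, all
  indices, multi-mapped reads included.  A multi-mapped read contributes
  weight $1/(\text{number of assigned templates})$ to each candidate
  template.  Each cluster counts 1 toward the (template, index) category
  with the largest weighted tally; $m$-way ties split $1/m$ each.

Majorities are computed on (weighted) read counts, not on distinct
barcodes, and every mode conserves the total: summed counts always equal
the number of clusters.  Tied tallies are detected with an absolute
tolerance of $10^{-9}$ so that equal sums of fractional weights (e.g.
$3 \times 1/3$ vs $1$) compare as equal.  Pooled clustering is applied
within a design class only; short and long barcodes have different lengths
and are never compared against each other.

## Mapping

The native mapper compares the design's target-region coordinates against
every reference target, ungapped, assigning all templates within
`max_mismatch` substitutions (default `ceiling(width/10)`: 1 for 8-base,
5 for 50-base targets).  This is the appropriate tool for a designed
panel of a few short targets at known read positions; it deliberately does
not chase indels (such reads fail the fixed-base filter anyway).  Reads
shorter than the target-region end are compared over their covered
positions, requiring at least half the target.  For anything larger or
gapped, `import_sam()` ingests the output of an external aligner,
including secondary alignments as multi-mappings.

## Saturation analysis

`coverage_curve()` subsamples reads to a ladder of fractions (default
100, 32, 10, 3.2, 1, 0.32, 0.1 percent) and reports mean ± SD of the
count over `n_repeats = 8` independent draws per fraction.
`random_base_curve()` truncates the compared positions to the first $k$
random bases at a fixed subsampling fraction (default 10%).  Counts are
normalized to the maximal swept value, and `required_random_bases()`
scans for the smallest $k$ reaching a relative count of 0.95.

Numerical conventions, chosen once:

* Subsampling is exact-count without replacement
  (`round(fraction * N)` reads), not Bernoulli, so nominal fractions map
  to reproducible read counts; draws are seeded `seed + repeat_index`.
* Truncation keeps the $k$ random positions closest to the 5' end.  Which
  positions the truncation should keep is genuinely open; the 5'-most
  choice reflects that real reads are sequenced 5' to 3'.
* Reported coverage divides reads entering clustering by the resolved
  cluster count.
* The 100% point is deterministic: it is computed once and its SD is 0.

### Error and composition estimators

Each cluster's **consensus** is its per-position majority barcode (ties
toward the lexicographically smallest base), taken as the estimate of the
original molecule's barcode.  From consensuses the package reconstructs
three quantities of interest: the per-base substitution rate (mismatches
between member reads and their cluster consensus, over clusters with at
least 2 reads — singletons define their own consensus and carry no
evidence), per-fixed-position mismatch rates (flat ≈ the substitution
rate under pure substitution noise; increasing with distance from the
primer when indels are present), and the per-position base composition of
the barcode pool (measured on consensuses, so each molecule counts once
regardless of read multiplicity).  These estimators are reconstructions
of the quantities the method needs, not re-implementations of any
particular published computation.

## The simulator

The simulator is first-class, tested code: it generates the molecule pool
(`draw_molecules()`), then reads (`amplify_and_sequence()`), logging every
injected error so that the test suite can reconcile each emitted read
byte-for-byte against the truth.

* **Panel**: `preset_paper_panel()` reproduces the study composition —
  two identically composed indexed samples with, per sample, 40,000 /
  40,000 / 4,000 / 300 / 100 / 20 copies of LT1–LT6 and 20,000 / 20,000 /
  4,000 / 4,000 / 4,000 copies of ST1–ST5 (84,420 long-template molecules
  per sample in total).
* **Coverage**: negative binomial per molecule, mean 15 (inside the
  12.6–20.9 reads-per-molecule window in which counting is certified)
  with dispersion `size = 4` — the standard overdispersed choice, reducing
  to Poisson as `size` grows.  The true dispersion of the experimental
  coverage distribution is unknown; it is a free knob, and
  `min_reads = 1` switches to a zero-truncated draw for analyses that
  assume every molecule was read.
* **Errors**: per-base substitution 0.25% (midpoint of the 0.23–0.29%
  range estimated for this sequencing chemistry), insertions and
  deletions 0.05% each, N-masking 0.05%, applied independently per read.
  Indels shift the remainder of the read with no re-padding, which is
  exactly the frame shift the fixed-base filter detects.  Errors are
  applied once per read (sequencing-like); early-cycle PCR errors shared
  by many reads of a molecule are not separately modeled — with such
  errors a molecule would legitimately split into two clusters, a
  limitation shared by the analysis itself.
* **Contamination**: per-read index swapping (`swap_prob`) and
  per-molecule sample mislabeling (`contam_prob`) both place reads under
  the wrong index, emulating index switching and primer carry-over.
* Quality strings are emitted constant (they are never used), and only
  Read1 is modeled.

What passing tests on simulated data do *not* show: the simulator draws
i.i.d. errors and i.i.d. coverage, so it cannot expose position-dependent
error profiles, PCR jackpots, or context-dependent indel hot spots present
in real libraries.  The package's claims about real data rest on the
method, not on the simulation; the simulation certifies the *software*.

## Problem sizes and runtime

The test suite simulates 20–400 molecules per scenario (seconds each) plus
one full-scale recovery of a 20,000-copy template (~300,000 reads,
about 15 s).  The acceptance script repeats the 20,000-copy recovery over
three seeds and the 20-copy recovery over five.  The pigeonhole clustering
handles the ~33,000 distinct barcodes of the full-scale run in about two
seconds; the quadratic reference method is only for cross-checking small
inputs.

## Known limitations

* Single-linkage chaining can, in principle, merge two true molecules via
  a bridge of error reads; at $4^{24}$ barcode variety and *Distance* 2
  this is vanishingly rare, but at very small $k$ (truncation sweeps)
  chains collapse aggressively — which is precisely the behavior the
  variety requirement detects.
* Directional network methods (which use read-count asymmetry between
  neighboring barcodes) and edit-distance clustering are out of scope;
  indels are handled by the fixed-base filter instead.
* The native mapper is ungapped by design; use `import_sam()` for gapped
  aligners.
* Reads failing any filter are dropped, never corrected or trimmed.
* `demultiplex()` defaults to exact index matching; whether the original
  instrument demultiplexer tolerated mismatches is unstated, so the
  tolerance is exposed as a flag.
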