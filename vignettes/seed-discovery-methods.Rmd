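---
title: "Methods: conservation-based miRNA seed discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-based miRNA seed discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `mirSeedScan`, the
parameters that matter, the numerical conventions, and — because the package
ships its own synthetic-data generator — exactly what the simulations do and
do not demonstrate about real data.

## The model

The pipeline looks for 7-nt UTR elements whose conservation across a panel
of species exceeds what neutral drift would produce. Its central abstraction
is the **Window Conservation Score (WCS)**: the arithmetic mean of the
per-base conservation scores inside one 7-nt window. Three modelling
commitments follow from how conservation tracks are produced:

* **Relative, not absolute, conservation.** Each species' track typically
  derives from its own multiple-sequence alignment (its own genus or clade),
  so absolute scores are not comparable across species. All ranking
  (CS50, CS95) is therefore strictly within-species; cross-species
  information enters only through pooled counts.
* **The binomial null.** Within one species, the median WCS (CS50) splits
  retained windows into equally many high and low by construction — but only
  marginally. For any *particular* 7-mer, without selective constraint, each
  of its windows independently lands above or below the species median with
  probability 1/2, which is the null of the one-tailed test
  `P(X >= n_high)`, `X ~ Binomial(n_high + n_low, 1/2)`. This marginal
  argument is an approximation: windows of one 7-mer within a species share
  sequence context and are not perfectly exchangeable with the window
  population at large. The test direction is one-sided by design —
  conservation *above* background; depleted 7-mers are never candidates.
* **Pooling.** High/low counts are summed over species and a single
  binomial test is run per 7-mer. The alternative — per-species tests
  combined afterwards — weights species by evidence rather than by window
  count; the pooled form was chosen because the counts are the directly
  observable quantity and the decision is made once per 7-mer. Species in
  which a 7-mer never occurs contribute nothing either way.

The detected, conserved UTR 7-mer is the *site*; the reported *seed* is its
reverse complement, because a miRNA seed (positions 2–8) pairs with its
target site by Watson–Crick complementarity. Since published seed lists do
not always state their orientation convention, every entry point takes
`seedOrientation = "revcomp"` (default) or `"identity"` so a comparison can
be run both ways.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `utrLength` | 80 | nt | operational 3'UTR for annotations without UTR coordinates; covers the bulk of detectable short UTRs. A single constant, configurable but not heterogeneous. |
| `k` | 7 | nt | seed width (miRNA positions 2–8); fixes the universe at `4^7 = 16384`. |
| CS50 / CS95 | 50th / 95th percentile | — | CS50 splits high/low for the seed test; CS95 gates target-site calling (strictly greater; ties drop). |
| `alpha` | 0.05 | — | family-wise level after Bonferroni. |
| `mTests` | `"all_kmers"` (16384) | tests | genome-scale convention: every possible 7-mer is a potential test. `"observed"` is appropriate for small (simulated) genomes where most 7-mers never occur — with, say, 10^4 windows, an `all_kmers` correction would demand counts that small data cannot produce, making power, not error control, the binding constraint. |
| `repeatOverlapMinBases` | 1 | nt | strictest reading of "overlaps a repeat"; configurable. |

Coordinates are held as `GRanges` (1-based, closed) everywhere inside the
package; BED (0-based half-open), GFF3 (1-based closed) and wiggle formats
are converted only at the file boundary by `rtracklayer`, so no module ever
reasons about two conventions at once.

## Numerical choices

* **Percentiles** use linear interpolation between the closest order
  statistics (`stats::quantile`, type 7), fixed and documented so CS50/CS95
  are deterministic for a given score list.
* **Ties at CS50** (WCS exactly equal) are excluded from both counts: the
  definition of high/low is strict inequality, and exclusion keeps the null
  probability at exactly 1/2. To make exact ties detectable in floating
  point, WCS is computed by the same left-to-right 7-term summation for
  every window, so windows with identical score patterns get bit-identical
  WCS values. Degenerate input with all scores equal therefore yields all
  ties, no testable counts, and zero candidates.
* **Binomial tails** use the exact survival function (`pbinom`,
  `lower.tail = FALSE`), valid for pooled counts in the tens of millions; a
  `log = TRUE` mode is available because genome-scale tallies can push the
  tail below the smallest positive double.
* **The hypergeometric point probability** is computed in log space
  (`lchoose`) and the significance is the *inclusive* upper tail
  `P(X >= k)` — the standard enrichment reading of an observed overlap. The
  implementation is cross-checked in the tests against `stats::dhyper` and
  against exhaustive enumeration of all draws for small universes, two
  routes it never uses itself.
* **Determinism.** The pipeline contains no randomness, and all character
  sorting uses radix (C-locale) ordering, so identical inputs give
  byte-identical output tables regardless of locale. Output rows are sorted
  by corrected P value with lexicographic tie-breaks.
* **Degenerate inputs.** Genes abutting a chromosome edge get an empty,
  flagged UTR and are excluded downstream; windows containing `N` or a
  position without conservation information are dropped rather than
  partially scored (a partial mean would change the statistic); species
  retaining no scored window are excluded with a warning, and a scan with no
  surviving species is an error.

## What the simulator emulates — and what it does not

`simulateBundle()` generates per-species bundles: uniform-composition
genomes, non-overlapping genes on random strands (laid out so every 80-nt
UTR falls between gene bodies), i.i.d. per-base background scores from
`Beta(mean 0.30, concentration 10)`, and planted sites — per (UTR, true
seed) with probability `plantProb`, the seed's reverse complement written
into the sense strand at a uniform offset with its 7 scores redrawn from
`Beta(mean 0.95, concentration 10)`. Repeats cover 5% of the genome in
50-nt intervals placed away from planted sites (a `plantInRepeats` scenario
inverts this to verify that repeat exclusion blocks recovery). Coding
intervals equal gene bodies, as in compact prokaryotic genomes. Everything
is reproducible from one RNG seed, and the bundles round-trip through the
same FASTA/GFF3/bedGraph/BED readers real data would use.

**The site-isolation buffer.** The generator leaves the conservation track
uncovered for `isolateFlank = 6` nt on each side of every planted site.
This is a deliberate property of the simulation design, not of the method:
a window that *partially* overlaps a planted site inherits both elevated
conservation and up to six fixed bases of the site, so every planted seed
would otherwise spawn a family of systematically conserved "shifted-shadow"
7-mers. Those shadows are not errors of the caller — they are real conserved
elements the generator created by accident — but they make "false positive"
ill-defined. Leaving the flanks unscored (the windowing contract already
drops windows touching missing scores) makes the exact planted window the
only scored window containing planted bases, so ground truth is unambiguous
at window resolution. On real genomes, shifted neighbours of a genuinely
conserved site *will* co-occur in candidate lists; users should expect
candidate seeds to cluster in shift families. Setting `isolateFlank = 0`
restores raw planting.

Other things the simulator does **not** emulate: realistic nucleotide
composition or codon structure, phylogenetic correlation between species
(each species is independent, whereas real conservation tracks share
ancestry), alignment artefacts, annotation errors, overlapping genes, and
UTRs truncated by neighbouring ORFs (the scan deliberately does not mask
ORF-overlapping UTR elements at the seed-calling stage; coding overlap is
applied only when extracting target genes). Passing tests on simulated data
therefore demonstrate the statistical machinery — calibration of the tests,
correctness of the filters, determinism — not performance on real archaeal
genomes.

## Problem sizes used by the test suite

The package's statistical acceptance checks run at sizes chosen to make the
properties measurable while keeping the suite quick on one CPU: family-wise
error is estimated from 100 independent null simulations of 3 species × 60
genes with `mTests = "observed"` (expecting ≥ 95 runs with zero
candidates); parameter recovery runs 20 replicates at the study conditions
of 10 species × 200 genes, 5 true seeds, `plantProb = 0.2`, background mean
0.30, planted mean 0.95, expecting sensitivity 1.0 with 0 false positives
in ≥ 95% of replicates. Exactness checks compare the binomial caller with
brute-force pmf summation for every tally with `n <= 25` and the
hypergeometric tail with exhaustive draw enumeration for universes up to
`N = 12`.

## Known limitations

* The 80-nt UTR is a blunt instrument: real 3'UTR lengths vary, and an
  element just past the cutoff is invisible.
* The pooled binomial treats windows as independent Bernoulli trials;
  overlapping windows within one UTR and repeated occurrences of a 7-mer in
  one gene violate independence, making the raw P values anticonservative
  for clumped signals. Bonferroni's conservatism pushes the other way; the
  null simulations in the test suite measure the net family-wise error
  empirically rather than assuming it.
* Perfect 7-mer matching only: no G:U wobble, no mismatch tolerance, no
  free-energy model.
* Functional enrichment of target genes is intentionally out of scope: the
  package exports the per-species foreground and background gene lists a
  DAVID-style service consumes, nothing more.
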