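---
title: "Methods: screening alignment chains for conserved sequence deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening alignment chains for conserved sequence deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Recurrently evolved trait loss — reduced fins in distantly related fish
lineages, for example — can be mapped by *forward genomics*: compare many
genomes that either retain the ancestral trait ("outgroups") or have
independently lost it ("targets"), and look for reference-genome sequence
that is deeply conserved in the trait-complete species yet missing from
multiple independent trait-reduced clades. `condelscan` implements this
screen for **conserved sequence deletions (CONDELs)** on top of pairwise
whole-genome alignment chains (UCSC chain model: scored, ordered ungapped
blocks between a reference and each query genome).

The genotype signal is a **chain gap**: an inter-block stretch of
reference sequence unaligned in a query. A gap is *single-sided* when the
query advances zero bases (a clean deletion) and *double-sided* when both
genomes have unaligned sequence (deletion plus insertion, or unalignable
divergence). The conservation signal is sliding-window percent identity
inside ungapped blocks, turned into per-species *conserved elements* by a
genome-wide coverage quota. A candidate is an interval where, near a
gene, deletion consensus across the screened target clades coincides with
deep outgroup conservation and (almost) no outgroup carries the same gap.

## Pipeline stages and their parameters

All coordinates are 0-based half-open throughout (the native chain/BED
convention), so nothing is ever shifted on input or output.

**Orthology filter.** For each gene and query species the screen uses a
single orthology-confident chain. A chain's candidacy score is its
alignment score weighted by the covered fraction of the canonical
(longest; ties by transcript id) transcript's exonic bases. The best
chain is *confident* when the best/second score ratio is at least 10 (a
sole chain counts as ratio infinity) **or** at least 10 of the nearest
flanking genes (up to 10 per side) share the same best chain
(gene-in-synteny). The source method cites these two thresholds without
spelling out the combination rule; we adopt the disjunction, expose both
thresholds (`ratio_thresh`, `synteny_thresh`, `n_neighbors`), and note
that a conjunctive variant only shrinks the confident set.

**Chain gaps.** Every junction with `dt > 0` yields one deletion-evidence
interval. To avoid mistaking unsequenced assembly for genuine deletion, a
gap whose query-side context lies within 100 bp (`assembly_flank`) of a
run of at least 6 Ns (`n_run_min`; "longer than 5 Ns" read as run length
≥ 6) is invalidated. The distance is measured on the query assembly's
forward strand — the only frame in which assembly N-runs exist — with
minus-strand chain coordinates converted first. Exclusion drops the whole
gap rather than trimming its neighbourhood: the filter is a per-interval
validity call, and whole-gap dropping is the conservative reading of
"excluded (subtracted)". Valid gaps merge within 20 bp (`merge_dist`),
per chain, never across chains.

**Conserved elements.** Identity is computed in windows of 10, 25, 50 and
100 bp (`window_sizes`) advancing one base at a time, entirely inside
single blocks — identity across an indel is undefined in the chain block
model. Matching is case-insensitive (soft-masking guided the upstream
aligner, not this score) and `N` never matches. Per species, windows are
sorted by identity only; the selection keeps the smallest top set whose
merged union covers 5 % of the reference (`coverage_frac`) and then adds
the entire tie class of the last included identity value, making the
result deterministic regardless of sort stability. Selected windows merge
within 20 bp per chain.

**Association scan.** A gene is scorable when it maps confidently to at
least 17 outgroups and 5 targets (`min_outgroups`, `min_targets`). Its
window spans 200 kb (`flank`) on each side of the canonical TSS —
400,001 bp unclipped. Deletion consensus requires a valid gap in at least
⌈⅔ · clade size⌉ species of **every** screened target clade
(`clade_frac`; the denominator is all configured clade species — species
without an orthologous chain contribute no gap). Consensus intervals are
intersected with the regions conserved in at least 17 outgroups; pieces
of ≥ 20 bp (`min_raw`) are raw candidates, merged within 20 bp, and
merged pieces of ≥ 50 bp (`min_final`) survive. A candidate is then
discarded if more than one (`max_violations`) *scorable* outgroup — one
whose confident chain spans the candidate entirely — carries a valid
overlapping gap. Candidates found via several genes are deduplicated by
exact interval equality, with linked genes unioned; per-gene windows see
the same global tracks, so identical regions produce identical
coordinates (a window-edge clip can make intervals differ, in which case
they are honestly reported separately).

## Statistics

* **Boschloo's exact test** is used for editing-experiment phenotype
  counts. The statistic is the one-sided Fisher exact p-value of the
  observed table; the p-value is the supremum over the common success
  probability of the chance of a table at least that extreme under two
  independent binomials. The supremum is located on a 10,001-point grid
  and refined by local optimization (p-value accurate to ~1e-10).
  Two-sided inference doubles the smaller one-sided p-value, and the
  nuisance maximization treats the supplied table's *columns* as the
  binomial experiments — both conventions mirror the implementation used
  in the published analyses, which the package reproduces exactly; a
  `groups = "rows"` switch provides the textbook row-margin convention
  instead. Uniform dominance over Fisher's test holds under either.
* **Welch's t** and the **Mann–Whitney U** (exact enumeration up to
  combined n of 20 without ties, normal approximation with tie
  correction otherwise) wrap the standard R implementations.
* **Phylogenetic GLS means** under Brownian motion,
  `(1'V⁻¹1)⁻¹ 1'V⁻¹ y` with `V` the shared-branch-length matrix, give
  tree-corrected trait means; `phylo_welch()` feeds those means into a
  Welch test whose dispersion comes from the raw per-species values — a
  documented interpretation of "Welch's t on phylogenetically corrected
  means", validated as a procedure (it reduces exactly to the plain
  Welch test on a star tree), not against any printed value.
* **PWM scanning** reports hits on both strands whose relative score —
  log-odds rescaled between the matrix's attainable minimum and maximum
  to 0..1000 — reaches 925. The PFM-to-PWM conversion uses a total
  pseudocount of 0.8 split by a uniform 0.25 background (a common motif
  convention; the upstream tool's constants are not published), both
  configurable.

## The synthetic-data generator

`simulate_condel_bundle()` builds a complete, seed-reproducible study: a
random reference chromosome (default 100 kb — large enough that the 5 %
quota, multi-scale windows and per-gene scans all behave as at genome
scale while a full screen stays interactive); 8 genes with evenly spaced
TSSs and alternating strands; 17 outgroups; and two screened target
clades of 4 and 3 species. Twenty deletions of 60–300 bp are planted on
an even grid, each inside a planted conserved region (deletion ±100 bp);
ten further neutral conserved elements carry no deletion. Outgroups and
targets accumulate substitutions at 0.02/site background and 0.001/site
in conserved regions. Chains are emitted directly from the known
simulated alignment — the screen is being tested, not an aligner.
Feature coordinates are computed without randomness, so different seeds
move the noise but never the truth; the same seed reproduces the bundle
byte for byte.

Dedicated configuration switches plant genotype–phenotype violations
(the same deletion in chosen numbers of outgroups) and assembly N-runs
next to deletion junctions in target genomes (to exercise the 100 bp
exclusion rule). The default configuration is noise-free — no background
indels, no assembly gaps — and on it the screen recovers every planted
locus exactly, with no false positives.

Two deliberate departures from realism matter when interpreting passing
tests. First, simulated chains align the entire chromosome, so window
identity is the only conservation discriminator; with a 0.02 background
rate most 10 bp windows are mutation-free, the top identity tie class is
genome-wide, and per-species conserved tracks are consequently broad.
The screen's specificity then rests, as designed, on the clade-consensus
deletion requirement — real data add alignability itself as a second
discriminator. Second, the violation scenario uses 19 outgroups rather
than 17: with exactly 17 outgroups and a 17-outgroup conservation quota,
even one violating outgroup (whose deletion removes its conserved
coverage) makes the quota unreachable, so "one violation tolerated, two
fatal" is only observable with spare outgroups — as in the real study,
where outgroups outnumber the threshold. With 19, a two-violation locus
still passes the conservation quota and is removed specifically by the
violation filter. More generally, the generator has no rate
heterogeneity beyond its two classes, no rearrangements, and plants
clean deletions, so recovery there demonstrates the interval logic and
thresholds, not robustness to alignment artefacts.

## Numerical and degenerate-input choices

* Interval merging treats separation `start_next − end_prev ≤ max_dist`
  as mergeable, so touching intervals always merge; the metric is not
  defined in the source description and is fixed here once.
* `coverage_count()` with a species threshold above the number of tracks
  warns and returns an empty result instead of erroring — an
  under-populated screen is a data problem, not a programming error.
* Conserved-element selection below an unreachable quota warns and
  returns all windows.
* Degenerate 2x2 tables: an empty treatment group errors; a table with
  no outcome variation returns statistic 1, p 1. Two constant samples
  with equal means give `t = 0, p = 1`; with unequal means Welch's df is
  undefined and the call errors. A fully tied Mann–Whitney comparison
  returns p = 1.
* Chain parsing validates the format invariants (block sums against both
  spans, positive sizes, non-negative gaps, `+` reference strand) and
  reports the offending record's line number; writing then parsing is
  bit-exact.

## Interfaces

The package is driven from R: `condel_screen()` on an in-memory bundle
returns a classed result with `print()`/`summary()` methods, and
`run_condel_screen()` orchestrates the stages from a YAML/list
configuration — every threshold above is a named key defaulting to the
screen's canonical value — writing BED/TSV outputs plus a manifest with
checksums, package version and seed, so unchanged inputs reproduce
identical outputs. Stage functions (`orthology_map()`,
`extract_chain_gaps()`, `score_windows()`, `call_conserved_elements()`,
`target_deletion_consensus()`, `call_condels()`, `extract_condel_msa()`,
the statistics, and the simulator) are exported individually; scripted
use from a shell is a thin `Rscript -e` away, which is why no separate
command-line binary is shipped.

## Known limitations

* Net files, MAF, 2bit and chain re-scoring are out of scope; chains are
  consumed as given.
* Orthology confidence implements the two cited tests only — no
  reciprocal-best mapping or paralog resolution.
* The exact-interval deduplication will keep window-clipped variants of
  one region distinct; downstream consumers wanting a fuzzier grouping
  can post-process candidates with `merge_intervals()`.
* `phylo_welch()` corrects the means but not the variances; it is a
  reporting recipe, not a full phylogenetic hypothesis test.
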