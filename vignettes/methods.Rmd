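---
title: "Methods: ancestry painting, Ks dating and gene-tree support in musaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry painting, Ks dating and gene-tree support in musaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musaic)
```

`musaic` analyses hybrid genomes that are segmental mosaics of several
ancestral (sub)species. This vignette explains the models and rules behind
each stage, the parameters that matter, what the built-in simulator does
and does not emulate, and the numerical choices made where the design was
genuinely open. Coordinates are 0-based half-open everywhere, as in BED.

## Diagnostic tags

A *diagnostic tag* is a k-mer present in one ancestral group's sequence
panel and absent, on either strand, from every other group's panel. Tags
are stored canonically (the lexicographically smaller of a k-mer and its
reverse complement), so strand never matters downstream; `k` must be odd,
which rules out reverse-complement palindromes and gives every hit a
well-defined strand.

Parameters (`tag_config()`):

- `k` (default 31 bp): long enough that random collisions between diverged
  panels are negligible (4^31 ≫ any plant genome), short enough that a
  single substitution creates k new diagnostic k-mers on each side.
- `min_group_freq` (default 1.0): a candidate must occur in this fraction
  of its own group's panel sequences. The default demands fixation within
  the group, trading tag density for specificity.
- `max_hits` (default unlimited): tags hitting more loci than this are
  dropped by `match_tags()`. Painting relies on tag *density*, so
  multi-locus tags are kept by default; the flag exists for repeat-rich
  assemblies.

Matching is exact (Biostrings `matchPDict` on both strands); windows
containing non-ACGT characters can never match and so produce no hits.
With panels diverged ≥1%, roughly `2 * k * divergence` of positions seed
tags, i.e. tags every few tens of bases — ample for 10-kb windows.

## Ancestry painting

Tag hits are counted into fixed windows (each hit assigned by its start
coordinate; the last window of a chromosome may be short). A window is
labelled by the *dominance rule*: the group with the plurality of hits
wins iff the window holds at least `min_hits` hits in total **and** the
winner holds at least `ratio` of them; ties, low evidence and conflict all
give `NA` — a region to which no origin can be attributed. `NA` is a
statement about evidence, distinct from any real "unknown ancestor" group,
which is simply another label with its own tag panel.

Defaults (`painting_config()`): `window` 10 kb for the synthetic scale
used here (~100 kb is appropriate at whole-genome scale), `min_hits` 5,
`ratio` 0.75. The rule is deliberately the simplest one whose failure mode
is `NA`: increasing `min_hits` can only grow the `NA` set (a tested
monotonicity property), so confidence tuning never flips labels. Raw
counts are used by default; `normalize = TRUE` divides each group's count
by its total tag count for unbalanced panels. Breakpoints are resolved at
window granularity — no sub-window refinement, matching the resolution at
which such paintings are interpreted.

Whole contigs are assigned to haplotypes with the same rule
(`assign_contigs()`); unassigned contigs belong in both haplotype
assemblies. Chimeric contigs are detectable from the per-window table but
are not split.

## Trio phasing and haplotype tags

`phase_markers_from_trio()` uses standard Mendelian logic on biallelic
calls: a child heterozygote is phased when exactly one assignment of its
two alleles to the two parents is compatible with the parental genotypes
(an allele absent from one parent must come from the other). Sites
compatible with both assignments stay unphased; sites compatible with
neither are flagged Mendelian-inconsistent and excluded. Haplotype 1 is by
convention the parent-1 side. Map-phased markers from prior studies can be
supplied directly in the same table format; the package does not recompute
linkage maps.

`build_haplotype_tags()` substitutes each haplotype's alleles into the
reference and takes the k-mer centred on every phased site, so markers
closer than `k` share tags that carry both alleles; tags common to the two
haplotypes (possible via reverse-complement coincidences) are removed,
making the sets disjoint by construction.

## Synteny blocks, the >20 rule, and ortholog groups

The package consumes a one-best-hit-per-gene table (from gene identity on
synthetic data, or any aligner on real data); similarity search is not
reimplemented. `chain_blocks()` finds longest collinear chains by dynamic
programming: consecutive anchors must advance by 1–`max_gap` ranks in both
genomes (descending in the second genome for antiparallel blocks), and
non-overlapping chains are extracted greedily best-first until none
reaches `min_block` genes. Defaults `max_gap = 10`, `min_block = 5` follow
common collinearity-tool practice. Ties between equally long chains go to
the earlier chromosome pair and to "+" orientation, making the output
deterministic.

Blocks of two assemblies, each computed against the same reference, are
*associated* when they share **strictly more than 20** reference genes
("more than 20" is read as > 20: sharing exactly 20 does not associate).
Association is per block pair and never closed transitively. Orientation
is ignored for association — only the shared-gene count matters — since
inverted blocks still tie the same reference genes together. An ortholog
group is one reference gene plus its paired gene in each assembly whose
blocks are mutually associated; reference genes pairing with two genes of
one assembly are dropped with a warning rather than guessed.
`filter_groups_by_ancestry()` then restricts groups to those whose focal
member's midpoint lies in segments carrying a target ancestry label —
e.g. the regions a painting assigned to an unknown ancestor.

## Nei–Gojobori Ks and the molecular clock

`ng86()` implements the 1986 counting method with explicit conventions:

- *Sites.* Per codon position, the fraction of single-nucleotide changes
  that are synonymous, with changes to stop codons removed from both
  numerator and denominator (e.g. AAA scores 1/3 at position 3 and 0 at
  position 1, where TAA is excluded with denominator 2). S and N are
  averaged over the two sequences; S + N = 3 × counted codons exactly.
- *Differences.* Codons differing at d positions are resolved by averaging
  the synonymous/nonsynonymous step counts over all d! orderings of the
  single steps, excluding orderings that pass through a stop codon (if
  every ordering does, all are used — the endpoints themselves are always
  sense codons).
- *Correction.* dS = −(3/4)·ln(1 − 4pS/3). pS ≥ 3/4 cannot be corrected:
  the gene is flagged saturated and excluded from medians rather than
  clamped.
- *Degenerate input.* Codons containing gaps, ambiguity codes, or stops in
  either sequence are skipped pairwise; the genetic code table is
  injectable (standard nuclear by default).

These conventions follow common NG86 practice; exact numerical parity
with any particular legacy implementation is not claimed — parity with an
independently written brute-force enumeration is tested to 1e-12 on 1,000
random alignments.

Divergence time is the molecular clock `T = median Ks / (2 × rate)` with
`rate = 4.5e-9` synonymous substitutions/site/year, the average synonymous
rate estimated in Musaceae. The median (even counts: mean of the central
pair) is robust to the long right tail of per-gene Ks.

## Gene-tree branch support

`branch_support()` computes, for each internal bipartition of a species
tree, the proportion of gene trees containing it, among gene trees where
it is *evaluable*. Comparison is unrooted. For a gene tree covering a
taxon subset, the bipartition is restricted to that subset first; it is
evaluable only when both restricted sides keep ≥ 2 taxa. A restricted
split with a single-taxon side is present in every possible tree, so
counting such gene trees would only dilute the statistic — they are
excluded from the denominator. Polytomies contain none of the resolved
bipartitions they collapse, so they count against support but remain in
the denominator. `placement_support()` reads each gene tree's attachment
of a focal taxon (the bipartition of the remaining taxa induced by its
attachment edge) and tallies it against the branches of the species tree
with the focal taxon removed; attachments matching no candidate — or,
after restriction, several — are reported as `other`, and proportions sum
to 1.

Species and gene trees at desk scale come from Jukes–Cantor distances and
neighbor-joining (`nj_tree()`, exact on additive matrices; internal
branches below 1e-10 are collapsed so an all-zero matrix yields a star).
The support machinery accepts any newick gene trees, including externally
inferred maximum-likelihood trees on real data — the statistic, not the
tree inference, is the contribution here.

## The simulator: what it emulates, and what it does not

The generator exists so every downstream stage can be tested against known
truth without any external data.

- *Ancestral panels* evolve a random root along a rooted tree with branch
  lengths in years under a Jukes–Cantor process at `rate` (default
  4.5e-9/year), so sister tips separated by branches of `b` years diverge
  by 2·b·rate expected substitutions per site. JC is a deliberate
  simplification: clock linearity, not model realism, is what the
  downstream estimators need. Panels get `n_per_group` sequences (default
  2) separated by `within_group_years` (default 1e5, ≈0.1% within-group
  divergence) — enough variation to exercise the frequency filter while
  keeping groups internally homogeneous, as expected for diverged
  subspecies panels. The generative process behind real marker panels is
  not modelled; the simulator is calibrated to be sufficient for tag
  discovery, not to mimic any genotyping protocol.
- *Mosaics* concatenate donor slices taken at homologous (cumulative)
  coordinates, so breakpoints are recombination-like; truth tables tile
  each chromosome exactly.
- *Rearrangements* (inversions, reciprocal translocations) are applied in
  order via an interval block map that tracks every base's provenance;
  forward and inverse coordinate maps compose to the identity, which the
  tests check on random positions.
- *Trios* draw each child haplotype as a parental gamete with Poisson (or
  fixed-position) crossovers and emit per-base phase truth.
- *Codon pairs* for Ks testing evolve two copies of a random sense-codon
  sequence for `t_years` each. Candidate mutations arrive per specific
  single-nucleotide change; stop-creating candidates are rejected and
  synonymous candidates accepted with probability 1/(3 − n_stop), so the
  realised synonymous substitution rate per NG86-counted synonymous site
  (stop-reduced denominator) is exactly `rate`, and nonsynonymous
  candidates are accepted at `nonsyn_rate/rate` (default 0). The residual
  estimator bias — the Jukes–Cantor correction applied to
  two-fold-degenerate sites, which are two-state rather than four-state —
  is on the order of 1–2% at Ks ≈ 0.07, well inside the 5% recovery
  tolerance the tests use.

Not simulated: sequencing reads and error models, indels, coalescent gene
tree heterogeneity, selection beyond stop avoidance, and repeat content.
Passing tests therefore demonstrate correctness of the *computations*
under clean clock-like input, not robustness to assembly error or
alignment noise in real data.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen so
the whole suite runs in about a minute: panels of 20–300 kb, 60-kb mosaics
with 2-kb windows, 500 gene pairs × 300 codons for clock recovery
(Monte-Carlo SE of the recovered time ≈ 1–2.5%), ≤10-taxon trees and 50
gene trees for support oracles. Every generator is a pure function of its
spec and an integer seed; derived stages use fixed seed offsets so adding
one operation never perturbs another's stream. `run_demo_pipeline()` is
hash-stable given its seed.

## Known limitations

- Painting accuracy is bounded by window granularity: each true breakpoint
  contributes up to one `NA` or mislabelled window; very short segments
  (< `min_hits` worth of tags) are absorbed or reported `NA`.
- The >20-genes association rule is a hard threshold; block pairs near the
  boundary flip with small changes in chaining parameters.
- Branch support with heavily overlapping but distinct taxon subsets can
  leave bipartitions with small denominators; the table reports
  `n_evaluable` so users can judge.
- NG86 saturates near Ks ≈ 1; dates beyond ~50 My at the Musaceae rate are
  not meaningful with this estimator.
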