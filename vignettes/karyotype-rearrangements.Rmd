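---
title: "Calling chromosome rearrangements from whole-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromosome rearrangements from whole-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkaryo)
library(dplyr)
```

## The problem

Butterfly chromosomes are holocentric: kinetic activity is distributed along
their length rather than concentrated at a centromere. Fragments of broken
chromosomes therefore keep segregating, and fusion products are not
dicentric, so fusions, fissions and inversions can all reach fixation far
more easily than in monocentric genomes. Comparing chromosome-level
assemblies of related species is the most direct way to build an inventory
of the rearrangements that actually separate their karyotypes.

`synkaryo` implements that comparison as an automated pipeline over pairwise
whole-genome alignments in PAF format:

1. **Filter** alignment blocks by mapping quality and length.
2. **Map homology**: aggregate surviving blocks into a chromosome-by-
   chromosome correspondence matrix and classify its connected components
   as 1:1 synteny, k:1 fusions, 1:k fissions, or complex (translocation
   candidates).
3. **Call inversions** as maximal runs of reversed-orientation blocks
   within each homologous chromosome pair, and classify their positions as
   terminal, subtelomeric or interstitial.
4. **Polarize** events from the three pairwise comparisons of a species
   trio onto the branches of the rooted tree `((B, C), A)`.
5. **Visualize** as dot plots, paired ideograms and circular synteny plots.

A karyotype-evolution **simulator** plants known events along the tree and
emits realistic fragmented alignments, so every stage is testable offline
against ground truth.

## Filtering and its semantics

A syntenic block is one filtered PAF record. The gate keeps blocks with
mapping quality of at least 60 *and* an alignment block length (PAF column
11) of at least 2 kb; thresholds are strict-less for discarding, so blocks
exactly at 60 / 2,000 survive. A mapq of 255 means "unavailable" in the
PAF convention and is treated as missing (discarded whenever any mapq
filtering is requested). Records whose query and target carry the same
chromosome name are rejected outright: the pipeline is strictly pairwise
between two different assemblies. "Length" is the aligner's own per-record
block length rather than the query span, because that is the quantity the
aligner reports for the record as a whole.

## Homology relations

Each filtered block contributes its length to one cell of the
correspondence matrix. Cells are pruned as noise when they fall below
**both** partner thresholds: less than 5% of the larger side's aligned bp
*and* less than 100 kb of absolute support (either criterion alone
suffices to keep a cell). Relations are then the connected components of
the pruned bipartite chromosome graph — deliberately *not*
reciprocal-best-hit, because a k:1 fusion needs all k partners attached to
one target chromosome. Components spanning two or more chromosomes on
both sides are reported as `complex` and never silently split; in clean
lepidopteran data such components are unexpected and the function warns.

The pruning defaults are calibration choices, not measured quantities: the
original analyses of this kind assign homology visually from dot plots.
The defaults were chosen, before any end-to-end validation was frozen, so
that sub-threshold simulator noise cannot fabricate a fusion partner, and
they are arguments on every relevant function.

W chromosomes are excluded from relation building by default. The W is
tiny and repeat-dominated (in the female satyrine karyotype it is roughly
12-fold smaller than the Z), so its alignment signal is mostly spurious; a
flag re-enables it. Fusions touching a Z chromosome are flagged
`involves_Z` and labelled `neo-Z` — a Z-autosome fusion is exactly how a
neo-Z sex chromosome forms.

## Inversions

Assembly strand is arbitrary, so each chromosome pair is first normalized:
if '-' blocks carry the majority of aligned bp the query coordinates are
mirrored and strands toggled (ties resolve to no flip; mirroring twice is
the identity). An inversion is then a maximal run of consecutive '-'
blocks in target order — the anti-diagonal of a dot plot read left to
right — merged across empty gaps of at most `max_gap`, and reported when
it has at least `min_blocks = 3` blocks and spans at least
`min_span = 50` kb. Only maximal runs are reported (no recursive
segmentation of nested inversions), and sub-threshold minority runs are
tallied as micro-rearrangements rather than called.

Positions are classified by the distance of the call from the nearer
chromosome end as a fraction of chromosome length: below 2% `terminal`,
below 15% `subtelomeric`, otherwise `interstitial`. Classical cytogenetics
distinguishes these positions qualitatively but offers no quantitative
definition, so the two cutoffs are explicit, documented artifact decisions
and both are arguments.

Collinearity is scored as the fraction of aligned bp on the heaviest chain
of blocks strictly increasing in both coordinates — a block-length-weighted
longest increasing subsequence, computed in O(n log n) with a Fenwick tree
over prefix maxima (the test suite checks it against an independent O(n²)
dynamic program).

## Polarizing events on a trio

With three species and the rooted topology `((B, C), A)`, a single fixed
rearrangement is visible in exactly the two pairwise comparisons whose
path crosses its branch:

| present in A–B | present in A–C | present in B–C | placement |
|---|---|---|---|
| no  | yes | yes | branch C, fixed |
| yes | no  | yes | branch B, fixed |
| yes | yes | no  | A-side path, fixed |
| any other pattern | | | unresolved, inconsistent |

Without an outgroup, the third pattern cannot distinguish the A terminal
branch from the internal stem, so the package reports a single
`<A>_or_stem` category rather than guessing. Presence in all three
comparisons cannot be produced by one event on a three-taxon tree and is
flagged inconsistent (recurrent events, polymorphic inversions lost in one
lineage, or mismatched calls all produce such patterns). Real data do show
such cases: an inversion seen in only one comparison is exactly the
signature of a rearrangement that is not yet fixed in all populations —
which is why these calls are surfaced rather than suppressed.

Calls are matched across comparisons through the species the two
comparisons share: inversions by reciprocal overlap (default 0.5) on the
shared genome's coordinates, fusions and fissions by identity of their
chromosome member sets on the shared species (they are whole-chromosome
events, so coordinates are not the right key). Matching is transitive; a
call that would join two distinct events of one comparison raises an
ambiguity error rather than picking a side.

## The simulator

`simulate_tree()` evolves an ancestral karyotype of `ancestor_n = 29`
chromosomes (28 autosomes and one Z — the ancestral satyrine complement)
along `((ligea, aethiops), jurtina)`. The default preset plants:

* on the **internal path** (stem): nine inversions — eight autosomal and
  one interstitial Z inversion, in a subtelomeric/interstitial mix;
* on the **aethiops branch**: one terminal Z inversion, nine simple
  autosomal fusions, and one Z-autosome fusion producing a neo-Z —
  yielding an extant n = 19 against n = 29 in the other two species.

The nine shared inversions are placed on the stem rather than the jurtina
terminal branch: the two placements are indistinguishable from pairwise
comparisons alone (the `jurtina_or_stem` category above), and the stem
placement makes them shared by both *Erebia* lineages, which is the
observed pattern.

Numerical choices, all fixed while the generator was designed:

* **Genome scale.** Default chromosomes are 0.7–1.4 Mb, about 1/16 of the
  real 402–506 Mb satyrine assemblies, so a full trio simulation plus all
  three comparisons runs in under two seconds; `full_scale = TRUE`
  switches to 8–25 Mb chromosomes. The ancestral Z is drawn at the top of
  the size range: the lepidopteran Z is typically among the largest
  chromosomes, and a large Z also guarantees that the two Z inversions the
  preset stacks on one lineage remain a strict bp minority, keeping
  majority-vote strand normalization well defined.
* **Blocks.** Homologous segments are tiled with blocks of 2–52 kb (the
  range seen in real filtered alignments of these species) separated by
  unaligned gaps of at most 8 kb, emulating micro-indel divergence without
  modelling indels explicitly. True blocks get mapq 60; configurable noise
  adds low-mapq blocks, sub-2-kb blocks, and spurious well-mapped blocks
  on random chromosome pairs.
* **Inversion spans** default to 150–250 kb. With 2–52 kb blocks this
  guarantees at least three blocks per planted inversion (two blocks can
  cover at most 104 kb), so caller recall cannot depend on tiling luck.
* **Placement classes** are drawable by name and kept in disjoint
  chromosome regions (terminal flush right, subtelomeric on the left
  flank, interstitial in the middle away from the terminal region), so two
  events on the same chromosome can never overlap.
* **Fusion junction orientation** is random (head-head or head-tail) and
  logged; each chromosome and each event product takes part in at most one
  event per branch, so fusions stay simple two-partner events.

Every event is recorded in a ground-truth log whose replay on the ancestor
reproduces the extant coordinate maps exactly; fusions, fissions and
inversions are all length-preserving, so total genome length is conserved
along every lineage. Optionally the simulator emits genome sequences
(random fixed-GC content — the callers only ever see coordinates), which
lets the coordinate maps be verified at base level.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: repeat landscapes and alignment artifacts around
them, W chromosome content, base-level mutation, genuine micro-indels,
segmental duplications, and assembly errors. The simulator's noise model
is uncorrelated with genome position, whereas real mis-mappings cluster in
repeats. Results on real alignments therefore still warrant visual
inspection of the dot plots, which the plotting functions are designed to
support.

## A worked example

```{r example}
sim <- simulate_tree(sim_config(seed = 1))
sim

trio <- analyze_trio(sim)
trio

glance(trio$comparisons$bc)          # ligea ~ aethiops
head(tidy(trio))                     # per-event branch placements
```

Plots mirror the three standard figure families:

```{r plots, fig.width=7, fig.height=5, eval=FALSE}
bc <- trio$comparisons$bc
autoplot(bc)                                        # dot plot
plot_ideogram(bc$query_karyotype, bc$target_karyotype,
              bc$blocks, bc$relations, highlight = bc$inversions)
plot_circos(bc$blocks, bc$query_karyotype, bc$target_karyotype)
```

All renderers are pure functions of their inputs up to the image encoder;
tests assert on the intermediate plot-data structures (`dotplot_data()`,
`ideogram_data()`, `circos_data()`), never on pixels, because image-library
output is platform-dependent.

## Problem sizes and limitations

The test suite validates the full pipeline across 20 simulation seeds at
the default scaled-down genome (~30 Mb per genome, ~1,000 blocks per
pair), plus several hundred randomized oracle comparisons per caller; the
whole run takes well under a minute. Known limitations:

* Breakpoints are block-resolution, not base-resolution.
* Micro-rearrangements below the partner or span thresholds are tallied
  but not called.
* The polarizer is exact for three taxa only; more taxa need genuine
  ancestral-state reconstruction, which is out of scope.
* One documented ambiguity is inherent to the design: without an outgroup,
  events on the internal path cannot be assigned to the stem versus the
  outgroup-side terminal branch, and the package does not pretend
  otherwise.
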