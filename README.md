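# synkaryo

Comparative synteny and karyotype-rearrangement analysis for holocentric
genomes, in R.

Holocentric chromosomes — standard in Lepidoptera — lack a localized
centromere, so chromosome fusions, fissions and inversions can all reach
fixation: fragments keep their kinetic activity and fusion products are not
dicentric. Comparing chromosome-level assemblies of related species is the
direct way to inventory the rearrangements that separate their karyotypes.
`synkaryo` turns that comparison into an automated, tested pipeline over
pairwise whole-genome alignments in PAF format:

* **`read_paf()` / `filter_blocks()`** — parse alignments and keep syntenic
  blocks with mapq ≥ 60 and block length ≥ 2 kb (thresholds strict-less
  for discarding; mapq 255 treated as missing).
* **`build_correspondence()` / `classify_relations()`** — aggregate blocks
  into a chromosome correspondence matrix and classify its connected
  components as `one_to_one` synteny, k:1 `fusion`, 1:k `fission` or
  `complex` (translocation candidates, never silently split).
* **`detect_neo_sex()`** — flag fusions involving the Z: a Z–autosome
  fusion is how a neo-Z sex chromosome forms.
* **`normalize_orientation()` / `call_inversions()`** — canonicalize strand
  polarity per chromosome pair, then call inversions as maximal runs of
  reversed-orientation blocks (≥ 3 blocks, ≥ 50 kb by default) and
  classify them as terminal / subtelomeric / interstitial.
  `collinearity_report()` scores each pair by a block-length-weighted
  longest increasing subsequence.
* **`match_events_across_pairs()` / `polarize_events()`** — reconcile calls
  from the three pairwise comparisons of a species trio onto the rooted
  tree `((B, C), A)`. A single fixed event is visible in exactly the two
  comparisons crossing its branch: pattern (0,1,1) → branch C, (1,0,1) →
  branch B, (1,1,0) → the A-side path (terminal branch or stem —
  indistinguishable without an outgroup, so reported as one category);
  every other pattern is flagged `inconsistent` (e.g. a polymorphic
  inversion not yet fixed in all lineages).
* **`simulate_tree()` / `sim_paf()`** — a karyotype-evolution simulator
  that plants fusions, fissions, inversions and a Z–autosome fusion along
  the tree, tracks base-exact coordinate maps and ground-truth logs, and
  emits realistic fragmented alignments (2–52 kb blocks, optional noise),
  so the entire pipeline is verifiable offline.
* **`plot_dotplot()` / `plot_ideogram()` / `plot_circos()`** — the three
  standard figure families, all backed by testable plot-data functions.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on result objects, `autoplot()` for comparisons.

## Worked example

Simulate the default scenario — an ancestral satyrine-like karyotype of
n = 29 (28 autosomes + Z) evolved along `((ligea, aethiops), jurtina)`
with nine inversions on the internal path and, on the aethiops branch,
nine autosomal fusions, one Z–autosome fusion and one terminal Z
inversion — then run all three pairwise comparisons and polarize:

```r
library(synkaryo)

sim <- simulate_tree(sim_config(seed = 1))
sim
#> <karyo_sim> seed 1
#>   ancestor: n = 29
#>   jurtina: n = 29, 31 Mb
#>   ligea: n = 29, 31 Mb
#>   aethiops: n = 19, 31 Mb
#>   events: 20

trio <- analyze_trio(sim)
trio
#> <trio_analysis> jurtina / ligea / aethiops
#>   aethiops: 10 fusion, 1 inversion
#>   jurtina_or_stem: 9 inversion

glance(trio$comparisons$bc)   # ligea ~ aethiops
#> # A tibble: 1 × 10
#>   n_blocks aligned_bp max_block_length n_one_to_one n_fusion n_fission n_complex
#>      <int>      <dbl>            <dbl>        <int>    <int>     <int>     <int>
#> 1     1009   26943624            51960            9       10         0         0
#>   n_inversions n_neo_z median_monotone_fraction
#> 1            1       1                        1
```

The ligea–aethiops comparison recovers all ten fusions, including the
neo-Z, with full support:

```r
tidy(trio$comparisons$bc)
#> # A tibble: 19 × 5
#>    query             target      kind       support_bp support_fraction
#>  1 ligea_1+ligea_11  aethiops_1  fusion        2227850                1
#>  2 ligea_18+ligea_2  aethiops_2  fusion        2020397                1
#>  4 ligea_22+ligea_Z  aethiops_Z  fusion        1981278                1
#>  ...
#> 11 ligea_4           aethiops_10 one_to_one    1151447                1
```

`support_fraction` is the share of the involved chromosomes' aligned bp
explained by the relation; the single `n_inversions` in this pair is the
planted terminal Z inversion, and `n_one_to_one = 9` are the autosomes the
fusion wave left untouched. Event placements
(`tidy(trio)`) assign all ten fusions to the aethiops branch and all nine
shared inversions to the internal path, with zero inconsistent events.

For real data, replace the simulated inputs with files:

```r
blocks <- read_paf("ligea_vs_aethiops.paf")
kq <- load_karyotype("ligea.fa.fai", sex_labels = c(Z = "Z"), species = "ligea")
kt <- load_karyotype("aethiops.fa.fai", sex_labels = c(Z = "Z"), species = "aethiops")
cmp <- compare_pair(blocks, kq, kt)
autoplot(cmp)   # dot plot with inversion annotations
```

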