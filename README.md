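# plasmidlead

Orientation and leading-region analysis of conjugative elements:
positional anti-defence gene enrichment, anti-defence islands and
ssDNA (Frpo/ssi) promoter detection.

## The problem

When a conjugative plasmid transfers, the relaxase nicks the origin of
transfer (oriT) and a single strand enters the recipient 5′-end first.
The side of the oriT opposite the relaxase — the **leading region** —
arrives first and is exposed, as single-stranded DNA, to the recipient's
defence systems before the plasmid is established. `plasmidlead` is for
researchers studying plasmid biology and host–MGE conflict who want to
ask, on their own contigs: *are anti-defence genes (anti-CRISPRs,
anti-restriction proteins, SOS inhibitors) concentrated at the first
transferred ORF positions, oriented for expression from the transferred
strand, clustered into islands, and equipped with single-strand
promoters?*

## What it computes

Given per-contig gene annotations (GFF3/TSV), relaxase/TraM and oriT
homology hits (HMMER tblout / BLAST outfmt 6; a built-in word-size-5
seeded aligner can replace the external oriT search), an ORF
cluster membership and a profile→category map, the pipeline:

1. **Orients contigs** at the best-scoring oriT, rejecting contigs where
   the geometry is ill-defined (>2 relaxase/TraM hits, relaxase–oriT
   distance > 3,500 bp, oriT inside the relaxase, edge placement), and
   indexes ORFs relative to the oriT: position 0 is the first leading
   ORF, negative positions are lagging. Each ORF gets a
   **T-strand-expressibility** flag: can the entering single strand
   template its transcription?
2. **Deduplicates** contigs sharing > 90% of their ORFs (by cluster
   membership), keeping the larger element.
3. **Tests enrichment** per position (one-sided Fisher exact test of the
   anti-defence count at a position versus all other positions pooled,
   positions with ≥ 50 ORFs, BH-FDR α = 0.001) and per gene family
   (concentration in the first 28 leading ORFs), with five-ORF windowed
   frequency curves, family orientation votes and majority annotations.
4. **Delineates anti-defence islands**: maximal runs of anti-defence /
   MTase / SSB / toxin–antitoxin genes in the leading region, bounded by
   the oriT and often terminated by a umu-like operon.
5. **Scans for Frpo/ssi ssDNA promoters** in 50–350 bp leading-region
   intergenic spans: homology to known elements, σ70 consensus search
   (−35 `TTGACA`, −10 `TATAAT`, 15–19 nt spacer, AT-rich UP element) and
   hairpin evidence from base-pair maximization, classified into tiers
   Frpo / Frpo′ / Frpo\*\*.
6. **Simulates** fully synthetic fixtures with planted ground truth for
   every stage (`simulate_contigs()`, `simulate_null()`), which is how
   the statistical guarantees of the pipeline are tested.

The model and every default threshold are documented in the methods
vignette (`vignettes/leading-region-analysis.Rmd`).

## Worked example

Simulate a 60-contig cohort with planted leading-region enrichment
(anti-defence frequency 0.20 at positions 0–9 vs 0.01 elsewhere),
islands and Frpo elements, then run the full pipeline at the reference
parameterisation:

```r
library(plasmidlead)
library(dplyr)

sim <- simulate_contigs(sim_config(
  n_contigs = 60, genes_per_contig = c(20, 30), seed = 101,
  island_prob = 0.4, frpo_prob = 0.4,
  duplicate_groups = list(k = 2, copies = 2, mutation_rate = 0)))
res <- run_pipeline(sim, run_config())

glance(res$enrichment)
#> # A tibble: 1 × 5
#>   n_positions n_tested n_significant alpha min_orfs
#>         <int>    <int>         <int> <dbl>    <int>
#> 1          34       80             5 0.001       50

res$enrichment |>
  filter(category == "anti_defence", significant) |>
  select(relative_position, n, n_total, f_w, q_value)
#> # A tibble: 4 × 5
#>   relative_position     n n_total   f_w      q_value
#>               <int> <int>   <int> <dbl>        <dbl>
#> 1                 0    18      60 0.2   0.0000276
#> 2                 1    22      60 0.23  0.0000000906
#> 3                 2    20      60 0.267 0.00000161
#> 4                 7    16      60 0.197 0.000381
```

Positions 0–2 and 7 of the leading region are significantly enriched:
e.g. at position 1, 22 of the 60 ORFs are anti-defence genes (windowed
frequency 0.23) against a genome-wide background near 5%, q ≈ 9e-8.
The two planted duplicate contigs are removed before testing
(`glance(res$dedup)` reports 60 representatives, 2 removed), and the
island and promoter stages report:

```r
as_tibble(res$islands) |> select(-members) |> head(3)
#> # A tibble: 3 × 7
#>   contig_id start_position end_position n_members boundary_start boundary_end
#>   <chr>              <int>        <int>     <int> <chr>          <chr>
#> 1 ctg0002                0            2         3 oriT           umu_like_operon
#> 2 ctg0003                0            4         5 oriT           umu_like_operon
#> 3 ctg0006                0            2         3 oriT           umu_like_operon

count(res$frpo, tier)
#> # A tibble: 3 × 2
#>   tier           n
#>   <chr>      <int>
#> 1 frpo_prime    24
#> 2 frpo_star     11
#> 3 none         692
```

Islands sit against the oriT and end at umu-like operons, as expected
from the planted architecture; 24 of the planted Frpo-like elements are
recovered at the Frpo′ tier across ~730 scanned regulatory regions.
`plot_position_frequency(res$enrichment)` draws the frequency-by-position
curves with significant positions marked, and `plot_island_map()` draws
a per-contig gene map.

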