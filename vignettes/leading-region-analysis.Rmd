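---
title: "Orienting conjugative elements and quantifying anti-defence enrichment in leading regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orienting conjugative elements and quantifying anti-defence enrichment in leading regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidlead)
library(dplyr)
```

## The biological question and the model

During bacterial conjugation a relaxase nicks the plasmid at the origin of
transfer (oriT) and a single strand (the T-strand) enters the recipient
5'-end first. The portion of the plasmid on the far side of the oriT from
the relaxase — the *leading region* — therefore arrives first, while the
relaxase gene itself arrives last (the *lagging region*). If genes that
neutralise host defences (anti-CRISPRs, anti-restriction proteins, SOS
inhibitors) are preferentially encoded in the leading region and oriented
so that the incoming single strand can act as a transcription template,
they can act before the host destroys the incoming DNA. `plasmidlead`
implements the computational machinery needed to test this positional
hypothesis on assembled contigs:

1. **Geometry**: anchor each contig at its oriT, infer the leading
   direction from the relaxase position, and index ORFs relative to the
   oriT (0 = first leading ORF, negative = lagging).
2. **Enrichment**: per-position and per-gene-family one-sided Fisher
   exact tests with Benjamini–Hochberg FDR control.
3. **Islands**: delineate clustered runs of anti-defence and
   DNA-protecting genes bounded by the oriT and, frequently, a umu-like
   (DNA polymerase V homologue) operon.
4. **ssDNA promoters**: detect Frpo/ssi-like elements in leading-region
   intergenic DNA by homology and by sigma-70 consensus plus hairpin
   (dsDNA-mimicry) evidence.
5. **Simulation**: generate fully specified synthetic fixtures with
   planted ground truth for every stage, so each statistical property of
   the pipeline is testable end to end.

## Geometry: from hits to oriT-relative coordinates

A contig enters the analysis with a gene table, protein-level
relaxase/TraM hits and nucleotide-level oriT hits (e-value threshold
1e-6 at ingest). Contig-level quality filters make the orientation well
defined: more than two relaxase/TraM hits, a relaxase–oriT nucleotide
distance above 3,500 bp, an oriT entirely inside the relaxase gene, or a
relaxase/oriT at the first or last annotated position all reject the
contig, each with a machine-readable reason. An oriT partially
overlapping the relaxase is retained. With several oriT hits the
best-scoring one is used (ties: lowest e-value, leftmost, then query id).

The nic position inside the oriT is generally unknown, so the oriT
midpoint anchors the coordinate system; only the relative order of ORFs
matters downstream. The leading side is the side opposite the relaxase
(sign of oriT midpoint minus relaxase midpoint), gene side is decided by
the gene midpoint (robust to genes straddling the oriT; a midpoint
exactly on the anchor counts as leading), and positions run 0, 1, 2, …
outward on the leading side and −1, −2, … on the lagging side. Under the
default `"toward_oriT"` convention a gene is *T-strand expressible* when
its transcription direction opposes the leading direction, i.e. the
transferred strand (5' end at the nic) can template its transcription.
The operational strand test is not uniquely fixed by first principles,
so the opposite convention is available in the configuration. Both
relative positions and expressibility flags are invariant under reverse
complementing a contig — a property the test suite checks on every
simulated fixture. Contigs are treated as linear assembly fragments.

```{r geometry-demo}
sim <- simulate_contigs(sim_config(n_contigs = 4,
                                   genes_per_contig = c(12, 16),
                                   seed = 7))
qc <- qc_filter_contigs(sim$genes, sim$hits$relaxase, sim$hits$orit)
geometry <- assign_relative_positions(sim$genes, qc)
head(select(geometry, contig_id, gene_id, relative_position,
            t_strand_expressible), 8)
```

## Deduplication

Redundant contigs inflate positional counts. Following standard
practice, ORFs are clustered externally (CD-HIT/MMseqs2-style membership
tables are consumed, and the simulator emits truth memberships); two
contigs sharing strictly more than 90% of their ORFs collapse to the one
with more ORFs. Three choices the membership data do not dictate are
fixed as follows: the shared fraction uses the *smaller* contig as the
denominator, so containment of a sub-plasmid triggers removal; the
intersection is a *multiset* intersection, so duplicated genes count per
copy (plasmids frequently carry gene duplicates); and the greedy sweep
visits contigs by decreasing ORF count with a lexicographic tie-break,
which makes the representative set deterministic, permutation-invariant
and idempotent.

## Enrichment statistics

Per position, the category count is compared against the pooled counts
of all other positions with an upper-tail hypergeometric (one-sided
Fisher) test. Note that the 2×2 built from a position versus the pooled
complement has exactly the same margins as drawing the position's ORFs
from the grand totals, so the "pooled complement" and "global totals"
readings of the test coincide; there is consequently one implementation
and no configuration switch. Only positions carrying at least 50 ORFs
are tested, and BH-FDR is applied across tested positions at
alpha = 0.001; the combined anti-defence class (anti-CRISPR +
anti-restriction + SOS inhibition) and each constituent category are
tested separately. Reported frequency curves use a five-ORF centred
window truncated at the index range edges. The display rule of at least
500 sequences per position is a report-layer filter
(`report_positions()`) and never affects testing.

Gene families (a second, coarser clustering) are tested for
concentration in the first 28 leading ORFs (internal indices 0–27; the
same ORFs are sometimes numbered 1–28, and the two conventions are
treated as identical here) by the same one-sided test with BH-FDR across
families. A family's orientation is the majority vote of its members'
T-strand expressibility (exact ties are reported as ties), and its
annotation the modal member annotation with a lexicographic tie-break.

`fisher_one_sided()` delegates to `stats::phyper()` (exact in
log-space); the test suite verifies it against a direct log-binomial
tail summation for every 2×2 table with a population of 200 or fewer,
to an absolute tolerance of 1e-9, and verifies `bh_fdr()` (built on
`stats::p.adjust`) against a naive step-up implementation on 1,000
random p-vectors.

## Anti-defence islands

Islands are formalised as maximal runs of island-qualifying genes
(anti-defence plus orphan MTases, SSBs and toxin–antitoxin systems)
starting within leading positions 0–27, tolerating at most `max_gap = 2`
consecutive non-qualifying genes inside, terminated by a umu-like gene
(which marks the distal boundary as a umu-like operon), and requiring at
least `min_members = 3` qualifying genes. The proximal boundary is
always the oriT. These run/gap constants are this package's
formalisation of a qualitative pattern — the literature describes island
composition and boundaries but no count rule — so they are configuration
parameters, and correctness is defined against a brute-force window
oracle in the tests rather than against the biology. Islands may extend
past position 27 when qualifying genes continue; such islands are
flagged. A transposase splitting two runs yields two islands.

## Frpo/ssi single-strand promoter scan

Regulatory regions are the strand-aware intergenic spans upstream of
leading-region genes, kept when 50–350 bp long. Three evidence channels
feed the tier call:

* **Homology** to a set of known Frpo/ssi sequences, using the built-in
  seeded aligner (word size 5, match +1, mismatch −3, gap open 5 and
  extend 2 as costs — the standard short-query parameterisation). Hits
  are filtered on raw score (default ≥ 20, roughly a 20-nt exact match)
  rather than an e-value model: Karlin–Altschul calibration is out of
  scope, and a deterministic score threshold is exactly testable.
  External blast6 tables can be supplied instead at any point.
* **Consensus elements**: every placement pair of the −35 (`TTGACA`) and
  −10 (`TATAAT`) hexamers with at most 2 mismatches each and a 15–19 nt
  spacer; the AT fraction over the 20 nt upstream of the −35 is reported
  as UP-element evidence (AT-rich ≥ 0.75 is flagged but not required
  for a tier).
* **Hairpin (dsDNA mimicry)**: the region is folded by deterministic
  base-pair maximization (Watson–Crick plus G:T wobble, minimum hairpin
  loop 3, deterministic traceback). This is a combinatorial stand-in
  for thermodynamic folding: it measures how much of the element can be
  locked into a duplex, which is the property that lets an ssDNA
  promoter mimic double-stranded DNA. A dot-bracket structure from an
  external thermodynamic folder can be plugged in through
  `structure_from_dotbracket()`.

The stem flag requires both (i) at least half of the twelve element
nucleotides paired and (ii) a contiguous helix of at least `min_stem`
stacked pairs touching the elements. The helix requirement matters:
on ~160 nt sequences, maximal-pairing structures of random DNA pair
well over half of all positions, and a hexamer pair within the mismatch
budgets arises by chance in roughly half of shuffled controls, so paired
fraction alone would accept a large share of nulls. `min_stem` was
calibrated once on dinucleotide-shuffled planted elements before the
test suite was frozen: planted elements carry engineered ~50 bp stems
and are recovered at 100% for any threshold up to 12, while
element-touching helices in shuffled controls almost never exceed 8
stacked pairs; the default is 10, at which 2% of shuffled controls
retain a stem call.

Tiers follow the three-level similarity scheme: `frpo` (homology hit to
a known element), `frpo_prime` (no homology; total element mismatches
≤ 2 plus stem evidence), `frpo_star` (total mismatches ≤ 4 plus stem;
low-certainty), else `none`. The mismatch budgets and spacer bounds are
operational definitions — the similarity tiers are described
qualitatively in the literature — and all are configuration-exposed.

## The synthetic-data generator

`simulate_contigs()` emits gene tables, hit tables (HMMER-tblout-style
for proteins, blast6-style for the oriT), a dedup membership, a family
table, MOB-type metadata, optional contig sequences, and a truth table
that the test suite cross-checks against every emitted file. Each contig
carries exactly one relaxase ORF adjacent (≤ 3,500 bp) to one oriT
copied (with 5% substitutions by default) from a bundled synthetic
stand-in query set; the real oriT databases are external resources and
are not shipped. Category labels are drawn per position group — by
default 0.20 anti-defence frequency at leading positions 0–9 versus
0.01 elsewhere, the planted-signal regime the statistical tests are
exercised under — and anti-defence genes are placed in the
T-strand-expressible orientation with probability 1 by default.
Optional extras plant anti-defence islands terminated by two umu-like
genes, redundant contig groups (the dedup truth), and Frpo-like elements
in leading intergenic gaps. Intergenic background sequence is i.i.d.
uniform A/C/G/T: the statistics under test do not depend on realistic
sequence composition, and planted signals are explicit.

What the generator does *not* emulate — phylogenetic structure, real
MOB-type biology, codon structure, assembly error — bounds what green
tests mean: they certify the statistical and geometric machinery under
the stated model, not performance on real metagenomes.

`simulate_null()` removes all positional structure (identical category
frequency at every position, no islands, duplicates or promoters) and
is the type-I-error harness: across twenty 2,000-contig replicates at
alpha = 0.001, at least nineteen must flag zero positions.

## Problem sizes and numerical choices

The bundled analyses use these scales, chosen to make every property
measurable while keeping a full run of the suite and the acceptance
script comfortably interactive: positional-recovery studies use 1,000
contigs of 60–80 ORFs; null replicates 2,000 contigs × 20 seeds (5 in
the acceptance script, which also re-runs the planted study);
duplicate-group fixtures 50 contigs; aligner admissibility 200 planted
queries (50 in the script); folding verification covers all structures
of 200 random sequences up to length 14; the end-to-end demo uses 60
contigs. Exact DP is used wherever feasible (`local_align_oracle()`
caps at 1e6 cells, `max_basepairs()` at 400 nt) and every tie in every
selection rule (oriT choice, category conflicts, dedup order, modal
annotation, folding traceback) is broken deterministically, which is
what makes byte-identical reruns possible.

## Known limitations

* The oriT midpoint is a proxy for the nic site; ORF indices are
  insensitive to this, but the position-0 tie rule at the midpoint is a
  convention.
* Base-pair maximization overestimates pairing relative to a
  thermodynamic model; the stem-helix requirement compensates, and the
  dot-bracket hook allows an external folder.
* The aligner reports raw scores, not e-values; thresholds are exact
  but not corrected for search-space size.
* MOB typing is consumed as metadata, never inferred.
* Circular replicons are handled as linear fragments.
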