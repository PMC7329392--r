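---
title: "Mining Kex2-processed repeat proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Kex2-processed repeat proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kepmine)
```

## The biological problem

Fungi secrete peptides cut out of larger precursor proteins.  One
recurring precursor architecture — seen in the ustiloxin and phomopsin
RiPP pathways, in yeast alpha-mating factors and in several fungal
effectors — couples an endoplasmic-reticulum signal peptide with a run of
short, mutually similar peptide units separated by dibasic motifs (KR,
KK, RK, RR) that the Golgi protease Kex2 cleaves.  Proteins of this shape
are called KEPs (Kex2-processed repeat proteins).  Cyclized products of
such precursors additionally require a neighbouring gene encoding a
DUF3328-domain protein (Pfam PF11807), so the gene neighbourhood of a KEP
carries functional information: pheromone-like KEPs lack the cyclization
factor, toxin-like ones tend to have it nearby.

`kepmine` implements the complete desk-scale analysis: detection of KEPs
from protein sequences, typing by reciprocal similarity, repeat-unit
sub-typing and profiling, gene-neighbourhood statistics for DUF3328 and
Tyrosinase genes, pheromone/mating-factor annotation, and census tables —
plus a synthetic-data generator that plants all of this structure with
exact ground truth, so every stage is testable without downloading
genomes.

## Detection

### Signal peptide gate

Real analyses should supply SignalP output (`read_signalp()`).  For
self-contained runs, `predict_signal()` applies a fixed rule triple
mirroring the tripartite signal-peptide architecture within the first 45
residues: a K/R in positions 1–6 (n-region charge), a run of at least 8
hydrophobic residues (A, C, F, I, L, M, V, W) starting in positions 2–15
(h-region), and a small-residue motif `[AGSTC]-x-[AGSTC]` whose last
position, at least two past the hydrophobic run, is the cleavage site
(c-region); the smallest qualifying position wins.  These rules are not a
SignalP re-implementation and make no claim of fidelity on real
sequences; they exist so that the generator and the gate agree exactly,
which the tests verify in both directions.  Real-data fidelity is
delegated entirely to the file-input path.

### Seed-sliding identity voting

Repeated positions in the mature sequence are found by self-comparison.
Every window of `seed_length` residues (default 40) is a *seed*.  Each
seed is slid gaplessly across the whole mature sequence — every offset
with at least one overlapping residue, excluding the seed's own source
placement, partial overlap allowed with unmatched overhang scoring
nothing — and its *best* placement is the one with the most identical
aligned residues (smallest placement start on ties; the unknown residue X
never matches anything, including another X).  The seed then votes for
each of its own residues that matched at that best placement.  A
position's score is its votes divided by the number of seed windows
covering it, so scores lie in [0, 1] and read as "the fraction of local
contexts whose best self-alignment confirms this residue as repeated".
Positions with score above `repeat_threshold` (default 0.6) are called
repeated.

Two numerical details matter:

* **Seed length adapts to short sequences.**  A window can only attest
  repetition it can contain, so for a mature length $L$ the working seed
  length is $\min(40, \max(8, \lfloor L/3 \rfloor))$.  Without this, the
  smallest admissible KEP (three 8-residue units, spanning about 30
  residues) dilutes every 40-residue window with flanking sequence and
  scores hover uselessly at the threshold.
* **The mask is contiguity-filtered.**  Overlapping seeds choose
  correlated best placements, so in non-repetitive sequence the residues
  that happen to match at a locally dominant lag get high scores — but
  sparsely, while true repeats produce dense runs.  The working mask
  therefore thresholds a centred running mean of the scores (window 5,
  truncated at the ends) and discards masked runs shorter than 5
  positions.  Point substitutions inside repeat units sit between
  score-1 neighbours and are bridged; isolated spurious matches are
  eliminated.  The raw `score > threshold` mask is kept on the track for
  inspection (`tidy()`, `autoplot()`).

The optimized scorer runs in $O(L^2)$ time via per-lag prefix sums and is
vote-for-vote identical to the direct per-seed, per-placement definition;
the test suite checks this against a brute-force oracle on hundreds of
random and tandem-array sequences.

A protein counts as *tandem-repetitive* when the mask splits the mature
sequence into more than 2 alternating blocks.  A consequence worth
stating: a sequence that is repeats from end to end forms a single block
and does not qualify — the rule presumes the flanking pro-regions that
natural precursors carry.

### Kex2 processing and the acceptance filter

Dibasic sites are scanned left to right, non-overlapping and
leftmost-greedy (after `...KRR...` the scan resumes after the KR), and
site residues are excluded from fragments.  A fragment is a repeat unit
when at least `masked_fraction` (default 0.5) of its positions are masked
and its length is within 8–100 residues.  The staged filter assigns each
rejected protein the first failing stage: `NO_SIGNAL`, `TOO_SHORT`
(mature under 16 residues), `NOT_REPETITIVE`, `NO_KEX2_SITE`,
`FRAGMENT_TOO_LONG` (any fragment over 100 residues, not only repeat
units — the exclusion describes whole proteins), then `UNITS_TOO_SHORT` /
`TOO_FEW_UNITS` (fewer than 3 units of at least 8 residues; the former
when enough fragments pass the masked-fraction rule but are too short).

## Typing and profiles

Two KEPs belong to one type when reciprocal E-values are below 1e-30 with
each sequence covered above 70%; types are single-linkage components,
labelled `#1`, `#2`, … by decreasing member count (ties broken by the
lexicographically smallest member id, so labels are permutation-stable)
with stand-alone KEPs labelled `"0"`.  Within a type, repeat units group
into sub-types at identity > 65% and coverage > 70%; sub-types with at
most 2 members are flagged small.  Alignment is Smith–Waterman
(BLOSUM62, gap open 11 / extend 1, a length-$k$ gap costing $11 + k$) via
`Biostrings`; E-values use the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the standard gapped constants
$\lambda = 0.267$, $K = 0.041$, and $n$ equal to the total residue count
of the search set in database mode.  These constants are config-exposed;
the decision thresholds (1e-30, 1e-10) are so extreme that modest
constant error does not flip them.  Identity is counted over aligned
columns (gaps are columns, X never matches), and "coverage" means the
query's aligned span over its full length, required in *both* directions
— the only reading under which reciprocal search adds information.
Composition-based score adjustment and low-complexity filtering are not
emulated; this is a known fidelity gap relative to BLAST-based numbers.

Sub-type profiles use center-star alignment: the member with the highest
summed pairwise score is the center, all others are aligned to it
globally, and member insertions open gaps in the center.  Per-column
residue frequencies get a pseudocount of 0.05 per residue, keeping unseen
residues representable while barely moving observed frequencies.  This
replaces external MSA/profile-HMM tooling deliberately: the downstream
uses (consensus motifs, composition rates) need only the frequency
matrix, and the package stays free of binary dependencies.

## Gene neighbourhood

Distance between genes is the difference of their start-order ranks on
the same contig (adjacent = 1), strand ignored, undefined across contigs
— the analysis counts genes, not base pairs.  The window is `radius`
(default 15) genes on *each* side, truncated at contig ends.  Two
summary statistics are emitted because published "average distance"
figures can be read either way: `nearest_mean` averages each KEP's
nearest labelled gene (over KEPs with a hit), and `allhits_mean` averages
all hits up to `allhits_max_dist` (default 10).  Conditional histograms
stratify KEPs by presence of a conditioning label (e.g. Tyrosinase
counts given DUF3328 presence), and the strata reconstruct the
unconditional counts exactly.

## Census conventions

Per-phylum means of KEPs per strain divide the total KEP count by *all
surveyed strains*, zero-KEP strains included, and the sample SD is taken
over the same per-strain counts — this is the arithmetic that reproduces
a published two-strain phylum with counts {5, 7} printing mean 6.00 and
SD 1.41, as well as the totals-row mean.  With a single strain the SD is
reported as 0.

## The synthetic generator

`simulate_kep_study()` plants every structure the pipeline measures:

* **Precursor architecture**: signal peptide (constructed to the
  heuristic's rules with a known cleavage position) + a non-repeated
  leader pro-region of 25–40 residues + a dibasic site + (unit + site)
  × k + a 5–10 residue tail.  The flanks exist because the ">2 parts"
  rule requires non-repeated blocks around the repeat array; the leader
  length was sized so that members of even the smallest legal family
  (3 × 8-residue units) share enough aligned, near-identical sequence
  (signal + leader + tail are family-level) for reciprocal E-values to
  clear 1e-30 at 5% unit mutation with margin.
* **Families**: each of `n_families` ancestors carries its own unit
  (length 8–30, rejection-sampled to pairwise identity < 30%), unit
  count (3–12), signal, leader and tail; members mutate each unit copy
  independently at `mutation_rate` (default 5%).  Units never start or
  end with K/R and never contain adjacent K/R (mutations resample on
  collision), so the planted sites are exactly the sites found and the
  truth intervals are exact.
* **Decoys**, one class per rejection reason.  The `no_repeat` class is
  certified repeat-free by a detector-independent property — no 5-mer
  occurs twice — so its ground-truth label cannot be wrong by sampling
  accident; the other classes are structural.
* **Gene orders**: one contig per strain, KEP anchors evenly spaced at
  least 34 ranks apart so 15-gene windows never interact; DUF3328
  planted near a `duf3328_fraction` (default 0.22) of KEP genes at a
  truncated-geometric distance with mean about 3.09; Tyrosinase planted
  only near DUF3328-positive KEPs; background MFS_1 labels scattered at
  3% of genes.

The generator emulates the *statistical* structure the method assumes —
repeat arrays, dibasic separators, clustered cyclization-factor genes.
It does not emulate real proteome composition, domain architecture
beyond the planted labels, genuine signal-peptide diversity, length or
amino-acid biases, or shared evolutionary history beyond single-ancestor
families.  Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted structure, not real-data
sensitivity or specificity.

Reference problem sizes used by the test suite and `scripts/acceptance.R`
— 20 strains × (5 KEPs + 36 decoys) for detection, 6 families × 10
members for typing, 500 KEPs for neighbourhood recovery — are the
package's reference study conditions; sensitivity at 5% mutation is
required to reach 0.99 and reaches 1.0 at mutation 0.

## Worked example

```{r example}
sim <- simulate_kep_study(sim_config(seed = 42, n_strains = 4,
                                     keps_per_strain = 3,
                                     decoys_per_class = 2,
                                     genes_per_strain = 120))
res <- kep_run_pipeline(sim$proteins, sim$predictions, sim$genes,
                        sim$domains, strains = sim$strains, quiet = TRUE)
glance(res)
head(res$type_table)
```

## Known limitations

* The repeat scorer's voting and mask-cleaning conventions are one
  self-consistent reading of a method whose published description leaves
  the seed set, placement range and normalization open; alternative
  conventions would shift the funnel on real data.  The conventions here
  were chosen for bounded scores, length stability and clean behaviour
  on random sequence, and are frozen.
* E-values are analytic Karlin–Altschul, not BLAST-calibrated; absolute
  values near a threshold can differ from BLAST by a small factor.
* Proteins that are repeats end-to-end (no flanking pro-region) are not
  called tandem-repetitive under the parts rule.
* The signal heuristic is a construction standard shared with the
  generator, not a predictor; use SignalP files for real data.
* Convention checks against the two published pheromone-precursor
  records (fragment counts 12/15, Y-containing fragments 2/3) require
  the real sequences, which are not redistributable here; the check is
  implemented (`kep_fragment_report()`) and runs once the records are
  placed under `inst/extdata/`.
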