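---
title: "Methods: the Conservation Priority Index and its workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Conservation Priority Index and its workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpirank)
```

## The model

The package scores lake-country units — the national portion of a lake —
for site-based conservation priority. Three ingredients enter the index.

**Species relative rarity.** Within a country with `Wt` assessed lakes, a
species found in `Ws` of them has rarity `SRR = 1 − Ws/Wt`. Rarity is
deliberately country-scoped: conservation treaties are implemented by
national authorities, so a species that is widespread globally but
confined to one lake within a country still signals irreplaceability at
the scale where decisions are made. The flip side is a boundary artifact:
a country with a single assessed lake has `Ws = Wt = 1` for every species,
so every SRR — and the index itself — is 0 there. That zero is an honest
statement that rarity cannot be assessed from one site, not a statement
that the lake is worthless.

**Threat weighting.** Each unit's distinct species are tallied by IUCN Red
List category and weighted ET=7, EXw=6, CR=5, DD=5, NE=5, EN=4, VU=3,
NT=2, LC=1; the conservation score `Cwt` is the weighted sum. Two choices
deserve comment. First, data-deficient and not-evaluated species share the
critically-endangered weight: treating unknown status as low concern is
how poorly studied species slip into extinction, so the index takes the
precautionary stance. For the same reason, species missing from the status
table entirely default to NE rather than raising an error. Second, the
raw-code normalizer maps the standard extinct codes EX and EW onto the
weight table's ET and EXw labels (extinct, extinct-in-the-wild); legacy
LR/nt and LR/cd become NT and LR/lc becomes LC.

**Area as a cost proxy.** The index divides by the unit's surface area
`Aw` (km²) times a scaling constant `k`:

`CPI = (Cwt × RRw) / (Aw × k)`.

Area stands in for the cost of protecting the site and for the greater
ecological substitutability of large habitats. The division makes CPI a
density-like quantity (per km²), so small lakes with rare, threatened
assemblages can outrank large species-rich ones.

Two formulations circulate for aggregating rarity and threat: a per-unit
product of the two summed quantities, and a per-species product summed
across species. This package implements the former — `Cwt × RRw` at the
unit level — because only that form is consistent with unit-level rarity
sums far above 1 in published league tables, and because it keeps the two
components independently reportable. Likewise `RRw` is the *plain* sum of
member-species SRR, not a per-species mean: dividing by richness would
cancel the very richness signal the score is meant to carry.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | 8 | — | Number of distinct IUCN weight levels considered; rescales CPI without reordering it. Users weighting fewer categories should set it accordingly. |
| `threshold` | 0.5 | CPI | High/low priority cut. High is defined strictly (`CPI > threshold`); a value exactly at the threshold is classified low, since only the strict inequality defines the high class. |
| `weights` | table above | — | Configurable because the weights are assigned, not derived; the shipped values are the published defaults. |
| `train_fraction` | 0.7 | — | Train share of the classifier split. |
| `n_permutations` | 100 | — | Site orderings averaged in the accumulation curve. |
| rf `ntree` / gbt `nrounds` | 500 / 100 | — | Standard defaults for these ensemble sizes; neither is prescribed by the index itself. |
| rf `tune_step_factor`, `improve` | 2, 0.05 | — | mtry tuning: step multiplier and minimum relative out-of-bag improvement to accept a step. |

## Record cleaning

Filtering runs in a fixed stage order, each stage logging records in,
records out, and a drop reason, so drops plus survivors always equal the
input count: (1) names without a complete specific epithet ("Oreochromis
spp.", single-word names) are dropped; (2) records with no waterbody are
dropped unless a user-supplied bounding-box lookup resolves their
coordinates to a lake; (3) waterbody names are harmonized to canonical
English registry names through a synonym map (case-insensitive and
accent-folding, so "lac Édouard" matches "lac Edouard"); (4) records whose
lake has no registry entry — hence no determinable area — are dropped;
(5) records whose country conflicts with the registry's (lake, country)
pairing are dropped. Expert corrections (relocating records misassigned to
the wrong lake) are not automated; they enter as an explicit override
table applied before filtering, keeping the judgment call visible and
auditable. Filtering is idempotent: survivors pass unchanged through a
second run.

Richness and every downstream score use distinct (species, lake, country)
triples; raw record counts appear only in reports. Occurrence archives
mix surveys of wildly different effort, so record counts carry sampling
intensity, not abundance.

## Statistics

Pearson correlations among richness, `Cwt`, area, and `RRw` use the
standard t-test with `df = n − 2`. The two priority classes are compared
with the unpaired Mann–Whitney rank-sum test — the group sizes are unequal
and unpaired, so the paired signed-rank variant does not apply — reporting
the U statistic of the first group, a tie-corrected normal deviate z
without continuity correction, and the effect size `r = |z|/√(n1+n2)`
(the convention used by rank-based effect-size tools). For small samples
(`n1 + n2 ≤ 12`) the p-value switches automatically to exact enumeration
of all group assignments, because the normal approximation is off by far
more than publication precision there (e.g. two-sided p of 0.33 vs 0.12
at the extreme of two groups of three); z, and hence the effect size,
remains the normal deviate in either case.

The species accumulation curve averages cumulative distinct-species counts
over random unit orderings (delegated to `vegan::specaccum`). When the
number of units is small enough that all `n!` orderings fit within the
permutation budget, the complete set of orderings is used, making the
curve the exact expectation; otherwise seeded random orders are drawn.
This matters because off-the-shelf "complete enumeration" in permutation
libraries excludes the observed ordering, which biases the mean curve at
tiny n.

## Classifiers

The feature matrix holds area, `Cwt`, `RRw`, and one-hot country
indicators in sorted-country order; the label is the priority class, with
*high* the positive class for recall, specificity, and precision (the
class of interest is the one a planner acts on). The split is stratified
by class: priority classes are typically imbalanced (roughly 1:4 in the
motivating application), and an unstratified 30% test set would
occasionally contain a single class, making half the metric suite
undefined. The random forest tunes mtry by step-factor search on
out-of-bag error; the gradient-boosted model uses a two-class
soft-probability objective with multiclass log-loss — the two-class case
of the usual multiclass setup, mathematically equivalent to binary
log-loss. Partial dependence clamps one feature across a grid and
averages the predicted high-class probability over the evaluation rows.
All fits are seeded and bit-reproducible.

## The synthetic generator

`generate_dataset()` emulates what the index assumes about real occurrence
archives: several countries; right-skewed lake areas
(log-normal, default meanlog 3 and sdlog 1.5, i.e. a median around 20 km²
with a long tail of great lakes); per-lake target richness following a
power law `richness ∝ area^z` with multiplicative log-normal noise
(defaults z = 0.3, sdlog 0.2 — a mid-range species–area exponent for
lacustrine fish); a configurable fraction of single-lake endemics (default
0.3) with the remaining species placed in random within-country subsets of
at least two lakes; and an IUCN mix drawn from the empirical composition
of a continental lake-fish assessment (≈67% LC, with NE and DD the next
largest groups). Species never span countries by default, matching the
country-scoped rarity definition.

What it does **not** emulate: spatial structure (no lake geometry, no
geographic autocorrelation of composition), taxonomic noise beyond the
injected epithet corruption, temporal dynamics, and observation effort
gradients. Tests passing on synthetic data therefore validate the
*computations* — not the adequacy of GBIF sampling for any particular
region. `inject_noise()` appends corrupted copies of rows (incomplete
epithets; stripped waterbody and coordinates) rather than mutating rows in
place, so the filter's recovery of exactly the clean table is a checkable
identity.

## Numerical choices and degenerate inputs

- Ranking ties break deterministically: descending `Cwt`, then ascending
  area (the cheaper unit first), then lake name.
- Units with missing or non-positive registry areas are excluded from CPI
  with a warning, mirroring how lakes without determinable areas are
  discarded upstream.
- An empty survivor set, an empty species set in a unit (RRw = 0), and a
  single-unit accumulation curve are all valid, handled inputs.
- Grouped rarity sums run in sorted-species order, so results are
  invariant to input row order down to the last bit; the test suite's
  independent brute-force oracle exploits this to assert exact (not
  approximate) agreement.

## Problem sizes

The shipped tests run the oracle-equivalence suite on 50 generated
datasets of up to ~6 lakes per country, the importance-recovery suite on
20 seeded repeats of 150-unit datasets, and the exhaustive rank-sum
comparison on all group-size pairs up to a combined n of 12 — sizes chosen
to make exhaustive enumeration and repeated refitting cheap while leaving
every code path exercised.

## Known limitations

- CPI is a *relative, within-analysis* score: adding or removing assessed
  lakes changes `Wt` and every SRR in the country, so scores are only
  comparable within one run.
- Area is a crude cost proxy; true protection costs depend on catchment,
  tenure, and threats the index does not see.
- Rivers and other linear habitats are out of scope — damming fragments
  them into sections that would need independent treatment.
- The single-assessed-lake zero means data-poor countries are structurally
  down-weighted; that is a data gap, not a conservation judgment.
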