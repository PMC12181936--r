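---
title: "Building hierarchical PFAS categories: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building hierarchical PFAS categories: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfascat)
```

Per- and polyfluoroalkyl substances (PFAS) number in the thousands under any
structural definition, and only a handful have usable toxicity data. The
practical response is grouping: place structurally similar substances into
categories tight enough that data measured on a few members can be read
across to the rest, and pick those few members well. `pfascat` implements
that workflow end to end — from raw SMILES to a category hierarchy, per-
category representative substances, exposure annotation, harmonized points
of departure, structural-alert enrichment and a classifier that places new
substances into the existing categories.

## The category hierarchy

**Membership filter.** A substance enters the landscape when it contains at
least one of three substructures: (1) `R-(CF2)-CF(R')R''` with both carbons
saturated; (2) `R-CF2-O-CF2-R'` with `R, R'` fluorine, oxygen or saturated
carbon; (3) `CF3-C(CF3)(R')(R'')` with `R', R''` fluorine or saturated
carbon. This is deliberately narrower than the single `-CF3`/`-CF2-`
convention: it excludes, for example, 1,1,1-trifluoroethane and
trifluoroacetic acid. The patterns are encoded as SMARTS in
`pfas_definition_patterns()` and are swappable, because which definition is
"right" is a regulatory rather than chemical question.

**Structure standardization.** All structure-based operations run on
QSAR-ready SMILES: the largest organic component (ranked by carbon count,
then molecular weight), stereochemistry descriptors removed, common
protonation states neutralized, canonicalized. Standardization is idempotent
and unparseable structures are retained as unclassifiable rather than
dropped — a mixture or polymer record should surface as `"unclassified"`, not
vanish. Deduplication uses the full 27-character hashed InChIKey, so
stereo-free constitutional duplicates collapse while tautomer handling is
left to standardization.

**Primary categories.** An ordered, most-specific-first rule table
(`primary_class_rules()`) assigns each substance a broad first class
(perfluoroalkyl acids, PFAA precursors, polyfluoroalkyl acids, other PFAS,
each with a cyclic variant) and a finer second class (PASF-based substances,
n:2 fluorotelomer-based substances, HFCs, Aromatic PFASs, Si PFASs,
Polyfluoroalkanes, PolyFCA derivatives, ...). The published classification
tool this vocabulary comes from does not expose its internal rules, so the
table is this package's own reconstruction and is editable data, not code.
The hybrid rule then balances category sizes: a first class with more than
300 members is replaced by its second classes, and promoted second classes
with fewer than 10 members fall back into the catch-all `"others"` bucket.
The 300 cap is the published value; the low-count fallback of 10 is this
package's choice (the source states only "very low"), exposed as
`min_second_class`.

**Chain length and secondary categories.** The maximum contiguous
perfluorinated chain length is the longest run of carbons each bearing at
least two fluorines and no hydrogens, found by matching substructure
patterns of increasing run length — the same iterative procedure the source
methodology describes. Terminal `CF3` carbons count: perfluorooctanoic acid
scores 7 (the eighth backbone carbon is the carboxyl) and perfluorooctane
sulfonic acid scores 8, which pins down the convention; a strict
CF2-only mode sits behind `strict_cf2`. The run is found with
recursive-SMARTS atom terms (`[CX4;H0;$(C(F)F)]`) rather than explicit
`(F)(F)` branches — the latter enumerate every fluorine permutation along
the run and blow up combinatorially on long chains. For branched networks
this pattern iteration finds the longest simple path through qualifying
carbons. Substances split at chain length 7 (`gte7` vs `lt7`), giving
secondary categories such as `"Aromatic PFASs, gte7"`.

## From similarity to terminal categories

Structure similarity uses radius-3 circular (Morgan-type,
extended-connectivity) fingerprints at 1024 bits and Jaccard distance
`1 - |A ∩ B| / |A ∪ B|` on the bit sets. Fingerprints are computed by Open
Babel's ECFP6 implementation in a single batched subprocess call and folded
from 4096 to 1024 bits by OR; bit values therefore differ from other
toolkits' Morgan bits, but every downstream quantity depends only on
within-landscape distances, not on any particular bit scheme. Two all-zero
fingerprints are at distance 0 by convention.

The **objective distance threshold** asks: how far apart are substances that
everyone agrees belong to different categories? For every pair of secondary
categories with *different* primary roots, the median cross-category
pairwise distance is recorded; the threshold τ is the 15th percentile of
those between-category medians (linear-interpolation quantile convention,
documented because the source does not state one). A secondary category
whose own median pairwise distance strictly exceeds τ is too diverse and is
split; ties at τ are not split, with "meets or exceeds" available via
`split_ties` since the source uses both wordings. Singleton categories are
excluded from the median computation.

**Splitting** is agglomerative hierarchical clustering with Ward's criterion
on the precomputed Jaccard distance matrix (`hclust(method = "ward.D2")`,
whose merge heights match the common scientific-Python implementation on a
condensed distance input). "First-generation clusters" are read as the
clusters obtained by cutting the dendrogram at 0.7 × the maximum merge
height — the conventional dendrogram colouring threshold; a strict
root-bisection reading is ruled out because published categories show more
than two children. The cut fraction is config. Splitting recurses at most
two generations below the secondary level, and children are named by
appended cluster indices: a twice-split substance might land in
`"Aromatic PFASs, lt7, 4, 1"`, while a never-split category exports as
`"Aromatic PFASs, gte7, nan, nan"` (`"nan"` marks an unsplit level in the
tabular output).

## Representative selection

Each terminal category's **centroid** is its medoid: the member minimizing
the summed distance to all other members (ties to lowest index). For
categories with more than 5 members, **MaxMin picking** adds diverse
members: starting from the centroid, each step adds the candidate whose
minimum distance to the picked set is largest (ties to lowest index), with
k = 3 extra picks by default — enough to bound a category's structural
domain without flooding a testing program.

The **coverage curve** quantifies what a selection buys. With picks ordered
centroid-first and MaxMin to exhaustion, `m(k)` is the mean over all members
of the minimum distance to the first `k` picks, and coverage is the
normalized cumulative sum `c(k) = Σ m(1..k) / Σ m(1..n)`. `m` is
nonincreasing, `c` nondecreasing with `c(n) = 1`; a singleton is defined as
fully covered. By default the mean runs over all members (picked members
contribute zero at their own index); an unpicked-members-only variant is
available via `include_picked = FALSE`. Coverage targets of 50% and 80% are
summarized per category — 80% being illustrative, not prescriptive.

## Exposure annotation and triage

Physical state is assigned at 25 °C from predicted melting and boiling
points (gas: bp < 25; solid: mp ≥ 25; liquid: mp < 25 ≤ bp). Solubility,
volatility and high volatility use water solubility ≥ 0.5 mg/L, vapour
pressure ≥ 75 mmHg and Henry's law constant ≥ 0.1 atm·m³/mol; the ≥
direction on thresholds is this package's documented choice. These combine
into designations A (insoluble solids), B (soluble solids, soluble
non-volatile liquids), C (soluble volatile liquids, insoluble liquids,
soluble gases) and D (insoluble or highly volatile gases), with
`"not determined"` when properties are missing on every rule path, and D
taking precedence for a soluble gas that is also highly volatile. Production
volumes map into the ten reporting ranges with boundary values joining the
bin whose lower bound they equal.

The **triage workflow** nominates data-collection candidates per terminal
category through three gates — the category is data-poor (no member has an
oral or inhalation repeated-dose record with a NOAEL/LOAEL/LOEL/NOEL/NEL/LEL
value), contains inventory members, and contains monitored members — then
prefers, in order: representative picks already on the inventory; the
inventory member nearest the centroid; and the centroid/MaxMin selection
recomputed on the inventory-constrained category. Every nomination carries
its branch rationale.

## POD harmonization

Toxicity records are filtered to the oral route, the listed effect-level
types, study types and dose units, and the six standardizable species. Each
record is harmonized to a chronic human-equivalent benchmark dose (BMDh) by
an auditable factor chain: LOAEL-type values ÷ 3; subchronic ÷ 2; subacute
(short-term, 28-day) ÷ 5; species conversion by allometric body-weight
scaling `(bw_h / bw_a)^0.25`; and the mean of two conceptual-model
multipliers. The study-type → duration-class mapping, the body weights and
exponent, and the multipliers (0.5, 1.0 per effect class by default) are
documented reconstructions of the cited harmonization framework — the source
names the duration and LOAEL factors only — and all live in config tables
(`study_duration_classes()`, `default_species_factors()`,
`default_conceptual_models()`). Multiplying a record's logged factors always
reconstructs the input/output ratio exactly.

The per-substance POD is the 25th percentile of a lognormal moment-matched
to the mean and standard deviation of the substance's BMDh records
(`σ² = ln(1 + sd²/mean²)`, `μ = ln(mean) − σ²/2`); moment matching rather
than fitting log-transformed values is deliberate, since the procedure is
specified in terms of the arithmetic mean and sd. Substances with fewer than
5 records (or a single record) use the median sd across substances within
their effect class; sd = 0 degenerates to the mean. Noncancer and
reproductive/developmental records run as separate streams. Category
summaries report log10 POD quartiles, IQR, range and 1.5 × IQR whiskers.

## Flag enrichment and the category classifier

Assay-derived qualitative flags (graded 0/1/2; immune flags 0/1 only) are
QC-filtered and binarized — medium-plus-high positive by default, high-only
via `positive = 2`, since the source does not state which convention it
used. Toxicokinetic half-life bins 1–4 binarize as bin 4 = 1. For each
binary structural feature a 2×2 table against the flag yields a one-sided
Fisher exact p-value (enrichment direction) and an odds ratio `ad/bc` with a
Haldane–Anscombe 0.5 correction when any cell is zero (raw ratio via
config). A feature is enriched when OR ≥ 3, p < 0.05 and true positives ≥ 3;
constant features or flags get p = 1. Enriched features predict flags across
a landscape (positive iff ≥ 1 enriched feature carried), scored by
sensitivity, specificity and — for hard binary predictions — balanced
accuracy as the ROC AUC, consistent with published metric tables where the
AUC lies between sensitivity and specificity.

The **category classifier** is a random forest over fingerprint bits, chain
length and the ordinal-encoded primary category, with terminal categories
under 10 members pooled into `"miscellaneous"`. Chain length and bits are
standardized with statistics fitted on the training split only (the source
pipeline standardizes; raw bits are available via `standardize = FALSE`);
unseen primary categories at prediction time map to a reserved code. The
procedure — stratified 80/20 split, majority-class baseline, small random
search over tree counts under stratified 5-fold cross-validation, held-out
scoring, refit on all data — is deterministic given its seed, and balanced
accuracy (macro recall) is the metric throughout.

## What the synthetic landscape does and does not show

`generate_landscape()` builds homologous series from seven structural
templates (perfluorocarboxylic and -sulfonic acids, n:2 fluorotelomers,
sulfonyl fluorides/amides, aromatic, perfluoroether and ω-H series) over
perfluorinated runs of 2–11 plus non-PFAS decoys — about 150 substances
populating five primary classes, both chain bins, and every merge path of
the degradant workflow. Companion generators emit properties with monotone
chain-length trends, toxicity records built by inverting the harmonization
chain around planted lognormal medians (a 10× shift for long-chain members
by default), flag tables achieving a target feature–flag odds ratio in
expectation, and inventory/monitoring lists. Every generator is a pure
function of its arguments and seed.

Passing tests on this landscape demonstrate that the machinery is correct:
truth-table chain lengths match the categorizer, planted effects are
recovered, selections obey their oracles. They do not show that the
categories are toxicologically meaningful for real PFAS: the synthetic
families are cleaner, the within-family similarity higher and the landscape
three orders of magnitude smaller than the deposited ~15,000-substance
landscape. Reproducing the published landscape-scale numbers (threshold
0.8, 128 terminal categories, ...) requires that deposited dataset;
`scripts/replicate_landscape.R` runs the identical pipeline against it in
one command.

Test and acceptance runs use deliberately modest problem sizes — the ~150
substance landscape, 200 substances × up to 8 records for POD recovery,
150 substances × 200 replicates for enrichment power, 120 substances for
the classifier — chosen so the full pipeline is exercised at desk scale
while each property remains statistically decidable.

## Numerical conventions, in one place

* Quantiles: linear interpolation (R type 7) everywhere a percentile is
  taken.
* Ties: lowest index wins — centroids, MaxMin candidates, linkage merges.
* Splitting: strict `>` τ by default; `≥` behind `split_ties`.
* Ward cut: 0.7 × maximum merge height; all-identical distance matrices
  yield a single cluster.
* Jaccard on two empty bit sets: 0.
* Degenerate lognormal (sd = 0): POD = mean.
* Fisher odds ratio with a zero cell: +0.5 to every cell.
* Unparseable structures: `NA`/retained-unclassifiable, never silently
  dropped; parse failure is kept distinct from a negative PFAS test.

## Known limitations

* The primary-class rule table approximates an unpublished classification
  tool; agreement at the level of individual exotic structures is not
  guaranteed, which is why the table ships as editable data.
* Charge neutralization handles common protonation states textually;
  organometallics, quaternary nitrogens and exotic charge states pass
  through unchanged.
* Fingerprint bits are Open Babel ECFP6 foldings, not interchangeable with
  other toolkits' bit positions.
* Body-weight factors and conceptual-model multipliers are reconstructions;
  absolute BMDh values shift under a different calibration even though every
  relative comparison within a run is unaffected.
* The coverage denominator sums mean minimum distances over the full pick
  ordering; other normalizations would change absolute coverage fractions
  but not the ordering of categories by diversity.
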