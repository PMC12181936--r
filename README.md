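# pfascat

Hierarchical structural categorization of per- and polyfluoroalkyl
substances (PFAS), with representative-substance selection, exposure
annotation, point-of-departure harmonization, structural-alert enrichment
and a category classifier.

## The problem

Thousands of chemicals meet structural definitions of PFAS; almost none
have enough toxicity data for individual assessment. Regulatory testing
strategies therefore group PFAS into structural categories and test a few
well-chosen members per category, reading the results across to the rest.
`pfascat` is for computational toxicologists and cheminformaticians who
need that grouping to be reproducible: given a table of structures
(SMILES), it derives a category hierarchy, picks representative and diverse
members per category, quantifies how much structural diversity those picks
capture, layers on exposure and toxicity-data evidence to triage categories
for data collection, and trains a classifier so new substances can be
placed without re-running the landscape.

## The method

* **Membership**: a substance is in scope when it contains one of three
  substructures — R−(CF₂)−CF(R′)R″ (both carbons saturated),
  R−CF₂−O−CF₂−R′ (R, R′ ∈ {F, O, saturated C}), or CF₃−C(CF₃)(R′)(R″)
  (R′, R″ ∈ {F, saturated C}). Predicted degradation products can be merged
  in, deduplicated by InChIKey against the landscape.
* **Hierarchy**: primary categories from an ordered structural rule table
  with a 300-member hybrid rule; secondary categories by the maximum
  contiguous perfluorinated chain length *L* at the threshold *L* ≥ 7
  (`gte7`/`lt7`); terminal categories by recursive Ward clustering (at most
  two generations) of radius-3 circular fingerprints under Jaccard distance
  *d* = 1 − |A∩B|/|A∪B|, splitting any category whose median pairwise
  distance exceeds an objective threshold τ — the 15th percentile of median
  *between*-category distances.
* **Selection**: per terminal category, the centroid (medoid,
  argmin<sub>i</sub> Σ<sub>j</sub> d<sub>ij</sub>) plus up to 3 MaxMin
  picks (each maximizing the minimum distance to the picked set), with a
  coverage curve c(k) = Σ<sub>j≤k</sub> m(j) / Σ<sub>j≤n</sub> m(j), where
  m(k) is the mean minimum distance of members to the first k picks.
* **Evidence layers**: physical-state/physicochemical designations A–D,
  inventory and monitoring-list tags, a data-poor gate, and a triage
  workflow nominating candidates with branch rationales; in vivo effect
  levels harmonized to chronic human-equivalent benchmark doses (LOAEL ÷ 3,
  subchronic ÷ 2, subacute ÷ 5, allometric species scaling, conceptual-model
  mean) and summarized per substance as the 25th percentile of a
  moment-matched lognormal; structural features enriched against assay
  flags by one-sided Fisher exact test (enriched ⇔ OR ≥ 3, p < 0.05,
  TP ≥ 3); a random forest over fingerprints + chain length + primary
  category, scored by balanced accuracy.

Chemistry (SMILES parsing, canonicalization, InChIKeys, SMARTS matching,
ECFP fingerprints) runs on Open Babel via ChemmineOB and the `obabel`
command-line tool.

## A worked example

```r
library(pfascat)
library(tibble)

substances <- tibble(
  substance_id = c("PFOA", "PFOS", "PFBS", "FTOH_82", "TFE"),
  smiles = c(
    "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    "CC(F)(F)F"))

registry <- as_registry(substances)
matches_pfas_definition(registry$qsar_ready_smiles)
#> [1]  TRUE  TRUE  TRUE  TRUE FALSE

categorize_substances(registry)[, c("substance_id", "primary_category",
                                    "chain_length", "secondary_category")]
#> # A tibble: 5 × 4
#>   substance_id primary_category chain_length secondary_category
#>   <chr>        <chr>                   <int> <chr>
#> 1 PFOA         PFAAs                       7 PFAAs, gte7
#> 2 PFOS         PFAAs                       8 PFAAs, gte7
#> 3 PFBS         PFAAs                       4 PFAAs, lt7
#> 4 FTOH_82      PFAA precursors             8 PFAA precursors, gte7
#> 5 TFE          unclassified                1 unclassified, lt7
```

1,1,1-Trifluoroethane (`TFE`) carries a CF₃ group but fails all three
definitional substructures, so it is excluded ( `FALSE`) and lands in
`unclassified`. PFOA's chain length is 7 — the eighth backbone carbon is
the carboxyl — while PFOS scores 8, and both fall in the long-chain `gte7`
bin. The 8:2 fluorotelomer alcohol is a PFAA precursor with a fully
fluorinated run of 8.

The full workflow on a complete landscape (here the built-in synthetic
one):

```r
land <- generate_landscape()                 # ~150 substances, 7 families
pipe <- run_categorization_pipeline(land)    # categories -> tau -> terminals -> picks
pipe$threshold_report$tau                    # objective distance threshold
head(pipe$selections)                        # centroid + MaxMin per category
plot_coverage_curves(pipe$coverage)          # diversity captured vs picks
```

A thin command-line wrapper lives at `inst/cli/pfascat.R`
(`simulate` / `categorize` / `triage` subcommands).

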