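# knockr

Complete, pruned enumeration of growth-coupled knockout strategies in
genome-scale metabolic models.

## The problem

Strain engineers want deletion sets after which a microbe can only grow if it
also secretes a product of interest (*growth-coupled production*). Bilevel
optimizers (OptKnock-style) return a single optimal strategy; minimal-cut-set
enumerators return many but miss solutions below their preset thresholds.
`knockr` enumerates **all** reaction (or gene) knockout strategies up to a
chosen cardinality *k* that keep growth above a viability floor and push
production above a threshold — so the full solution set can afterwards be
ranked by whatever index matters: yield, substrate-specific productivity
(SSP), strength of growth coupling (SoGC), CO₂ balance, or proximity to the
wild-type flux state (linear MOMA).

## The method in brief

Given a model (stoichiometry *S*, bounds *lb ≤ v ≤ ub*, biomass objective,
GPR rules) under a defined medium, a deletion set *D* qualifies when, with
*lb_r = ub_r = 0* for all *r ∈ D*,

* FBA growth μ(D) ≥ 1% · μ_WT (viability floor), and
* the product exchange flux at optimal growth clears 5% of the maximum
  theoretical production rate — in its **best case** (`rate_max`) or even in
  its **guaranteed** worst case (`rate_grnt`), both taken from FVA of the
  product exchange with growth fixed at μ(D).

Enumeration is a depth-first tree walk: nodes at level *L* delete *L*
reactions; a node's children extend it by one reaction from its *target
space* — the preprocessed candidate reactions that can still carry flux at
the node's growth optimum (FVA-based by default, so alternate optima cannot
hide solutions). Subtrees are skipped exactly when the node's LP is
infeasible or growth falls below the floor; both conditions are monotone
under added knockouts, so pruning never loses a solution — a property the
test suite verifies against a brute-force oracle on seeded toy networks.
Preprocessing (blocked reactions, dead-end metabolites, essential reactions,
exchange/objective exclusion) bounds the candidate set before the walk; a
minimality filter keeps only strategies with no qualifying proper subset.
Gene mode translates strategies to minimal gene deletion sets and evaluates
the *effective* knockout (targets plus co-knocked reactions sharing those
genes).

All linear programs run on a built-in bounded-variable two-phase simplex
(Bland's rule, deterministic vertex choice), cross-checked in the tests
against an independent solver. Models load from BiGG-style JSON or SBML
Level 3 + FBC.

## Worked example

The built-in toy network has substrate uptake (≤ 10 mmol·gDW⁻¹·h⁻¹) feeding
a branch point where a biomass branch consumes a reduced cofactor that two
competing branches regenerate — one secreting product `P`, one byproduct `D`:

```r
library(knockr)

toy  <- make_toy1()
prep <- preprocess_model(toy)
prep
#> <preprocess_report>
#>   wild-type growth: 5
#>   blocked: 0 | dead-end metabolites: 0 | essential: 2
#>   removable candidates: 2

cfg <- traversal_config(target_level = 2, mode = "rate_grnt")
th  <- compute_thresholds(toy, "EX_P", cfg)
unlist(th)
#>         gr_wt    v_chemical   th_chemical biomass_floor
#>          5.00          5.00          0.25          0.05

enum <- enumerate_knockouts(prep$reduced_model, prep$removable, "EX_P",
                            cfg, thresholds = th)
enum
#> <knockout_enumeration> k = 2, mode = rate_grnt
#>   thresholds: gr_wt = 5, production threshold = 0.25
#>   nodes: 4 | node LPs: 4 | FVA LPs: 10
#>   minimal solutions (rate_grnt): 1

solutions(enum)[, c("level", "reactions", "growth", "product_min", "product_max")]
#> # A tibble: 1 × 5
#>   level reactions growth product_min product_max
#>   <int> <chr>      <dbl>       <dbl>       <dbl>
#> 1     1 R4             5        5.00           5
```

Deleting the byproduct branch `R4` is the unique single knockout whose
*guaranteed* production rate (5, the `product_min` column) clears the 0.25
threshold: with the competing branch gone, every optimal-growth flux state
must secrete P — production is growth-coupled. The strategy metrics panel:

```r
met <- evaluate_strategies(toy, solutions(enum), "EX_P", substrate_uptake = 10)
met[, c("reactions", "growth", "yield", "ssp", "sogc", "moma_growth")]
#> # A tibble: 1 × 6
#>   reactions growth yield   ssp  sogc moma_growth
#>   <chr>      <dbl> <dbl> <dbl> <dbl>       <dbl>
#> 1 R4             5   0.5    25  0.25           5
```

yield = 5/10 mmol product per mmol substrate; SSP = growth × rate = 25; SoGC
= yield² / slope of the envelope's lower edge = 0.5²/1 = 0.25, the
closed-form value for a fully coupled strain. `autoplot()` draws production
envelopes and solution counts; `tidy()`/`glance()` give broom-style views of
an enumeration. For file-driven runs there is `run_config()` +
`run_enumeration()` (solutions TSV + metadata JSON) and a thin CLI wrapper
at `inst/cli/knockr.R`.

See `vignette("growth-coupled-enumeration")` for the full methods account:
target-space rules and the completeness argument, threshold conventions,
gene-level planning, metric definitions and numerical tolerances.

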