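---
title: "Enumerating growth-coupled knockout strategies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating growth-coupled knockout strategies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockr)
```

## The problem

Metabolic engineering of a production strain often aims at *growth-coupled*
overproduction: a set of gene or reaction deletions after which the cell can
only grow if it also secretes the product of interest. Given a genome-scale
metabolic model (stoichiometry $S$, flux bounds $lb \le v \le ub$, a biomass
objective and gene-protein-reaction rules), the design question is
combinatorial: which sets of at most $k$ deletions couple production to
growth? Bilevel optimizers return one (near-)optimal strategy; minimal-cut-set
enumerators return many but filter by preset yield thresholds. This package
instead enumerates **all** qualifying strategies up to cardinality $k$, using
a depth-first traversal whose pruning provably discards only sets that cannot
lead to a solution, so the result can afterwards be ranked by any index a
strain engineer cares about (yield, substrate-specific productivity, strength
of growth coupling, CO~2~ balance, proximity to the wild-type flux state).

## Constraint-based machinery

All quantities derive from linear programs over the steady-state polytope
$\{v : S v = 0,\ lb \le v \le ub\}$:

* **FBA** (`solve_fba()`): maximize one flux, typically biomass
  ($\mu = v_{\mathrm{biomass}}$, h^-1^).
* **FVA** (`run_fva()`): per-reaction min/max flux with the objective held at
  a fraction of its optimum (two LPs per reaction).
* **Knockout** (`apply_knockouts()`): $lb_r = ub_r = 0$ for deleted
  reactions. Reversibility is encoded purely by $lb_r < 0$; reactions are
  never split into forward/backward halves.
* **Medium** (`apply_medium()`): exchange fluxes are negative for uptake;
  listed exchanges get $lb = -\text{max uptake}$, all unlisted exchanges are
  closed for uptake with secretion left open (minimal-medium semantics).

The LPs are solved by a bounded-variable two-phase primal simplex written for
this package, with Bland's smallest-index rule for both pivot choices. Bland's
rule never cycles, and it makes the returned vertex a deterministic function
of the input, which in turn makes enumeration output reproducible
run-to-run. The basis is densely refactorized every iteration: wasteful on
paper, but the models this package targets in-process are small enough that
robustness is worth more than speed, and the kernel is cross-checked in the
test suite against an independent solver on random feasible LPs.

Numerical conventions, used consistently everywhere:

* a flux with $|v| \le 10^{-6}$ counts as zero (solver feasibility scale);
* "growth fixed at its optimum" is implemented as
  $\mu \ge (1 - 10^{-9})\,\mu^\*$ so floating-point ties cannot empty the
  feasible set;
* steady-state residuals of reported states must stay below $10^{-6}$
  (asserted in tests);
* production thresholds are compared with $\ge$ under an absolute $10^{-6}$
  tolerance.

## Qualification of a deletion set

A run fixes two thresholds up front (`compute_thresholds()`):

* the **biomass floor**, 1% of the wild-type growth rate $\mu_{WT}$: a strain
  below it is considered non-viable;
* the **production threshold**, 5% of the maximum theoretical production rate
  $V_{\mathrm{chem}}$ (product exchange as FBA objective in the base model).

Both fractions are configurable (`traversal_config()`); the defaults are the
conventional choices for this class of methods. For a candidate deletion set
the product exchange flux is then scanned at optimal growth
(`product_rates_at_optimal_growth()`), giving a guaranteed (minimum) and a
best-case (maximum) rate. A set qualifies in `rate_max` mode when the
best-case rate clears the threshold, and in the stricter `rate_grnt` mode
when even the guaranteed rate does. Guaranteed-rate solutions are always a
subset of best-case solutions; the package records both flags on every
qualifying set so one enumeration serves both readings. If the base model
cannot make the product at all ($V_{\mathrm{chem}} = 0$) the threshold
degenerates to zero with a warning, and every growth-viable set qualifies
vacuously.

## Preprocessing

`preprocess_model()` bounds the candidate space before any traversal:

* **blocked reactions**: FVA range $[0, 0]$ with no objective requirement;
* **dead-end metabolites**: structurally only-produced or only-consumed,
  iterated to a fixed point because removing one dead end can expose another;
* **essential reactions**: single knockout drives growth below the floor
  (the same 1% floor as qualification, not strict zero, for consistency);
* exchanges, drains and the objective are never candidates -- the medium is
  an experimental control, not a genetic intervention;
* in gene mode, reactions without a GPR are excluded (nothing to delete);
* a user exclusion list handles whatever additional criteria apply.

The remainder is the `removable` set. Blocked and dead-end-attached reactions
are structurally removed to give the reduced model; since they could never
carry flux, reduction is flux-neutral (the wild-type optimum is unchanged, a
tested invariant), and enumeration on the reduced model equals enumeration on
the full model.

## The traversal

The search tree places each deletion set of size $L$ at level $L$; the root
is the unperturbed strain. `enumerate_knockouts()` walks it depth-first:

1. Solve the node's FBA. If the LP is infeasible or growth falls below the
   biomass floor, skip the whole subtree. Both conditions are monotone under
   added knockouts (adding constraints can only shrink the feasible set and
   lower the optimum), so nothing reachable is lost. Infeasibility pruning is
   the classic rule; treating the growth floor as prune-eligible is an
   extension, justified by exactly the same monotonicity argument.
2. Test the node for qualification (levels $\ge 1$) and record it with both
   mode flags.
3. Compute the node's **target space**: the removable reactions, minus those
   already deleted, that can still carry flux at the node's growth optimum.
   Children are created for target-space members only.
4. Expand children in lexicographic order; each expanded reaction is barred
   from the subtrees of its later siblings, so every unordered set is
   constructed at most once.

Two target-space rules are provided. `fba_support` keeps reactions with
nonzero flux in the node's single FBA vertex -- one LP per node, but under a
degenerate optimum the solver's arbitrary vertex choice can hide a reaction
that an alternate optimum uses, and with it a true solution. In the canonical
toy model below, the two cofactor-regenerating branches are exactly such an
interchangeable pair. The default `fva_support` therefore asks FVA at the
node optimum whether a reaction *can* carry flux in any optimal state
(range not $[0,0]$), restoring completeness at the cost of two LPs per
candidate. The completeness argument for the combination of `fva_support`
with sibling deduplication: if reaction $b$ is excluded from the subtree of
sibling-set $D \cup \{a\}$, either $b$ was expanded earlier at this level (so
$D \cup \{a, b\}$ is reached along the earlier branch), or $b$'s flux range
at the optimum of $D \cup \{a\}$ is $[0,0]$ -- in which case every optimal
state already has $v_b = 0$, deleting $b$ changes neither the optimum nor the
product range over it, and $D \cup \{a, b\}$ qualifies exactly when
$D \cup \{a\}$ does, i.e. it is never a *new* (minimal) solution. The test
suite asserts this equality against a brute-force oracle on every generated
toy model.

A node that qualifies is still expanded: solutions exist at every
cardinality, and a qualifying superset of a qualifying set can behave
differently. Reported solution *counts*, however, follow the convention that
a set is only counted when none of its proper subsets already qualifies in
the same mode; `solutions()` applies this minimality filter by default and
exposes the unfiltered records on request. The target-space rule already
prevents most non-minimal sets (a deleted zero-flux reaction never enters a
child), so the filter is a safety net rather than the mechanism.

LP accounting mirrors the convention that one node costs one LP: the
node-level FBA count equals the number of constructed nodes; FVA solves
(target spaces, product ranges, envelopes) are counted separately.

### Gene mode

Deleting a reaction in the lab means deleting genes, and genes are shared.
`plan_gene_deletions()` picks, per target reaction, a minimal disabling gene
set (the minimal cut sets of its GPR, computed exactly on the expression
tree), preferring the union with fewest genes, ties broken lexicographically
-- the tie-break is this package's choice, as is reporting one canonical plan
and not every variant. All other reactions whose GPR dies under the chosen
genes are *co-knocked*; in gene mode the traversal qualifies the effective
set (targets plus co-knocked) and canonicalizes strategies that share an
effective set into a single record. Strategies whose genes are essential
elsewhere are not screened out separately: lethality is already caught by the
growth floor.

## Ranking metrics

* **Production envelope** (`production_envelope()`): product min/max on a
  uniform growth grid from 0 to $\mu^\*$, two LPs per point, 40 points by
  default -- enough to localize breakpoints of the piecewise-linear edges on
  the models this is meant for.
* **SoGC** (`compute_sogc()`): squared product yield per unit substrate
  divided by the slope of the envelope's lower edge. The slope is taken over
  the final linear segment ending at $\mu^\*$, detected by walking
  breakpoints backwards while consecutive interval slopes agree to a relative
  $10^{-6}$; a two-point finite difference at $\mu^\*$ is selectable, and the
  two agree whenever the final segment spans more than one grid interval. A
  flat or falling lower edge means uncoupled production: SoGC is reported as
  0 with a flag rather than a negative or infinite value.
* **Yield / SSP** (`compute_yield_ssp()`): yield is product rate over
  substrate uptake; SSP defaults to growth x product rate, the form in which
  such tables are conventionally printed, with the literature variant
  (growth x yield) behind a flag. The two differ by the uptake factor only.
* **CO~2~ exchange** (`co2_exchange_flux()`): with growth fixed at its
  optimum and product fixed at its maximum, the remaining degrees of freedom
  usually leave the CO~2~ flux degenerate, so the FVA range and its midpoint
  are reported instead of an arbitrary vertex. Negative = uptake.
* **Linear MOMA** (`linear_moma()`): the knockout-model flux state minimizing
  $\sum_r |v_r - v_r^{WT}|$ via the split-variable LP. By default the sum
  runs over internal (non-boundary) reactions: the minimized quantity is the
  intracellular rerouting effort, and exchange fluxes -- which must move
  whenever secretion targets change -- are consequences, not costs.
  `penalize = "all"` includes them. The wild-type reference defaults to the
  deterministic FBA vertex of the base model; any optimal vertex may be
  supplied, and with a degenerate wild-type optimum the choice matters.

## The toy generator, and what passing tests do (not) show

`make_toy1()` is the canonical fixture: substrate uptake (10 mmol gDW^-1^
h^-1^) into a branch point, a biomass branch consuming a reduced cofactor,
and two competing cofactor-regenerating branches, one secreting the product
and one a byproduct. Every number is hand-derivable: wild-type growth 5,
maximum product rate 5, production threshold 0.25, and deleting the
byproduct branch is the unique single knockout that guarantees production
(range $[5, 5]$), with SoGC $0.5^2 / 1 = 0.25$.

`generate_toy_model()` randomizes the same motif: seeded uptake (8-12
mmol gDW^-1^ h^-1^), 2-4 branches, three GPR wirings (one-to-one, a gene
shared between byproduct branches, isozymes on the product branch), and
sometimes a structurally dead decoy reaction for preprocessing to find. The
generator guarantees feasibility with positive growth and positive product
capacity by construction. Because every branch regenerates the same cofactor,
the guaranteed-rate solutions are exactly the byproduct-branch combinations
-- a ground truth independent of any LP, which is what makes the oracle
comparison meaningful.

What these fixtures deliberately do not emulate: alternate cofactor pools,
futile cycles, large degenerate optimal faces beyond the branch ambiguity,
reversible internal reactions, and genome-scale GPR complexity. A green toy
suite therefore certifies the *logic* (completeness vs. brute force, pruning
soundness, mode nesting, mass balance, determinism) -- not numerical behavior
on curated genome-scale models, which the genome-scale checks in the test
suite cover when a model file is supplied. Problem sizes in the shipped suite
-- 20 seeded toys, at most 4 branches, $k \le 3$, 40-point envelopes -- were
chosen as the smallest instances that exercise every code path including
cascaded dead ends, co-knockouts and isozymes.

## Degenerate inputs and edge behavior

* Empty candidate set or $k$ larger than the viable depth: empty solution
  table, not an error; a zero-solution run exits successfully and says so.
* Product exchange blocked under the medium: reduction removes it; the run
  reports zero solutions distinctly rather than failing.
* Zero-growth knockout models: envelopes refuse to build (degenerate,
  $\mu^\* \approx 0$) and the metrics row for such a strategy is `NA` with a
  message, while the run continues.
* GPR-less reactions: always active; non-deletable in gene mode, excluded
  from the candidate set there.
* Knockout sets are canonicalized (sorted, joined with `;`) wherever they
  appear, so output is invariant to expansion order.

## Known limitations

* The simplex kernel is dense and written in R: appropriate for models up to
  a few hundred reactions; genome-scale traversals at $k \ge 3$ are
  feasible but slow compared to compiled solvers.
* Only the linear MOMA variant is provided; quadratic MOMA, parsimonious and
  loopless FBA are out of scope.
* Parallel traversal is not implemented. The sequential contract -- output
  is a deterministic, sorted solution table -- is exactly what any future
  concurrent implementation must reproduce byte-identically.
* Co-knockout planning reports one canonical gene plan per strategy; when
  distinct minimal gene sets have different co-knockout footprints, the
  alternatives are computable via `genes_disabling_reaction()` but not
  enumerated as separate solutions.
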