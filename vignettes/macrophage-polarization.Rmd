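---
title: "A Boolean model of macrophage polarization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Boolean model of macrophage polarization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macpol)
```

## The model

`macpol` models monocyte-to-macrophage polarization as a synchronous
Boolean network.  Ten extracellular signals act as inputs: the
pro-inflammatory inducers IFNγ, LPS, GM-CSF and IL-1; the
anti-inflammatory inducers IC (immune complexes), IL-4, IL-13 and IL-10;
and the two signals characteristic of the chronic lymphocytic leukaemia
(CLL) micro-environment, M-CSF and HMGB1, through which malignant B cells
re-educate monocytes into nurse-like cells (NLCs).  Thirty intracellular
components — receptors, the STAT family, IRF3/4/5, NF-κB, PPARγ, KLF4,
JMJD3, SOCS1 and the secreted factors IL-1β, IL-12, IL-10s, TNFα, TGFβ,
EGF plus HIF1α and RAGE — carry literature-derived update rules written
with `and`, `or`, `not` (see `macpol:::macrophage_rule_table()`).

Every node holds a binary state; all nodes update simultaneously
(`synchronous_step()`).  Inputs are modelled as identity-rule self-loops,
so they are constant along any trajectory and "all stimulus combinations"
is exactly the set of `2^10` input assignments.  The three phenotype
readouts (M1, M2, NLC) are *not* dynamic nodes: they are classification
labels computed from the attractors, which keeps the dynamic system at
N = 40 components.

### Assumptions

* One node per gene/protein; activation and expression are conflated into
  a single binary level.
* Synchronous updating.  Fixed points are update-scheme invariant, so all
  fixed-point results are robust to this choice; cyclic attractors are
  not, and the package therefore only *probes* cycles by sampling
  (`sample_attractor_periods()`) rather than characterising them.
* The logic rules encode documented activations/inhibitions; where the
  dependence of a target on several regulators was not documented as
  joint, `or` is used.

## Rule dialects

Published rule tables often leave chains such as

```
PPARG <- IL4RA or MCSFR or ERK and not (STAT6)
```

un-parenthesized.  Two readings are defensible, and `parse_rule()` makes
the choice explicit.  Under `"standard"` precedence (`not` > `and` >
`or`, the convention of the common Boolean-network file formats and
toolkits) this is `IL4RA | MCSFR | (ERK & !STAT6)`; under the
`"grouped"` dialect (`and`/`or` at equal precedence, left-associative)
it is `(IL4RA | MCSFR | ERK) & !STAT6`, reading the trailing
`and not` as a guard on the whole disjunction.  Exactly three of the
thirty bundled rules — IFNGR, STAT1, PPARG — are dialect-sensitive; fully
parenthesized rules parse identically in both dialects, and both parses
of every rule are available to the user.

The package default is **standard precedence**.  This is a substantive
choice, not a formality: under the grouped reading of PPARG, MCSFR
activation (via STAT6) shuts PPARG down, the strict M2 signature becomes
unsatisfiable at any fixed point, and the attractor landscape changes
wholesale (1584 fixed points, 190 unique profiles, 0% M2, computed by
`polarization_analysis(macrophage_model(dialect = "grouped"))`).  Under
standard precedence the landscape has 1384 fixed points and 214 unique
intracellular profiles with the M2-dominated category structure shown in
the README — the behaviour the model was built to exhibit, and the parse
that the mainstream Boolean-network toolchains would have applied to
these rule strings.

## Fixed-point enumeration

For each input assignment the solver:

1. clamps the inputs and propagates constants through the rules to
   closure (`condition_network()`) — with all signals off, for example,
   the whole receptor layer collapses to 0;
2. computes a feedback vertex set (FVS) of the remaining free core
   (`feedback_vertex_set()`, greedy, correctness checked by tests);
3. enumerates the `2^|FVS|` assignments of the FVS, filling in all other
   free nodes in topological order; and
4. keeps the self-consistent candidates, re-checking `F(x) = x` on every
   returned state.

For the bundled model the conditioned free core never exceeds a handful
of nodes (the default FVS of the full intracellular graph is
{STAT1, STAT3, NFKB, TNFA}-sized), so each assignment costs at most 16
candidate evaluations and the full `2^10`-assignment sweep runs in a few
seconds.  The result is provably independent of the FVS chosen; the test
suite asserts this, and validates the solver against
`brute_force_attractors()` — an exhaustive state-transition-graph oracle
— on hundreds of seeded random networks of up to ~13 nodes (the oracle
is exponential and guarded at 20 nodes).

## Supervised classification

Attractors are projected onto the 30 intracellular nodes and
deduplicated (`project_and_dedup()`); multiplicities record how many full
fixed points share a profile.  Two profiles are flagged non-biological:
the all-zero state and the all-zero-except-RAGE state (RAGE is driven
directly by the HMGB1 input, so that profile is a signalling artefact).
They are excluded from the phenotype categories but kept in the M0 count,
and percentages are reported over all deduplicated profiles; both
denominators are exposed by `summarize_categories()`.

The signatures require every clause active:

* M1: IL-12 ∧ NF-κB ∧ TNFα ∧ (STAT1 ∨ STAT5)
* M2 (strict, default): IL-10s ∧ (STAT3 ∨ STAT6) ∧ PPARγ
* NLC: TGFβ ∧ HIF1α ∧ EGF ∧ RAGE

"Active" means value 1 at the fixed point; averaged category profiles are
never thresholded back into labels.  The M2 signature binds the IL-10
marker to the secreted node IL10s, not the extracellular input IL10,
because classification happens after input removal.  A `"disjunctive"`
M2 variant — IL-10s ∧ (STAT3 ∨ STAT6 ∨ PPARγ) — is implemented because
the marker list is genuinely ambiguous; it is not the default since it
inflates M2 to ~82% of profiles and breaks the STAT6/IRF5/STAT5 knock-out
behaviour (losing STAT6 then *increases* M2 counts).  Categories are
mutually exclusive; the default `"priority"` policy resolves the rare
multi-signature profiles in the order NLC > M2 > M1 (on the bundled
model's fixed points TNFα and IL-10s are mutually exclusive, so M1/M2
overlaps cannot occur and `"strict_exclusive"` gives identical results).

## Condition semantics

`run_condition()` restricts the environment to a family of stimuli and
clamps everything else to 0.  The default `"all_subsets"` semantics pools
fixed points over *every* combination of the available stimuli, including
none of them: making a signal family "available" does not force any
member to be present.  Under this reading the M1-stimulus condition
yields 23 unique profiles (18 M0 + 5 M1), the M2 condition 7 (6 M0 +
1 M2) and the CLL condition 14 (10 M0 + 2 M2 + 2 NLC) — the presence of
NLC fixed points only under CLL signals, and of M2 states alongside
them, is the model's account of why the CLL micro-environment breeds
pro-tumoural macrophages.  `"nonempty_subsets"` and `"all_on"` are
selectable alternatives; `"all_on"` reduces to a single input assignment
and is the right tool for "everything present at once" questions.

## Perturbations

`apply_perturbation()` replaces a node's rule by a constant — 0 for a
knock-out, 1 for constitutive activation — which overrides the rule in
every state; clamp soundness is asserted over the full stimulus space.
Effect calls compare category counts of deduplicated profiles over all
`2^10` assignments between perturbed and baseline models:
`complete_loss` (baseline > 0, perturbed = 0), `decrease`, `increase`,
`unchanged`.  The "IRF4–JMJD3 axis" preset clamps both IRF4 and JMJD3 to
zero.  Three caveats, all computed by the test suite and visible in the
README output, deserve mention rather than silence:

* PPARγ knock-out abolishes M2 *completely* here, a direct logical
  consequence of PPARγ being a conjunctive M2 marker, and frees PPARγ's
  inhibition of STAT3 so that NLC counts rise.  Experimentally the loss
  is partial; a conditional knock-out cannot be expressed in two-level
  logic.
* IRF4–JMJD3 knock-out *decreases* M2 (144 → 72) rather than abolishing
  it: PPARγ and STAT6 remain activatable through IL4RA/MCSFR.
* STAT1 knock-out raises NLC counts (HIF1α is STAT1-inhibited), alongside
  the expected partial M1 loss.

## Unsupervised structure

Profile similarity uses the Jaccard–Needham measures on binary vectors:
with `S_ij` the number of positions valued `i` in the first vector and
`j` in the second,

    S = S11 / (S11 + S10 + S01),  D = (S10 + S01) / (S11 + S10 + S01).

`S + D = 1` whenever defined; for the all-zero pair (denominator 0) the
pair is treated as identical (`S = 1, D = 0`), the natural limit for the
Jaccard distance between equal vectors.  D is a metric, which the tests
check on sampled triples.

Clustering is hierarchical density-based on the precomputed distance
matrix (`hdbscan_precomputed()`): core distances from the
`min_samples`-nearest neighbour, the mutual-reachability transform, a
single-linkage hierarchy over the minimum spanning tree, condensation by
`min_cluster_size`, and excess-of-mass cluster selection, with
unabsorbed points labelled noise (0).  It is implemented in-package and
validated behaviourally on planted-partition benchmarks: datasets drawn
by `planted_clusters()` (centroids at pairwise Hamming distance ≥ L/3,
members by independent bit flips) are recovered exactly for flip
probabilities up to 0.05 when `min_cluster_size` matches the planted
cluster scale (≥ 8 members per cluster in the tests).  Cluster counts on
real attractor sets are parameter-sensitive — with the default
`min_cluster_size = 2` the 214 bundled profiles split into ~20 fine
clusters with the two non-biological states as noise — so the package
treats cluster *count* as a tunable-resolution property, and asserts
instead the resolution-robust statement that the supervised categories
map injectively onto distinct best-correlated clusters
(`category_cluster_correlation()`), M2 matching its cluster at the
highest correlation of its row.

## Synthetic generators

`random_network()` draws seeded random Boolean networks (choice of random
operator trees or random truth tables materialised as sum-of-products,
so every pipeline stage sees one expression representation); it exists to
validate the solver against the exhaustive oracle, not to imitate
biological topology.  `planted_clusters()` emulates exactly the
statistical structure the unsupervised step assumes — small
within-category, large between-category binary distance.  What passing
these tests shows is that the machinery is correct on data with planted
truth; it does not show that real attractor sets are this well separated
(the bundled model's M0 profiles, for instance, straddle the M1/M2 axis).
All generators are pure functions of their spec, seed included, and
restore the caller's RNG state.

## Numerical and engineering choices

* Deterministic orderings everywhere: inputs enumerate lexicographically,
  profile rows sort by bit pattern, cluster labels number by first
  member.  Identical configurations give byte-identical outputs.
* PCA (`pca_coordinates()`) is column-centered, unscaled, with each
  component's sign fixed by making its largest-magnitude loading
  positive.
* Zero distances are clamped at `1e-12` before taking density lambdas
  (`1/d`), so duplicate-heavy matrices cannot produce infinities.
* Degenerate inputs fail loudly: empty profile tables, constant matrices
  for PCA, `min_cluster_size < 2`, networks above the oracle/enumeration
  guards, conditioning a clamped node to the opposite value.
* Problem sizes in the tests: the solver-oracle equivalence sweeps 500
  seeded networks of 6–13 nodes with up to 2 inputs (the exhaustive
  oracle grows as `2^n`); cycle sampling uses 10^4 random initial states
  with a 100-step transient.  Both are comfortable single-CPU sizes and
  well beyond the scales at which the respective failure modes would
  show.

## Known limitations

* Two-level logic: graded phenomena (partial knock-outs, dose effects)
  are out of reach by construction.
* Cyclic attractors of the full model are only detected by sampling;
  their basins and exact census are out of scope, as is any asynchronous
  updating scheme.
* The NLC condition run yields 2 NLC profiles; configurations that
  produce more NLC states under CLL signals (e.g. the grouped PPARG
  parse) destroy the global category structure, so within this rule set
  the two results cannot be had simultaneously.
* No M2a/b/c/d sub-classification, no consensus clustering, no inference
  of rules from expression data.
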