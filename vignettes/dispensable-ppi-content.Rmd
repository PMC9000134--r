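---
title: "Estimating dispensable PPI content: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dispensable PPI content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidisp)
```

## The model and its assumptions

`ppidisp` estimates the *completely dispensable* fraction of a group of
protein–protein interactions (PPIs): the probability that a mutation
which edgetically disrupts a PPI of that group is effectively neutral.
The estimator rests on four assumptions:

1. New missense mutations fall into three fitness classes — effectively
   neutral (N), mildly deleterious (M), strongly detrimental (S) — with
   prior probabilities `prior_set()` = (0.27, 0.53, 0.20), taken from
   population-genetics estimates for human.
2. Common variants (minor allele frequency ≥ 1%) from healthy
   individuals behave like class N; Mendelian-disease variants behave
   like class M on average.
3. S-class mutations are quasi-null — they destabilize the whole
   protein rather than a single interface — so their *edgetic*
   disruption rate is ≈ 0. The edgotype engine therefore never predicts
   quasi-null; it only distinguishes edgetic from quasi-wild-type.
4. A mutation edgetically disrupts a PPI iff it sits on the interface
   mediating that PPI **and** raises the binding free energy by more
   than 0.5 kcal/mol (ΔΔG > 0.5, strict).

With per-class disruption rates P(T|N), P(T|M) measured on a mutation
cohort, total probability gives the marginal P(T), Bayes' theorem gives
the dispensable content P(N|T), and the algebraically equivalent closed
form `1/P(N|T) = 1 + (P(M)/P(N))·(P(T|M)/P(T|N))` shows the estimate
depends on the data only through the rate ratio. The package verifies
the two routes agree to 1e-12 relative tolerance.

**Confidence intervals.** The 95% CI uses the log-scale normal
approximation for a ratio of two independent proportions
(`bland_ci()`): `SE(ln r) = sqrt(1/a − 1/n1 + 1/b − 1/n2)`, z = 1.96
(configurable level). Because the closed form is monotone in the rate
ratio, ratio endpoints map directly to dispensable-content endpoints
and endpoint order is preserved. When a numerator is zero the closed
form is undefined; 0.5 is then added to all four counts and the result
flagged `corrected` (the published analyses never hit this case).

## Classifiers and their thresholds

Every transient/permanent property is a threshold rule; all
inequalities are **strict**, so a value exactly at a threshold falls to
the permanent/balanced side. This is the literal reading of "less
than the median" / "larger than the median" and makes tie behaviour
explicit and testable.

| property | statistic | rule (transient side) | default threshold |
|---|---|---|---|
| strength | binding free energy ΔG (kcal/mol) | weak iff ΔG ≥ cutoff | −25 (inclusive on the weak side) |
| temporal | Pearson r of partner profiles per time-course experiment | r < median, in a strict majority of defined experiments | dataset median |
| spatial (expression, promoter) | Pearson r across tissues | r < median | dataset median |
| balance (time) | mean abs log10 partner difference per experiment | value > median, strict majority | dataset median |
| balance (space ×2) | same, across tissues | value > median | dataset median |
| exclusivity | PPIs sharing ≥ 50% of the smaller interface | bins 0 / 1–4 / ≥5 | overlap 0.5 |

Supporting conventions, each chosen once and documented here:

* **Majority** means strictly more than half of the experiments with a
  *defined* value; undefined experiments are excluded from the
  denominator; even splits are permanent/balanced.
* **Pearson definedness** requires ≥ 5 shared defined conditions (the
  stated floor for tissue data) and non-zero variance; the same floor is
  applied to time-course experiments for consistency, which is safe
  because retained time-course experiments have ≥ 5 points by contract.
* **Zero or missing expression** values are skipped pointwise in the
  log10 differences — no pseudocount, because any pseudocount would
  inject a tunable constant the analysis never states.
* **Median** is the standard sample median (mean of the middle two for
  even counts), computed over all defined per-PPI values, pooled over
  experiments for time-course data. Derived single-value thresholds
  therefore split the labelled PPIs ~50/50 by construction, which is
  exactly what the acceptance suite asserts on synthetic data.
* **Mutual exclusivity** is stated qualitatively ("share their binding
  interface") in the source analyses; the package adopts the standard
  interface-overlap convention |intersection| / min(|A|,|B|) ≥ 0.5 on
  the shared protein, configurable via `overlap_threshold`. This is a
  documented substitute, not a published formula.

## Interactome construction rules

Interface residues are detected with the conventional 5 Å all-atom
contact rule (`compute_interface()`): a residue is interfacial iff its
minimum atom–atom distance to the other chain is ≤ 5 Å. The boundary is
read inclusively — a contact at exactly 5 Å counts — which is
immaterial for generic coordinates but is pinned down by a test. All
atoms present in the coordinate record are used (hydrogens included if
present); only ATOM records of the first MODEL are read, so
hetero/solvent records are excluded.

Template annotation (`annotate_ppi_template()`) requires each partner
to align (E ≤ 1e-5, best hit per protein–chain pair) to a *distinct*
chain of a template chain pair with ≥ 50% of that chain's interface
residues covered by the alignment's residue map (boundary inclusive);
interfaces are then re-expressed in protein coordinates through the
map.

Mutation bookkeeping follows fixed tie-break rules: deduplication by
(protein, position) keeps the first record in stable input order (the
sources do not state which duplicate survives; input order makes the
choice deterministic); the MAF boundary is inclusive (≥ 0.01); common
records sharing a position with a kept disease record are discarded.
Flank verification accepts a mutation iff the transcript window of
min(10, available) residues on each side, including the wild-type
residue, occurs at identical positions in the reference protein
sequence.

## Report precision

Printed reports round half away from zero: percentages to 1 decimal,
ratios to 2 decimals. The rate-ratio column of `format_analysis()` is
computed **from the rounded percentages** — reproducing the convention
of the published summary table, which is internally consistent at its
printed precision (e.g. 0.3/2.0 = 0.15) but not with the unrounded
ratio (0.138). Dispensable content is always computed from unrounded
proportions. One permanent-side exclusivity cell of the published table
(printed 4.0) is not reproducible from its raw counts under any
rounding convention we tried (the counts give 3.946); the regression
test therefore compares dispensable-content cells within 0.1 percentage
points while holding proportions and ratios to exact printed precision.

## What the synthetic generator emulates

`generator_config()` states a fixed world at the scale of the
Y2H-derived human structural interactome: 1,916 PPIs among 1,468
proteins, 57% weak (ΔG ≥ −25), cohorts of 1,080 common and 348 disease
mutations, 63 time-course experiments of 5–15 points, 16 tissues and
183 promoter-activity samples, interfacial ΔΔG means of 0.33 (common)
and 1.1 (disease) kcal/mol, and ground-truth disruption rates 0.003 /
0.02. Values the sources do not state were chosen once on realism
grounds and are not revisited: ΔG component means −15 ± 5 (weak) and
−35 ± 6 (strong) kcal/mol, truncated at the −25 boundary so the weak
share is exactly binomial; log10 expression noise 0.4 dex and
between-gene abundance spread 0.5 dex (typical RNA-seq scales);
interfacial fractions 0.15 / 0.25 reflecting interface enrichment of
disease variants; hub fraction 0.08 with degrees 3–9 so the
exclusivity bins 1–4 and ≥5 are both exercised.

Design choices inside the generator:

* **Toy coordinates are point clouds, not proteins.** Interface
  residues sit within 4 Å of the partner chain and all other residues
  at least 8 Å away, so the 5 Å rule is exercised with margin on both
  sides and the declared interface sets equal the geometric ones
  exactly (a tested invariant).
* **Per-pair co-expression targets come from a one-factor model.** A
  gene participates in many PPIs, so arbitrary per-pair Pearson targets
  are not jointly realisable. Each gene gets a loading λ ∈ [0, 1]; the
  pair target λ_a·λ_b and the abundance offset μ_a − μ_b are recorded
  as ground truth. The exact bivariate per-pair construction is exposed
  separately as `simulate_pair_profiles()` for contract tests. Note the
  targets live on the log scale; the classifiers correlate raw
  expression, which attenuates but preserves ranking.
* **ΔΔG draws are zero-truncated normals** (destabilizing only) with
  the class means of the config — the sources report class means, not
  shapes. Disruption status is assigned first (Bernoulli at the
  ground-truth rate) and the ΔΔG drawn conditionally above/below the
  0.5 cutoff, so realized disruption sets equal intended ones exactly
  and the analytic dispensable content
  `1/(1 + (P(M)/P(N))·(rate_d/rate_c))` is exact, not approximate.
* **Non-hub interfaces are disjoint per protein**, so mutual
  exclusivity arises only from hub proteins and a hub-free
  configuration provably yields bin "0" everywhere.
* All randomness flows from one master seed through fixed per-module
  sub-streams; regeneration is byte-identical.

A green synthetic test therefore establishes that the pipeline
machinery is self-consistent and that the estimator recovers known
rates — it does **not** establish anything about real structural
models, FoldX energetics, database quirks, or expression-data
normalization, all of which are outside the generator's world.

## Known limitations

* ΔG and ΔΔG are consumed as input tables; the package does not compute
  energies (FoldX-style calculations are external) and does not build
  homology models or run alignments.
* The interface-sharing rule behind mutual exclusivity is a documented
  convention (≥ 50% overlap of the smaller interface), not a published
  formula.
* Whether "majority of experiments" should count undefined-correlation
  experiments in the denominator is unstated; they are excluded here.
* The eligible-mutation convention for per-property totals (a mutation
  counts iff its protein has ≥ 1 group-labelled PPI) mechanically
  reproduces slightly varying published totals but is our convention,
  not an asserted fact about the source pipeline.
* The estimator assumes the two cohorts' disruption counts are
  independent binomials; hierarchical or shrinkage alternatives are out
  of scope.
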