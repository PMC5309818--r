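---
title: "Expression-weighted biomarker prediction in metabolic networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted biomarker prediction in metabolic networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timbr)
```

## The model

A genome-scale metabolic network is a stoichiometric matrix $S$ (rows
metabolites, columns reactions), flux bounds $v_{lb} \le v \le v_{ub}$,
and per-reaction boolean gene–protein–reaction (GPR) rules in which `OR`
joins redundant isozymes and `AND` joins subunits of an enzyme complex.
At steady state $Sv = 0$. Flux balance analysis (FBA) maximizes one flux
(typically a biomass pseudo-reaction, whose optimum is the specific
growth rate $\mu$, with doubling time $\ln 2 / \mu$); flux variability
analysis (FVA) reports each reaction's feasible flux interval.

TIMBR asks a different question: *how consistent are a compound's
transcriptional changes with the production of each secreted
metabolite?* For each exchangeable metabolite it computes a **global
network demand** — the minimum of a weighted flux sum subject to mass
balance, bounds, and a forced secretion rate — once under
treatment-derived weights and once under control-derived weights, and
scores the relative difference.

### From expression to weights

Per-gene log2 fold changes with FDR $q \ge 0.1$ are zeroed (the
threshold is the conventional discovery cutoff for microarray
differential expression; it is a tunable argument). The filtered values
are pushed through each reaction's GPR: `OR` nodes average their
children, so one responsive isozyme is diluted by unaffected partners and
can be cancelled by an oppositely-regulated one; `AND` nodes take the
child of largest absolute value, the subunit that most constrains the
complex. Ties at an `AND` node break toward the positive value, then the
first child — a deterministic rule that matters only on exactly
symmetric inputs. Genes without data contribute 0 inside a rule; a
reaction none of whose genes are on the platform is treated as "no data".

Default weights are 1 for biochemical and 2 for transport reactions —
transport is charged double so that parsimonious solutions do not
shuttle metabolites gratuitously — and exchange reactions take the
transport default. The weight is doubled where no gene association or no
data exists, making unannotated routes less attractive than routes whose
expression actually responded. With summarized value $r$, the two
condition weights are

$$w_{treatment} = w_{default} / 2^{r}, \qquad
  w_{control} = w_{default} \cdot 2^{r},$$

so an upregulated reaction is cheap under treatment and expensive under
control, and $w_{treatment} \cdot w_{control} = w_{default}^2$ always (a
tested invariant). Both split directions of a reversible reaction share
one weight: expression carries no directionality.

### Demands and scores

The demand LP runs on the irreversible form of the network (every
reversible column split into forward/reverse parts, all lower bounds
non-negative). Secretion of the target metabolite is forced to
$\min(100,\; 0.9\, v_{max})$ flux units, where $v_{max}$ is the
metabolite's maximum secretion rate by FVA under the same constraints
(one media object serves both the capacity probe and the demand solves);
the absolute cap keeps high-capacity metabolites comparable, the 90%
rule keeps low-capacity metabolites inside their feasible region.
Metabolites with $v_{max}$ at solver tolerance are reported
`skipped_unproducible` rather than scored.

The raw production score is the symmetric relative difference

$$p_{raw} = \frac{d_{control} - d_{treatment}}
                  {d_{control} + d_{treatment}} \in (-1, 1),$$

positive when treatment weights make production cheaper. This form is
antisymmetric under swapping the conditions, invariant to uniform
scaling of all default weights (both tested), and bounded, which makes
the subsequent z-normalization across metabolites meaningful. The
normalization uses the sample (n−1) standard deviation; with hundreds of
scored metabolites the choice against the population denominator is
numerically negligible, and a zero-variance score vector (the null case)
returns all zeros with a warning rather than NaNs. Only the optimal
demand values are contractual: flux vectors at the optimum are
degenerate in general and are returned for inspection only.

Downstream, scores feed three consumers: Pearson correlation of paired
score sets with Benjamini–Hochberg control and a three-way
positive/uncorrelated/negative call at FDR 0.1; quantile classification
(elevated at or above the upper quartile, reduced at or below the lower
— boundaries inclusive); and confusion-matrix evaluation against
experimental truth (sensitivity, specificity, Matthews correlation, with
positives = experimentally changed metabolites and predicted positives =
any non-unchanged call).

## Orthology-based GPR translation

Draft reconstruction for a second species replaces each human gene leaf
with the `OR` of its retained rat orthologues. Annotations are
aggregated across five databases (RGD, Homologene, Ensembl, KEGG,
UniProt) into a database score of 1–5; human genes with ten or more rat
partners are excluded *before* ranking (nonspecific annotations), then
pairs are ranked within each human gene by database score, then supplied
per-gene confidence, then rat id as a deterministic tie-break, and the
consensus subset keeps score ≥ 2 and rank ≤ 2 by default. Ranks are
computed on the full post-promiscuity table; computing them after the
database-score cut is the documented alternative ordering should exact
reproduction of published pair counts require it. Per-gene confidence
scores are consumed as a supplied ordinal column — their derivation
depends on external database snapshots and is not recomputed here.

Losses are never silent: an unmapped isozyme is dropped from its `OR`
(`isozyme_dropped`), an unmapped complex subunit degrades the `AND`
gracefully to its mapped subunits (`broken_complex` — deleting the
reaction would overstate species differences; the report surfaces these
for manual curation), and a fully unmapped rule becomes the empty rule
with an `orphaned` flag.

## The LP engine

Every optimization in the package is the same bounded LP, solved by a
bounded-variable two-phase primal simplex implemented in `R/simplex.R`
(dense refactorization each iteration, Bland's smallest-index rule for
the degenerate bases that flux cones produce routinely). Feasibility
uses tolerance 1e-9; downstream assertions hold results to 1e-6.
Infinite bounds are capped at $10^6$ flux units and an optimum riding a
cap is reported `"unbounded"`; infeasibility is detected by a positive
phase-1 optimum. The solver is cross-checked in the test suite against
an independent interior-point/HiGHS solver on random objectives over
fixture networks and against hand-enumerable path oracles.

Metabolic tasks close **every** exchange and open only the task's
inputs (uptake allowances, positive = consumption) and outputs
(secretion requirements); feasibility of the resulting LP is the task
outcome, and `should_fail` inverts it so that known incapabilities (a
species lacking an enzyme) pass when infeasible. Unlisted byproducts may
not leave the system — the stricter reading, chosen so that a task
certifies a complete conversion; relaxing it is a one-line media change
for sensitivity analysis.

## Inborn-error biomarker prediction

Under open-exchange media (12 configurable inorganic ions uptaken
freely, every other exchange limited to −1 arbitrary uptake units,
secretion unconstrained), the reactions disabled by an IEM's causal
genes are found by boolean GPR evaluation. The healthy condition forces
each affected reaction to ≥ 90% of its maximum feasible flux — for
reversible reactions the direction of larger absolute optimum, a choice
the range comparison needs because forcing both directions is
contradictory; the disease condition closes them. All affected reactions
are forced simultaneously by default (`simultaneous = FALSE` evaluates
them one at a time and combines by majority call). Biomarker exchanges
are compared by FVA interval midpoint sums: elevated when
$(min_d + max_d) - (min_h + max_h)$ exceeds
$\tau = 10^{-6}\max(1, |max_h|)$, reduced below $-\tau$, else unchanged
— a statistic that responds to a shift of either bound and is symmetric
in the two bounds. Cases whose forced-healthy LP is infeasible are
reported unevaluable, never guessed.

## Fixtures: what they do and do not show

The fixture generator builds compartmentalized toy networks — parallel
gene-associated pathways from uptake to secretion plus a biomass sink —
with GPR shapes drawn from a profile (single gene, isozyme pair, complex
pair, nested), reversibility by probability, and flux units on the
physiological fmol·cell⁻¹·h⁻¹ scale with uptake bounds of 10 so the
$\min(100, 0.9 v_{max})$ rule exercises both branches. Generation uses a
private seeded Mersenne-Twister stream (the caller's RNG state is
untouched) and is byte-reproducible. Species-delta pairs share every
metabolite and exchange and differ by named reactions present in one
network only, emulating a species-specific enzyme over a shared
namespace.

Planted-expression tables mark every gene on one minimal producing
pathway of a target metabolite as significantly changed (±effect,
default |log2fc| = 2 — a strong but routinely observed transcriptional
response — at q = 0.01) against an insignificant
$\mathcal{N}(0, 0.25)$ background at q = 0.5. The recovery property —
the target ranks strictly first under planted upregulation and strictly
last under downregulation — holds across seeded fixtures and is the
package's parameter-recovery acceptance check.

Fixtures are topological: they have no elemental mass balance, no
thermodynamics, and pathway overlap far sparser than a real GENRE. A
passing suite therefore certifies the algorithmic contracts (LP
correctness, weight algebra, score normalization, task semantics), not
predictive accuracy on biological data, which requires the published
genome-scale models and expression compendia as inputs.

## Problem sizes and runtime choices

The test suite and acceptance script run networks of 10–40 reactions,
20 planted-recovery fixtures, 10⁴ weight-reciprocity draws and
286-length score vectors — sizes at which the dense simplex solves each
LP in milliseconds and the whole acceptance run completes in seconds.
Genome-scale models (thousands of reactions) load and compute through
the same code paths but would benefit from a sparse factorized LP
backend; swapping one in behind `solve_lp()` is the intended extension
point.

## Known limitations

- No loopless FBA, thermodynamic constraints, or flux sampling; demands
  can in principle route through stoichiometrically balanced cycles that
  carry weight but no physiology (the weighted minimization itself
  discourages them).
- The dense simplex is not tuned for genome-scale models.
- SBML support targets Level 3 + FBC v2 (the dialect modern
  constraint-based tools write); legacy COBRA note-style GPRs are not
  parsed.
- Identifiers serialized to SBML are restricted to `[A-Za-z0-9_]`.
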