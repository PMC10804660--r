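---
title: "Personalized driver-gene prioritization: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized driver-gene prioritization: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverprop)
```

## The problem

Cancer cohorts are heterogeneous: the genes driving one patient's tumour
need not drive another's. Population-level driver detection (recurrence of
mutations across a cohort) misses drivers that are rare at the cohort
level but decisive for an individual. `driverprop` prioritizes driver
genes *per patient* using only a cohort tumour expression matrix and a
reference interactome — no mutation data is required for scoring (a
mutation table is used only to flag *rare* drivers afterwards).

The method has four stages, each exposed as package functions and
orchestrated by `run_pipeline()`.

## Stage 1: personalized gene interaction networks

For a focal patient $p$, two co-expression networks are built over the
genes shared by the expression matrix and the reference interactome:

* $G_1$: all $m$ patients. For each candidate gene pair, the Pearson
  correlation $r$ and its two-sided p-value from
  $t = r\sqrt{(m-2)/(1-r^2)}$ with $m-2$ degrees of freedom; the pair is
  an edge iff $p < \alpha_{\text{edge}}$ (default 0.05, raw — no
  multiple-testing correction, since the threshold acts as a per-edge
  screen, not an inference).
* $G_2$: the same construction with patient $p$'s column removed.

The personalized network is the symmetric difference restricted to the
reference interactome:

$$E(G_p) \;=\; \big(E(G_1)\,\triangle\,E(G_2)\big)\;\cap\; E(G_{\text{ref}}).$$

An edge survives exactly when the presence of patient $p$ tips its
correlation across the significance boundary — in either direction; each
edge carries a provenance tag recording which side contributed it.
Edges significant in both networks are uninformative about $p$ and are
removed; edges unsupported by the interactome are treated as noise.

Design notes:

* The "significantly different correlation" rule is realized as per-network
  significance followed by the set difference, not as a z-test on the
  difference of two correlations; this matches the stage order above
  (build $G_1$, build $G_2$, keep edges in exactly one). `alpha_edge`
  remains configurable for sensitivity analysis.
* $G_1$ is cohort-wide, not per-patient: a single patient's column admits
  no correlation estimate, so the only coherent reading of the
  "with-the-patient" network is the all-patients network, which changes
  per patient only through the complementary $G_2$.
* Zero-variance genes participate in no edges (rather than propagating
  `NaN` correlations).
* The pair scan is restricted to reference pairs by default
  (`restrict_pairs = TRUE`). Because the final edge set is intersected
  with the reference anyway, this is an exact optimization, verified in
  the tests by comparing both code paths and an independent brute-force
  recomputation (nested-loop `cor.test` plus explicit set algebra).

## Stage 2: candidate drivers by maximum matching

$G_p$ is transformed into its node–edge bipartite graph: genes on the
left, the network's edges on the right, a gene linked to every edge it is
an endpoint of (so every right node has exactly two left neighbours).
With unit weights on all incidences, a maximum matching

$$\max \sum_{(v,u)} x_{v,u} W_{v,u}, \qquad
  \sum_{u} x_{v,u} \le 1 \;\forall v, \quad
  \sum_{v} x_{v,u} \le 1 \;\forall u, \quad x \ge 0$$

assigns each matched interaction a distinct responsible gene; the matched
genes cover a maximum number of the patient's perturbed interactions and
are taken as the patient's candidate drivers. The per-node constraints are
inequalities (the standard matching polytope): an equality on the left
side would be infeasible whenever a gene is isolated or genes outnumber
edges. By total unimodularity the LP relaxation is integral, which the
test suite checks empirically against an external LP solver.

With all weights equal, maximum weight coincides with maximum
cardinality, so the implementation uses a deterministic augmenting-path
search (Kuhn's algorithm) rather than a general assignment solver: right
nodes are processed in sorted order and left neighbours scanned in sorted
order. The tie-break matters — different maximum matchings select
different gene sets, and everything downstream depends on which genes are
matched — so it is fixed rather than left to solver internals. A
non-unit-weight mode (for weighted interactomes) is available behind the
same interface.

Stacking the matched gene sets of all patients gives the binary
gene–patient association matrix $M$ (`assemble_associations()`), with one
row per gene ever matched; genes never matched are excluded rather than
kept as all-zero rows, because a zero row has no meaningful
nearest-neighbour geometry in the next stage.

## Stage 3: linear-neighborhood label propagation

Each gene's row $y_i \in \{0,1\}^m$ of $M$ is reconstructed from its $k$
nearest neighbours (Euclidean distance; on binary rows this is Hamming
distance up to a square root, matching the squared-error objective below;
distance ties are broken by gene symbol). The reconstruction weights
solve, per gene, the simplex-constrained quadratic program

$$\min_{w}\; w^\top (G^i + \gamma I)\, w
  \qquad \text{s.t. } \textstyle\sum_j w_j = 1,\; w \ge 0,$$

with $G^i_{jl} = (y_i - y_{i_j})^\top (y_i - y_{i_l})$ the local Gram
matrix and $\gamma$ (default 1) a Tikhonov ridge that keeps the problem
strictly convex and damps degenerate neighbourhoods (identical
neighbours give uniform weights). The solver is a small exact active-set
method written for this structure: on the current support the
equality-constrained KKT system is solved directly, variables driven
negative are clamped, and clamped variables with negative multipliers are
released; for a positive-definite Hessian this terminates at the exact
optimum, and the tests confirm agreement with a dense grid search over
the simplex.

The weights form the row-stochastic similarity matrix $S$ ($S_{ij} =
w_{ij}$ for neighbours, 0 elsewhere; zero diagonal, at most $k$ nonzeros
per row). $S$ is *not* symmetric — neighbourhoods are directional — and
propagation uses it as-is, which is the exact algebra of the
reconstruction model; a symmetrized variant is available behind a flag
for exploration. One consequence worth knowing: column sums of the score
matrix are conserved only when $S$ happens to be column-stochastic too
(e.g. mutual nearest neighbours); in general propagation redistributes
mass toward frequently-chosen neighbours, which is intended — such genes
are similar to many others and accumulate evidence.

Scores diffuse over $S$:

$$F^{(t+1)} = \alpha S F^{(t)} + (1-\alpha) F^{(0)}, \qquad
  F^{*} = (1-\alpha)(I - \alpha S)^{-1} F^{(0)},$$

with $F^{(0)} = M$. The closed form is computed by a sparse linear solve
of $(I-\alpha S)F^* = (1-\alpha)F^0$ (never an explicit inverse); the
truncated iteration is available as `mode = "iterative"` for very large
gene sets, and the two agree entrywise to well below $10^{-6}$ by
contract. For $0 \le \alpha < 1$ and row-stochastic $S$ the spectral
radius of $\alpha S$ is below 1, so the fixed point exists and is unique;
$\alpha \ge 1$ is rejected.

Parameters:

* $\alpha$ (default 0.5): the share of a gene's score received from its
  neighbours versus its own initial label. 0.5 weighs both equally and is
  the default operating point; `run_pipeline(alpha = ...)` exposes it.
* $k$: the neighbourhood size has no single principled value for binary
  association profiles. The default $k = \min(n-1, \lceil 0.1\,n\rceil)$
  is a small fractional neighbourhood in the tradition of locally linear
  reconstruction methods; it is recorded in the run manifest and echoed
  by the CLI precisely because results are sensitive to it.
* $\gamma$ (default 1): any positive value guarantees strict convexity;
  1 leaves the Gram and ridge terms on comparable scales for binary rows.

## Stage 4: calls, evaluation, rare drivers

Per patient, genes are ranked by $F^*$ (rank 1 = highest, ties by gene
symbol so ranks are reproducible). A gene is a **cohort driver** when it
appears in the top-`top_n` list (default 100) of *strictly more than*
`recurrence` (default 0.8) of patients. "Appearing" is defined on the
top-$N$ window rather than on raw matchings or nonzero scores: the
propagated matrix is dense, so some finite window is needed, and the
top-100 window is also the natural candidate set used for rare-driver
flagging. Both knobs are exposed.

Against a benchmark catalogue, `f_measure()` reports
$\mathrm{precision} = |P \cap B|/|P|$,
$\mathrm{recall} = |P \cap B|/|B|$, and their harmonic mean (0 when both
vanish). Predicted genes outside the benchmark universe still count in
precision's denominator; matching is exact, case-sensitive symbol
equality throughout the package — no alias or identifier mapping is
attempted, because silent symbol translation is a larger correctness risk
than requiring consistently-labelled inputs.

A **rare driver** record is any (patient, gene) pair where the gene is
mutated somewhere in the cohort but in at most 5% of patients, and ranks
within the patient's top 100.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed. It emulates the one
feature of real cohorts this method exploits — per-patient disruption of
co-expression — and deliberately nothing else:

* Background genes are i.i.d. standard normal per patient.
* Each planted driver is the hub of a module whose genes share a latent
  per-patient factor, giving within-module correlation `base_corr`
  (default 0.8) at `noise_sd = 1`.
* For each driver, a subset of patients has the *hub's* expression
  resampled independently — decoupling the driver from its partners in
  exactly those patients. Decoupling (rather than a mean shift) is the
  right perturbation because the pipeline detects correlation-structure
  change, not differential expression; and the hub (rather than the whole
  module) is decoupled so that the planted signal sits on driver-incident
  edges while partner–partner correlations stay intact.
* The default number of decoupled patients per driver is
  $\lceil m\,(1 - r_{\text{crit}}/\rho)\rceil$, where $r_{\text{crit}}$
  is the correlation whose t-test p-value equals 0.05 at $m$ samples and
  $\rho$ = `base_corr` (17 of 30 at the defaults). This places the
  contaminated cohort-level driver–partner correlation at the edge of
  significance — the regime where a single patient's inclusion genuinely
  tips the call, which is the signal the leave-one-out construction is
  built to detect. Far fewer decoupled patients leave driver edges
  stably significant (nothing to detect); far more leave them stably
  insignificant.
* The reference network contains all within-module edges plus an equal
  number of random decoy edges among background genes, so the
  reference-refinement step does real work.
* Mutations: each decoupled (patient, driver) pair is mutated with
  probability 0.5, plus 1% background noise.

What passing tests on this generator do **not** show: robustness to
RNA-seq count noise (library size, overdispersion), to batch effects, to
identifier mismatches between expression data and interactome, or to the
much larger and sparser geometry of genome-scale cohorts. The generator
plants exactly the signal class the method targets; real-data performance
depends on how much of that signal class real tumours exhibit.

## Numerical choices and degenerate inputs

* Correlation p-values use the exact t distribution; $|r| = 1$ maps to
  $p = 0$ (edge present at any threshold).
* Fewer than 3 included patients is an error (the t-test is undefined).
* Empty personalized networks yield empty matchings; a cohort where
  *every* matching is empty aborts the pipeline (there is nothing to
  propagate).
* All orderings that could affect output are pinned: canonical edge
  orientation (`gene_i < gene_j`), sorted patient processing, sorted
  matching tie-breaks, gene-symbol rank tie-breaks. Two runs with the
  same inputs, parameters and seed are byte-identical, and the run
  manifest (parameters, input hashes, reference-sample set) suffices to
  reproduce a run.
* The iterative propagation tolerance is $10^{-8}$ (max-abs change) with
  a 1000-iteration cap; at $\alpha = 0.5$ convergence is geometric and
  the cap is never reached in practice.

## Validation scale

The test suite validates each stage against an independent oracle at
sizes where exhaustive recomputation is feasible: matching against
exhaustive enumeration on 200 random networks of up to 8 genes and 10
edges (plus LP-relaxation integrality on the same instances);
reconstruction weights against a dense simplex grid on 50 association
matrices of up to 40 genes with $k \le 3$; personalized networks against
nested-loop recomputation on cohorts of up to 50 genes and 30 patients;
and end-to-end planted-driver recovery on ten seeded default cohorts
(60 genes, 30 patients, 3 drivers). These sizes exercise every code path
of the algorithms, whose behaviour does not change qualitatively with
scale; the same functions accept genome-scale inputs, where the
correlation scan over reference pairs dominates the cost.

## Known limitations

* Expression is used as supplied; no normalization, log-transformation or
  QC is performed or checked.
* Gene identity is the raw symbol string; mismatched vocabularies between
  inputs silently shrink the gene universe (by design — see above).
* The cohort-driver rule depends on `top_n` relative to the number of
  scored genes: when fewer genes are scored than `top_n`, every scored
  gene is in every patient's window and the recurrence filter is
  vacuous. At genome scale this does not arise; on small cohorts,
  set `top_n` below the scored-gene count.
* The LP-relaxation equivalence and matching-oracle checks are empirical
  (finite instance families), complementing — not replacing — the
  structural guarantees of bipartite matching theory.
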