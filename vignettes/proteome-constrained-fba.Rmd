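---
title: "Proteome-constrained flux balance analysis with proflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-constrained flux balance analysis with proflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proflux)
```

## The model

A constraint-based metabolic model describes a metabolic network by its
stoichiometric matrix $S$ (metabolites $\times$ reactions). At steady
state the flux vector $v$ satisfies $Sv = 0$ with per-reaction bounds
$L_i \le v_i \le U_i$. Flux balance analysis (FBA) selects, from this
feasible set, a flux state maximizing a cellular objective — here
biomass production:

$$\max_v \; Z = C'v \quad \text{s.t.} \quad Sv = 0,\; L \le v \le U,$$

where $C'$ is the row of objective coefficients (nonzero on the biomass
reaction). The optimum $Z^\ast$ is typically attained by many
alternative flux distributions; `proflux` resolves this degeneracy with
a second, parsimonious stage (pFBA) that assumes the cell meets its
objective with the least total enzymatic resource:

$$\min_v \sum_i |v_i| \quad \text{s.t.} \quad Sv = 0,\; L \le v \le U,\;
C'v \ge \gamma Z^\ast,$$

linearized by the standard split $v = v^+ - v^-$, $v^\pm \ge 0$. With
$\gamma = 1$ (the default) the biomass constraint is relaxed by a
relative $10^{-9}$ so solver round-off in $Z^\ast$ cannot render the
second stage infeasible. Note that $L_1$ minimality itself does not
guarantee a unique $v$ on every network; the deterministic solver
(fixed variable order, single thread) makes repeated runs agree
exactly, which is the reproducibility property the pipeline needs.

## Expression constraints

Proteome integration follows the E-flux idea: the more enzyme is
present, the more flux its reaction may carry. Each reaction carries a
gene–protein–reaction (GPR) Boolean rule; `evaluate_gpr()` scores it
against a per-condition expression map with

* `and` (complex subunits) $\to$ **min** of the subunit levels,
* `or` (isoenzymes) $\to$ **max** of the branch levels.

A reaction whose rule evaluates to a measured level $p$ gets bounds
$[-p, +p]$ if reversible and $[0, +p]$ if irreversible; reactions with
no rule, or whose rule is unmeasured, keep the model's default bounds
(conventionally $\pm 1000$ flux units; flux units are arbitrary,
mmol·gDW$^{-1}$·h$^{-1}$ implied).

Three details were genuinely open and are settled as follows:

* **Partially measured rules** (`missing_policy`): by default
  (`"unbounded"`) an unmeasured gene makes an `and` complex unmeasured
  (the constraint is dropped — we refuse to guess a complex's abundance
  from a subset of subunits), while under `or` an unmeasured branch is
  simply ignored when a measured sibling exists, since discarding a
  measured isoenzyme would throw away evidence. `"zero"` (missing =
  absent) and `"ignore"` (score only the measured part) are available;
  `"zero"` is what gene-level knockouts use.
* **Bound replacement vs intersection**: expression bounds *replace*
  the defaults outright, which is the literal reading of the mapping
  above; `cap_at_default = TRUE` intersects instead, preventing a large
  expression level from widening a physically motivated default.
* **Scale**: expression levels are used as bound magnitudes directly
  (`scale = 1`); the proportionality constant between normalized
  intensity and flux capacity is not identifiable from the data the
  pipeline sees, so it is exposed as a parameter rather than estimated.

## Differential expression

`select_de()` implements the two-part rule used to pick which proteins
constrain the model: $|\log_2 \mathrm{FC}| > 1.2$ *and* Welch two-sample
t-test $p < 0.05$ on replicate intensities. The threshold is read on the
log2 scale as written, applied two-sided (both directions are
reported), and no multiple-testing correction is applied by default to
match the raw-p rule; a Benjamini–Hochberg option exists
(`p_adjust = "BH"`). Normalization (`normalize_proteome()`) rescales
every replicate column so a column statistic (total intensity by
default, median optionally) equals the smallest column's — scaling down
to the least intense run, so factors never exceed 1.

## Mutants

In silico knockout sets both bounds of the targeted reactions to zero;
overexpression multiplies both bounds by a factor, 2 by default (a
doubling of catalytic capacity in both directions). These are
reaction-level edits on the bound set; a gene-level convenience
(`knockout_genes()`) zeroes genes in the expression map so the edit
propagates through the Boolean rules.

## Comparative flux analysis

To compare two conditions, each distribution's strictly positive fluxes
are $\log_2$-transformed and divided by the standard deviation of that
dataset's log-fluxes (each dataset is normalized with its own SD,
before pairing); the per-reaction fold change is the difference of the
transformed values. Fluxes $\le 0$ have no log transform; they carry
their original value and form a separate `nonpositive` class (the gray
class on map overlays), excluded from the numeric comparison.

The significance cut-off is data-driven: the smallest candidate $c$ on
a grid (0.001 steps from 0 to $\max |fc|$, the end point included) such
that the fraction of reactions with $|fc| > c$ stays below 30% of the
total. Exceedance uses a strict inequality, consistent with the
classification rule (`up` $\Leftrightarrow fc > c$); since the
exceedance fraction is non-increasing in $c$, the minimal candidate is
well defined, and classifications made at the selected cut-off can
never exceed the 30% cap. The cut-off returned on real data is a
property of the flux distributions and the grid; it is not an exactly
reproducible universal constant.

`pathway_summary()` aggregates classes per subsystem and per category
tag (`carbon`, `nitrogen`, `anabolic`, `catabolic`, `exchange`). The
C/N ratio — the affected proportion among carbon-tagged reactions over
that among nitrogen-tagged ones — summarizes which side of central
metabolism a perturbation hits harder; the inverse is reported
alongside, and both are `NA` when a denominator vanishes.
`kegg_export()` writes the two-column colour file the KEGG Mapper
"Color" tool accepts (blue/red/lightgreen/gray); rendering the maps is
out of scope.

## The LP solver

No dedicated linear-programming package is required: `proflux` carries
a small dense two-phase primal simplex (Bland's anti-cycling rule,
explicit slack/surplus columns, variables shifted to nonnegativity,
bound-pinned variables substituted out). Bland's rule gives
unconditional termination and the fixed pivot order gives bitwise
reproducibility. Tolerances: $10^{-9}$ on primal feasibility and
reduced costs, $10^{-6}$ relative for solution comparisons. All
variable bounds must be finite — models carry finite defaults — so
unboundedness cannot arise in practice; the status is still reported if
it does. The solver is validated in the test suite against an
independent LP method (`pracma::linprog`) on over a hundred randomly
generated networks, and against hand-solved LPs.

## Synthetic data: what it emulates, and what not

`make_toy_model()` composes motifs with known optima: a capped uptake
exchange (the analytic biomass optimum equals the cap), a linear
conversion chain feeding the biomass sink, two-reaction detours
parallel to chain steps (the parsimonious stage must route around
them: the minimal total flux is `cap * (chain length + 2)`), and
futile three-reaction loops (whose flux the $L_1$ stage must zero).
Chain reactions exercise both Boolean operators (`and` complex, `or`
isoenzymes, single genes) and carry carbon/catabolic annotations;
detours are nitrogen/anabolic, so pathway summaries have structure to
count.

`make_proteome()` draws replicate intensities log-normally —
$\mathrm{mean} \times 2^{\mathcal{N}(0, \sigma)}$ with $\sigma$ on the
log2 scale — and shifts DE proteins' means by $2^{\text{shift}}$ in
every non-control condition. Defaults encode the study conditions the
pipeline is exercised under: 3 replicates, baseline mean 20 (twice the
uptake cap, so control bounds are non-limiting), noise $\sigma = 0.2$
(≈15% CV, typical of quantitative intensity proteomics), and a $-2$
log2 shift (4-fold downregulation) of the biomass-path genes in the
stress condition. Under these conditions the stress proteome must
produce a lower simulated biomass than the control — the qualitative
growth-temperature narrative the pipeline exists to reproduce.

What the generator does **not** emulate: peptide-level artifacts,
missing values, correlated protein noise, genome-scale network size
(thousands of reactions), thermodynamic infeasibilities, or regulatory
effects beyond abundance. Passing tests therefore demonstrate the
correctness of the algorithms and their contracts, not predictive
accuracy on a real genome-scale model and proteome.

## Numerical and degenerate-input choices

* Knocked-out (zero-width) variables are substituted out of the LP
  before the simplex runs.
* A dataset whose positive fluxes have zero or undefined log-SD (fewer
  than two distinct positive fluxes) uses SD = 1 with a warning — on
  tiny networks every flux can sit at the same vertex value.
* An all-nonpositive flux vector yields an empty transformed set with a
  warning, not an error.
* Proteins missing from a condition, or with fewer than two replicates,
  are excluded from fold changes / tests with a message or warning.
* `determine_cutoff()` errors when no finite fold change exists and
  when no grid candidate satisfies the cap (extend the grid).
* Model validation reports problems (`validate_model()`) instead of
  raising; loaders raise only on files that fail validation outright.

## Problem sizes in the test suite

The suite runs on networks of roughly 6–13 reactions (where LP optima
are analytically known or enumerable), 100-network random sweeps for
solver equivalence, a 200-protein DE benchmark, all ~2,600 GPR trees of
depth ≤ 3 over four genes against a brute-force evaluator, and 1,000
random fold-change vectors for the cut-off guarantee. These sizes make
every expected value independently checkable; the algorithms themselves
are size-agnostic (the LP is dense, so models beyond a few hundred
reactions would want a sparse solver backend).

## Known limitations

* The dense tableau simplex targets small and medium problems; it is
  not a genome-scale production solver.
* SBML support is a documented fbc-style subset (bounds as parameters,
  one maximize objective, nested gene-product associations, annotations
  in notes); identifiers must be alphanumeric/underscore. The JSON
  dialect is the canonical lossless format.
* The L1-minimal flux distribution need not be unique; only
  reproducibility (determinism), not uniqueness, is guaranteed.
* Compartments are carried as tags and play no role in the mass
  balance.
* Gene-level knockouts are a convenience on top of reaction-level bound
  edits; no GPR re-evaluation semantics beyond "level 0" is implied.
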