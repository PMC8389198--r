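---
title: "Constraint-based analysis with reduced metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis with reduced metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redgem)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The steady-state flux polytope

A constraint-based metabolic model is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with flux bounds. Under the
pseudo-steady-state assumption the net production and consumption of every
internal metabolite is zero, so the feasible set is the polytope

$$P = \{\, v : S v = 0,\ lb \le v \le ub \,\},$$

with fluxes in mmol·gDCW$^{-1}$·h$^{-1}$ and the growth reaction in
h$^{-1}$. Exchange reactions cross the system boundary and touch exactly
one metabolite; uptake is negative flux by convention, so a measured
glycerol uptake of 0.182 mmol·gDCW$^{-1}$·h$^{-1}$ enters as a lower bound
of $-0.182$ on `EX_glyc`. The assumption is reasonable whenever the
physiological state changes slowly relative to metabolic turnover — e.g.
between consecutive sampling points of a cultivation with a roughly
constant growth rate — and it is what makes linear programming applicable.

## FBA, the LP core, and shadow prices

`fba()` maximizes one flux over $P$. Because no linear-programming package
with dual output is available to depend on, the package carries its own LP
core (`lp_solve()`): a bounded-variable two-phase primal simplex with
Bland's rule for both entering and leaving variables, so degenerate
problems terminate. It returns the optimal basis' row duals and reduced
costs and, as a self-check, the Lagrangian dual objective; every optimal
solve satisfies strong duality to well below $10^{-6}$. Solver tolerances:
reduced-cost optimality $10^{-9}$, pivot threshold $10^{-10}$, phase-1
feasibility $10^{-7}$. Verification thresholds in the test suite are
$10^{-6}$. Dense linear algebra is used deliberately: the package targets
reduced models (hundreds of reactions at most) and toy fixtures, not
genome-scale LPs with tens of thousands of columns.

The **shadow price** of metabolite $i$ is the dual of its mass-balance row,
reported as $\lambda_i = \partial Z^*/\partial b_i$ where $b_i$ perturbs
$S_i v = b_i$. Supplying the cell with a free amount $\varepsilon$ of the
metabolite corresponds to $b_i = -\varepsilon$, so the optimum changes by
$-\lambda_i \varepsilon$ and the interpretation rules read off the sign
directly: negative = limiting, zero = insensitive, positive = surplus.
Commercial solvers differ in the sign they report; the `raw_duals` field
makes the provenance explicit. Two caveats are documented rather than hidden:

- At **degenerate optima** the dual solution is not unique, and which
  vertex of the dual polytope the simplex reports is an implementation
  accident. The suite therefore asserts dual values only on non-degenerate
  fixtures. A dead-end metabolite is the extreme case: its balance row
  admits a whole half-line of dual values, so "off-pathway" insensitivity
  is tested on a bystander metabolite with its own reversible exchange,
  which provably has price zero.
- After `two_step_fba()` the reported shadow prices are the **step-1**
  duals: the quantity of scientific interest is the sensitivity of the
  production objective, not of the flux norm. `shadow_price_step = 2`
  switches this for users who want the norm LP's duals.

## Two-step optimization

`two_step_fba()` fixes the objective at its maximum $Z^*$ and minimizes
$\sum_j |v_j|$ using the split-variable reformulation $v = v^+ - v^-$ with
$v^+ \in [\max(0, lb), \max(0, ub)]$ and $v^- \in [\max(0,-ub),
\max(0,-lb)]$, which reproduces the original box exactly and needs only one
extra constraint row. The norm covers the *whole* flux vector, exchanges
included: in scenario-constrained use the exchanges are pinned by
measurement bounds, so their inclusion cannot distort the intracellular
distribution, and a single convention is easier to reason about
(`include_exchanges = FALSE` is available). If fixing the objective at
exactly $Z^*$ is infeasible through floating-point round-off, the step-2 LP
is retried at $Z^*(1 - 10^{-9})$ and the retry is messaged.

## FVA, sampling, and condition comparison

`fva()` solves two LPs per reaction subject to the objective staying at or
above `fraction_of_optimum` $\cdot Z^*$; the default fraction is 1, the
setting that corresponds to whiskers around a reported optimal flux
distribution.

`chrr_sample()` samples $P$ near-uniformly:

1. $P$ is parameterized by an orthonormal null-space basis of $S$ (complete
   QR of $S^\top$), so every sample satisfies $S v = 0$ to machine
   precision by construction.
2. The warm-up set is the $2n$ FVA extreme points — the points that attain
   each reaction's minimum and maximum — whose affine hull spans the
   polytope in practice.
3. The rounding transform is the symmetric eigenvalue factorization
   $V \sqrt{\Lambda}$ of the warm-up covariance. This is deliberately
   simpler than the maximum-volume-ellipsoid rounding of the original CHRR
   formulation: at reduced-model scale the covariance factorization is an
   adequate preconditioner, and it needs no optimization machinery.
   Zero-width eigendirections — which arise whenever a scenario pins a
   reaction with a hard equality such as the measured growth rate — are
   dropped from the walk rather than wasting steps on them; a fully
   degenerate covariance falls back to the identity with a warning.
4. Coordinate hit-and-run runs in the rounded space: pick a coordinate,
   intersect the line with the box constraints to get a chord, draw the
   step uniformly on the chord, and keep every `steps_per_point`-th state.

Default configuration is 5000 returned points with 1848 steps per point,
the density customary for characterizing metabolic flux spaces; the test
suite and examples run at 500 points / 100 steps, which is enough for the
properties asserted there. A single seeded generator drives the chain, the
seed is recorded in the sample object, and runs are bit-reproducible; the
caller's RNG state is saved and restored.

Two conditions are compared per reaction with the two-group Kruskal–Wallis
rank test (tie-corrected $H$, $\chi^2_1$ p-value) at the conventional
$p < 0.001$ cutoff, exactly two groups because the workflow contrasts two
cultivation phases. Raw p-values are reported alongside a
Benjamini–Hochberg column so users can apply multiplicity control; the
significance flag follows the raw cutoff, matching how such comparisons
are customarily annotated. Identical constant columns are defined to give
$H = 0$, $p = 1$.

One statistical note: the Kolmogorov–Smirnov uniformity property of the
sampler is a *stochastic* bound. At 500 points the KS statistic of an
exactly uniform sample exceeds 0.05 in roughly a fifth of runs; the
acceptance script therefore evaluates it at 5000 points, where the bound
holds with overwhelming probability, while the fixed-seed test uses the
scaled-down setting.

## Model reduction

The reduction toolchain mirrors bottom-up curation practice:

- **Dead ends** (`find_dead_end_metabolites()`): metabolites lacking either
  a producer or a consumer, reversibility counting as both. **Blocked
  reactions** (`find_blocked_reactions()`): FVA min and max both within
  tolerance of zero with all exchanges opened. The shared tolerance default
  is $10^{-9}$, comfortably above LP round-off and far below any
  biologically meaningful flux.
- **`prune()`** keeps chosen subsystems (plus protected reactions), then
  iterates dead-end and blocked removal to a fixed point. The objective is
  shielded from the iterative sweeps, but a subsystem selection that would
  discard it is an error rather than a silent rescue. Pruning is
  idempotent, and every pass is recorded in a replayable log
  (`replay_reduction_log()` reproduces the output exactly).
- **Biomass precursors** (`check_biomass_precursors()`): each substrate of
  the biomass reaction gets a temporary maximized sink; unproducible ones
  can be dropped with `drop_unproducible_precursors()`. Coefficients are
  *not* renormalized after a drop: the dropped precursors are by
  construction minor contributors, and rescaling the survivors would
  distort the growth yield more than the removal does.
- **Gap filling** (`gap_fill()`) is a greedy heuristic — repeatedly add the
  candidate that newly enables the most targets, ties broken by pool order —
  not an exact MILP. Curation-scale gaps are few and shallow; greedy keeps
  the implementation solver-light, and sufficiency (all targets producible
  afterwards) is asserted, not assumed.
- **TICs** (`detect_tics()`): with every exchange closed, any remaining
  flux capability is a thermodynamically infeasible circulation. Implicated
  reactions are found by closed-system FVA, and loops are grouped as
  connected supports of actual circulations. `correct_tics()` restricts
  directionality using user-supplied standard Gibbs-energy estimates with a
  dead band of $\pm 5$ kJ/mol — the order of typical estimation
  uncertainties — leaving in-band or evidence-less members unresolved, and
  reverting any correction that would make the model infeasible. Transport
  reactions go through the same machinery; they need no special class.

## Validation against measured rates

`validate_scenario()` applies a scenario (hard growth; measured uptakes as
lower bounds; measured secretions as upper bounds), runs `two_step_fba()`,
and reports $SE_i = (X_i - \hat X_i)^2$ per flux and
$MSE = \frac{1}{p}\sum SE_i$ over the $p$ fluxes with experimental values
(`NA` rows are excluded from $p$). Both the mean and the plain sum (SSE)
are reported because published per-scenario aggregates are sometimes sums;
the package computes both and corrects neither. Reported measurement
uncertainties are carried as metadata, not folded into SE.

## The synthetic generator and what passing tests mean

`generate_toy_network()` emulates, at 14 reactions, the architecture of a
reduced central-carbon + secondary-metabolite network: glycerol uptake →
glycolysis chain → C3 node; a TCA-like cycle with a glyoxylate-shunt
analog; anaplerotic carboxylation; a lumped amino-acid branch; and a
product branch condensing a C3 intermediate with the C5 amino acid,
releasing a succinate analog — the arrangement of the clavulanic-acid
pathway. The default carbon uptake bound is 10 mmol·gDCW$^{-1}$·h$^{-1}$
(a round mid-range uptake magnitude), giving the closed-form product
optimum `uptake / 4` recorded in the ground truth. Optional injections with
recorded ground truth: a two-reaction TIC (one reversible and one
irreversible parallel reaction — with both reversible, no *single*
directionality restriction could dissolve the loop), dead-end orphans, an
unreachable three-reaction branch, a prunable "minor" subsystem, and
longer parallel routes that the L1 step must avoid.

`generate_scenario()` builds a measurement scenario from a known flux
distribution: hard growth at the true rate, uptakes as lower bounds and
secretions as upper bounds at their *true* values, and Gaussian noise (the
minimal error model; published tables report symmetric uncertainties) added
to the *reported* experimental rows only. This separation is what makes
the noise-recovery property exact: predictions reproduce the truth, every
reported row carries independent noise, and the expected validation MSE
equals $\sigma^2$. Had the noise also entered the constraint bounds,
bound-pinned exchanges would show $SE = 0$ and noisy secretion caps could
even make the LP infeasible. The experimental rows cover the exchange
fluxes; the growth rate is the constraint, not a validated measurement.

`brute_force_fba_oracle()` is the independent check on the LP core:
exhaustive vertex enumeration over all choices of $n - \mathrm{rank}(S)$
bound-fixed variables, limited to 14 reactions.

What the toy scale does **not** emulate: genome-scale dimensionality and
its numerical conditioning, gene–reaction rule evaluation, compartmental
transport, realistic biomass compositions, and measurement error structure
beyond i.i.d. Gaussian noise. Tests passing here demonstrate algorithmic
correctness on networks with known ground truth, not predictive accuracy
on any particular organism's reconstruction.

## Known limitations

- The simplex is dense and single-threaded; genome-scale models will be
  slow. The design target is reduced models.
- SBML support covers Level 3 + fbc flux bounds, objectives and gene
  products, with subsystem and rule strings carried in notes; it is a
  documented subset, not a full SBML round-trip for arbitrary third-party
  files. MATLAB `.mat` binaries are not read; convert to the JSON dialect
  or SBML first.
- PCA on a two-condition shadow-price matrix is performed as described
  because the workflow calls for it, but with two columns the centered
  matrix is rank one and `top_changing_metabolites()` carries the same
  information more directly.
- Shadow-price interpretation inherits all the caveats of LP duality at
  degenerate optima; classifications should be read alongside FVA ranges.
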