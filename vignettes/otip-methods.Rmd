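---
title: "Optimal tubulin isotype profiles: model, weights and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal tubulin isotype profiles: model, weights and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otip)
```

## The model

Human β-tubulin comes in eight isotypes, fixed here in the canonical order
βI, βIIa, βIIb, βIII, βIVa, βIVb, βV, βVI (genes TUBB, TUBB2A, TUBB2B,
TUBB3, TUBB4A, TUBB4B, TUBB6, TUBB1).  Both a cell type's isotype
expression and a drug's binding preference are represented as probability
8-tuples: non-negative, summing to 1.  This is a deliberate abstraction —
input expression values arrive in arbitrary non-negative units (typically
relative mRNA levels, a proxy for protein abundance) and are always
renormalized, including after zero-imputation of isotypes missing from an
assay.  Whether published tables were themselves renormalized after
excluding unmeasured isotypes is generally unknowable; this package
renormalizes unconditionally and treats that as part of the data model.

Damage of a drug profile $r$ to a cell with profile $q$ is the dot product
$D_{dot}(r,q) = r^\top q$.  Because $r$ lies on the simplex, the damage is
a weighted average of the entries of $q$: it is bounded by
$[\min_i q_i, \max_i q_i]$ and symmetric in its arguments.  It is linear
in $r$, which makes the whole framework a linear program, and also linear
in $q$, which is what makes drug cocktails composable (below).

The alternative Kullback–Leibler damage
$D_{KL}(r,q) = -\sum_{i: r_i>0} r_i \ln(r_i/q_i)$ (natural log, $0\ln 0 =
0$) is non-positive and vanishes exactly at $r = q$: it rewards a drug
that disrupts *all* isotypes in proportion to their usage, where the dot
model rewards hammering the single most abundant isotype.  A drug putting
mass on an isotype the cell does not express gets $-\infty$ with a
classed warning by default (`on_unsupported = "error"` upgrades this to an
error); the warning keeps the score usable on sparse profiles while
surfacing the pathology.

## The optimization

`otip_optimize()` solves

$$\max_r\; q(c)^\top r \quad \text{s.t.}\quad q(t_h)^\top r \le w_h\ \forall h,\quad r \ge 0,\ \textstyle\sum_i r_i = 1$$

with the two-phase simplex method (`boot::simplex`, tolerance $10^{-10}$,
a fixed deterministic configuration).  Unconstrained, the optimum is the
vertex of the most-expressed isotype, with damage exactly $\max_i q_i$;
ties break to the first isotype in canonical order, a documented
convention used everywhere in the package.  Constrained optima typically
mix two or more isotypes.  Constraints met with equality (tolerance
$10^{-7}$) are reported as `active_constraints`: these name the tissues
that limit the achievable damage, and also flag possible degeneracy — when
the optimal face is not a single vertex the solver's deterministic vertex
is returned.  Infeasibility is a first-class `status`, not an error,
because an empty feasible set is a meaningful screening outcome ("no
admissible drug exists for these caps").

`otip_sum_optimize()` replaces the hard caps with penalties and maximizes
the linear net benefit $q(c) - \sum_h v_h q(t_h)$ over the simplex; the
optimum is always the vertex of the largest net-benefit coefficient.

`otip_kl_optimize()` pairs the concave KL objective with the *linear* dot
caps.  The literature discusses the KL objective only unconstrained
(where the optimum is exactly $r = q(c)$, reproduced to machine
precision); the constrained pairing is this package's extension, chosen
because it stays convex.  It is solved through the smooth dual: the
optimizer has the closed form $r_i \propto q_i e^{-(A^\top\lambda)_i}$
with multipliers $\lambda \ge 0$ minimizing
$\log\sum_i q_i e^{-(A^\top\lambda)_i} + \lambda^\top w$, found by
L-BFGS-B (analytic gradient, `factr = 10`, up to 1000 iterations).  Caps
of exactly zero are pre-processed into forced-zero coordinates, LP
feasibility is verified on the admissible support first, and the returned
primal point is rejected if any cap is violated beyond $10^{-7}$.

## The weighting model

Caps $w_h = w(t_h; c, a, p)$ come from a fixed pipeline
(`weight_for()`): (1) organs specific to the other gender are dropped
entirely (no constraint); (2) the baseline cap for (tissue, route) is
looked up, inhalant delivery reusing the local-route baseline; (3) under
local/inhalant delivery the target organ — the tumor site, plus the lung
for inhalant — is multiplied by `target_protection_factor` (default 0.25)
and every other organ by `local_relaxation_factor` (1.2, i.e. damage
allowance elevated by 20%); (4) conservative treatment multiplies by 0.75,
aggressive by 1.5; (5) clinician-flagged organs multiply by
`extra_protection_factor` (0.5); (6) the result is clamped to $[0,1]$ —
a cap above 1 is vacuous since dot damage never exceeds $\max_i q_i \le
1$.  Steps 3–5 are a pure product, so their order (ambiguous in prose
descriptions of such schemes) is numerically irrelevant; the tests assert
this by recomputing the product in a different order.

The default baselines are **illustrative placeholders**, not measured
toxicity data: liver and kidney 0.10 (most exposed through metabolism and
excretion), brain and heart 0.20 (vital organs), colon and small
intestine 0.10 under oral delivery, all other tissues 0.40.  Only the
ordering is meaningful; every number can be overridden through a YAML or
JSON config (`read_weight_config()`), which is the intended use once
empirical values exist.  The 0.25 target-protection and 0.5
extra-protection factors likewise have no published value and are
configurable.

For the penalized variant the CLI derives $v_h = s\,(1 - w_h)$ with
`--penalty-scale` $s$ (default 1).  This is this package's own mapping —
any monotone decreasing function of $w_h$ would respect the intent that
more-protected tissues (smaller caps) carry larger penalties.

## Energies, affinities and combinations

`binding_profile_from_energies()` converts per-isotype binding free
energies to an affinity profile by the Boltzmann form
$r_i \propto e^{-\Delta G_i / RT}$, computed as a max-shifted softmax so
it cannot overflow, with $R = 8.31$ J/(mol K) fixed and $T$ defaulting to
310 K.  The conversion is invariant under adding a constant to all
energies, so tables reported relative to an arbitrary reference row are
usable as-is.  The shipped peloruside A / laulimalide table is exactly
such a table (each row contains a 0 reference cell) and its physical unit
is not stated in the source; the fixture therefore records the unit as
`"unspecified"` and converting it requires an explicit unit declaration —
the caller owns that physical assumption.  Whether laulimalide's many 0
cells mean "no binding" or "reference-equal binding" is likewise not
interpreted; they are carried as data.  An explicit `+Inf` energy is
accepted and means "no binding" (affinity exactly 0); `NA`/`NaN`/`-Inf`
are rejected.  The linear score
$\Delta G(d,c)=\sum_i q_i \Delta G_i(d)$ is exposed only as a score
proportional to $-\frac{1}{RT}\log \mathrm{IC}_{50}$ — no absolute IC₅₀
calibration is attempted, since only proportionality is established.

Drug cocktails of non-interacting compounds compose linearly:
`combine_profiles()` forms $\sum_k \alpha_k r(d_k)$ for convex
coefficients, and by linearity of the dot model the cocktail's damage on
any cell equals the same convex combination of component damages (asserted
to $10^{-12}$ in the tests).

## The grid oracle

`brute_force_oracle()` independently verifies the solvers by enumerating
*every* point of the simplex grid with denominator $1/\text{step}$
(vertices included) on the isotypes actually expressed by the cancer or
any constrained tissue, at most 4 of them.  The enumeration is
implemented in C++ so that step $10^{-3}$ over 4 isotypes (≈ $1.7\times
10^8$ points) takes about a second.  One subtlety: the 8-dimensional LP
may park probability mass on isotypes *nobody* expresses — such mass
contributes nothing to the objective or any constraint, merely absorbing
the $\sum_i r_i = 1$ budget — so a support-restricted grid is a lower
bound on the LP optimum, not an equal.  Because unexpressed isotypes are
exactly interchangeable, `include_slack = TRUE` pools them into a single
extra grid coordinate, an exact reduction that restores two-sided
agreement; the tests check both modes.

## The synthetic generator

Profiles are probability tuples, so `sample_profiles()` draws symmetric
Dirichlet vectors (normalized gamma variates; default concentration 2 per
isotype gives moderate, realistic heterogeneity), optionally zeroing
isotypes with a given probability and renormalizing — emulating assays in
which some isotypes fall below detection.  A seed fixes every output;
cancer and healthy tables use separate seed streams, and the global RNG
state is restored afterwards.  The generator does **not** emulate any
empirical expression distribution: it produces exchangeable isotypes with
no tissue structure, no cancer-vs-healthy shift, and no correlation
between tissues.  A green test on synthetic data therefore establishes
correctness of the algorithms and contracts, not biological validity of
any particular optimum.  `demo_panel()` is a fixed, hand-written toy
panel (labelled illustrative) covering all routes, both genders and one
provably infeasible configuration, used by the documentation and the
end-to-end tests.  Published headline optima for real cancers are *not*
reproduced here: doing so would require the underlying expression dataset
(not printed in any source available to the package) and the exact weight
values (published only as figure colors).

## Numerical conventions

* Profile validation: entries $\ge 0$, sum within $10^{-9}$ of 1 at
  construction; stored exactly renormalized.  Normalization is idempotent
  to $10^{-12}$.
* LP: `boot::simplex`, eps $10^{-10}$; solution feasibility re-checked at
  $10^{-7}$; a failure to converge is raised as an error distinct from
  infeasibility.
* KL: natural logarithm; $0\ln 0 = 0$; dual L-BFGS-B with analytic
  gradient; active-constraint tolerance $10^{-6}$ (the dual approach
  approaches the boundary smoothly rather than landing on a vertex).
* Softmax with max-subtraction; temperatures are validated positive.
* Ties everywhere break to the first isotype in canonical order.
* `fraction_of_optimum` is the damage ratio clamped to $[0,1]$, defined
  as 0 when the reference optimum's damage is 0.
* Human-readable reports round percentages to whole percent; JSON output
  keeps full precision (`digits = NA`).

## Known limitations

mRNA is used as a proxy for protein abundance; splice forms, α-tubulin,
off-target protein interactions, pharmacokinetics, resistance mechanisms
and tumor heterogeneity/evolution are all outside the model (repeated
re-optimization after a biopsy is supported trivially by re-running the
optimizer on the new profile).  Nerve and blood cells — clinically
prominent sites of anti-tubulin toxicity — are absent from the default
panel for lack of quantitative expression data.  The default weight
values are illustrative; conclusions drawn from them illustrate the
machinery, not clinical guidance.
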