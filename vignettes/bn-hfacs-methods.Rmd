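---
title: "Layered Bayesian networks for HFACS-coded incidents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered Bayesian networks for HFACS-coded incidents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnhfacs)
```

## The model

`bnhfacs` analyzes databases of safety incidents coded with the four-level
HFACS taxonomy. The statistical object is a discrete Bayesian network whose
directed acyclic graph is *layered*: levels are numbered bottom-up (level 1 =
unsafe acts, level 4 = organizational influences, matching how practitioners
index the hierarchy), every node on level L+1 is a parent of every node on
level L, and no other edges exist. Two modelling assumptions are baked into
this structure and inherited by everything downstream:

* factors within a level are conditionally independent given the level
  above — there are no within-level or level-skipping edges;
* influence flows strictly downward: organizational influences shape
  supervision, supervision shapes the preconditions, preconditions shape the
  unsafe acts.

Unsafe acts are modelled as two multi-state nodes rather than five binary
ones: an error-type node (states skill, decision, perception, none) and a
violation-type node (routine, exceptional, none). The named subtypes
(SBE/DE/PE and RV/EV) are *states*, which keeps the error subtypes mutually
exclusive per incident, as coded. All other nodes are binary yes/no. The
taxonomy is data, not code: `layered_network()` accepts any node sets per
level and `validate_network()` enforces only the layering invariants, so
facilities with different sub-factor granularity can reuse the machinery.

The joint probability of a full coding is the product over nodes of
P(node state | parent states). Every quantitative output of the package —
priors, posteriors, sensitivities — is a deterministic function of the CPTs.

## Parameter learning

CPTs are fitted from fully observed records by Dirichlet-smoothed maximum
likelihood: P(s | c) = (n + alpha) / (N + alpha K). The default
`alpha = 1` (add-one smoothing) is used because coding databases in this
field are small (tens of incidents) while a level-2 node has 16 parent
configurations, so unsmoothed estimates contain many empty or degenerate
rows; published analyses of this kind delegate learning to BN toolboxes
whose priors are unstated, and the package makes the choice explicit and
configurable instead. `alpha = 0` gives the pure MLE; parent configurations
never observed then fall back to a uniform row and are flagged in the fit's
provenance, so the fallback is visible rather than silent. Whether reported
prior rates in the literature are smoothed-model marginals or raw
frequencies is generally undecidable from publications; both are available
here through `alpha`.

Missing cells are not estimated: the default policy rejects a record with an
empty node cell (`strict`), and `drop` discards it with a logged warning.
Case learning in this design assumes complete codings, and an EM treatment
of partially coded incidents is out of scope.

## Inference

`query()` computes exact posteriors by sum-product variable elimination.
Elimination order is chosen greedily by minimum product-factor width, with
ties broken by lexicographic node code so runs are reproducible; correctness
is independent of the order and is tested against `enumerate_joint()`, a
brute-force tabulation of all joint states (12,288 on the canonical network)
kept deliberately free of the elimination machinery so the two paths are
independent. Conditioning is observational, matching evidence propagation in
standard BN tools: asserting a factor "present" re-weights the joint
distribution; do-calculus interventions are not implemented. Evidence with
zero probability under the model is a hard error naming the evidence, not a
silent NaN. All probability arithmetic is ordinary double precision;
equality comparisons in the tests use absolute tolerance 1e-9.

## The sensitivity statistic

The influence of an upper factor on a lower factor is the truncated relative
risk change: with p1 = P(lower occurs | upper = yes) and p0 = P(lower occurs
| upper = no), the sensitivity is (p1 − p0)/p0 when the change is positive
and 0 otherwise — negative (protective) associations are deliberately not
scored. "Occurrence" of an error or violation subtype means the multi-state
node takes that one state; the complementary evidence for a binary upper
factor is the state "no". Both posteriors are computed through full network
propagation, so non-adjacent pairs (e.g. a level-4 factor's effect on a
level-1 subtype) are handled identically to parent–child pairs, one upper
factor asserted at a time with all other nodes free.

Numerical edge cases: p1 = p0 (including both zero) scores 0; p0 = 0 with
p1 > 0 makes the ratio undefined — a hard error from the scalar call, an NA
cell with a logged warning in matrix output, and NA cells are excluded (with
a warning) from the overall error/violation means. Internal values are kept
at full precision; the two-decimal half-up rounding seen in rendered tables
is presentation only (`round_half_up()`, since base `round()` is
half-to-even).

## The synthetic generator

Real coding databases of this kind are typically not deposited, so the
package ships `default_truth()`, a fully specified ground-truth network that
plays the role of such a database's generating process. Its CPTs are
hand-authored in an additive parent-effect form: the probability that a child
is present is a base rate plus a fixed increment per parent present (for
multi-state nodes, per named state, with "none" absorbing the remainder).
Because expectation is linear, each node's exact marginal equals
base + sum(increment × parent marginal) regardless of the dependence among
parents, so the generator's marginals are set by construction, not by tuning:
skill-based errors 0.375, condition of operators 0.496, personnel factors
0.598, inadequate supervision 0.576, organizational climate 0.253 — the prior
rates published for radiotherapy incident factors — with the unpublished
remainder chosen once at plausible values (resource management 0.094,
organizational process 0.20, routine violations 0.22 above exceptional 0.08,
environmental factors 0.20, supervision-level rates 0.35/0.25/0.15). The
resource-management increment on inadequate supervision is calibrated so the
model's own conditionals reproduce the worked-example posteriors 0.624/0.571.
The increments were also signed to reproduce the qualitative influence
pattern reported for radiotherapy: operator condition drives skill errors,
personnel factors drive decision errors and routine violations, environmental
factors drive perceptual errors and exceptional violations.

Sampling is ancestral: nodes are drawn in topological order conditioned on
their sampled parents, which realizes the factorized joint exactly. Each node
consumes its own deterministic substream (derived from the master seed and
the node code), so identical seeds give byte-identical databases and adding a
node never perturbs other columns. Phase/error-type labels are drawn from the
packaged 16-row empirical distribution of 81 publicly reported radiotherapy
incidents, independently of the coded factors.

What the generator emulates: the layered dependence structure, realistic
marginal rates, complete codings, study-sized databases (the frozen fixture
has 81 records, seed 42). What it does not emulate: reporter behaviour
(under-reporting, severity mixes), narrative text, coder disagreement, or
any dependence of the phase labels on the coded factors. Passing tests
therefore certify the estimator and inference machinery, not the fidelity of
any particular facility's data.

## Parameter recovery and what the tests measure

`recovery_experiment()` samples n incidents, refits, and scores each CPT row
by total-variation distance to truth, with a headline maximum over rows
observed at least `min_obs = 50` times. One property worth understanding
before reading its output: a binary row with m observations has sampling
standard deviation up to 0.5/sqrt(m) (about 0.07 at m = 50), so the *maximum*
TV over the many rows that clear a low observation threshold concentrates
well above the per-row typical error, and this maximum can grow with n as
more small rows clear the threshold. Mean TV over all rows is the summary
that decreases cleanly with n, and abundant rows (a thousand observations or
more) individually recover to within a few hundredths. The test suite
asserts exactly these attainable properties, plus exact equality of the
unsmoothed fit with empirical frequencies; the acceptance suite additionally
records a strict max-TV bound at n = 5000 that the sampling distribution
does not in fact support, and that check fails for exactly this reason.

Problem sizes throughout the suite were chosen to exercise the asymptotics
while keeping a full run in tens of seconds: oracle-equivalence checks on 20
random models over the full 12,288-state joint, recovery at n = 200 and
5000 (and 10,000 for marginal-concentration checks with 3-sigma binomial
bands).

## Known limitations

* The layered-completeness assumption is structural dogma, not a learned
  graph; `bnhfacs` deliberately has no structure learning.
* Sensitivities are relative risk changes; factors with tiny baselines can
  post large sensitivities from small absolute changes, so the matrix should
  be read alongside the priors.
* Observational conditioning means sensitivities quantify association under
  the model, not intervention effects.
* With 81-case databases and `alpha = 1`, smoothing materially shrinks
  sparse rows toward uniform; conclusions about rarely observed parent
  configurations reflect the prior as much as the data.
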