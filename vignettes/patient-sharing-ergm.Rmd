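---
title: "Modelling physician- and patient-induced patient-sharing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physician- and patient-induced patient-sharing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshare)
```

## The scientific problem

Two physicians share a patient when both treat that patient within an
observation window. Aggregating co-treatment over all patients yields an
undirected *patient-sharing network* over physicians, a standard proxy for
professional exchange in health-services research. In outpatient systems of
the Bismarck tradition, patients choose their physicians freely, so a
patient-sharing tie can arise through two distinct mechanisms:

* **physician-induced** — one physician referred the shared patient to the
  other; the tie reflects deliberate coordination, and the referral leaves
  a documented trace in claims data;
* **patient-induced** — the patient consulted both physicians on their own
  initiative; no referral is documented.

`pshare` builds both channels from an encounter-level claims table and
models each binary network with exponential random graph models (ERGMs)
whose statistics encode the role structure of primary care: every physician
is coded as a general practitioner (GP, role 1 — including pediatricians,
appropriate when the patient population is children and adolescents) or as
a medical specialist (role 0). The scientific questions are triadic: do
GPs cluster with each other, do GPs broker between specialists
(gatekeeping), are open chains closed by referrals or by patients?

## From claims to networks

`project_to_physicians()` projects the bipartite patient-physician
incidence onto physicians: the weight of pair \{i, j\} is the number of
distinct patients treated by both. `dichotomize()` applies the tie rule
(default: at least one shared patient — a threshold chosen because higher
cutoffs silently discard real but infrequent collaborations).
`split_channels()` classifies each tie:

* a pair is *physician-induced* if at least one shared patient has a
  referral row connecting the two physicians — and that patient actually
  visited the referrer, since a patient-sharing tie requires co-treatment
  by definition;
* a pair sharing patients with no such referral is *patient-induced*.

The two channel edge sets are therefore disjoint and partition the combined
network's edge set. This is a tie-level convention: a pair with both
referral-mediated and self-directed shared patients counts once, as
physician-induced, because the documented referral is the stronger
signal of coordination. An alternative convention would let the channels
overlap; we chose the partition because it keeps the two models
comparable on non-overlapping evidence, and because with it the channel
densities add up to the combined density, which aids interpretation.
All roster physicians are retained in every channel, so physicians never
involved in a referral appear as isolates of the physician-induced network
— itself an interesting descriptive quantity.

Claims data carry no reliable temporal ordering of encounters, so all
networks are undirected; directed transfer networks are out of scope.

## The ERGM and its statistics

For a binary symmetric adjacency $y$, the model is
$\Pr(Y = y) \propto \exp\!\big(\sum_A \theta_A z_A(y)\big)$ over the
statistics $z_A$. A positive $\theta_A$ means configuration $A$ occurs
more often than chance, given everything else in the model. The
configurations implemented are:

| name | statistic |
|---|---|
| `edge` | number of ties |
| `GGG_triad`, `GGS_triad`, `GSS_triad` | triangles whose role multiset is {G,G,G}, {G,G,S}, {G,S,S} |
| `GGG_chain`, `GGS_chain`, `SGS_chain` | *open* two-paths (endpoints not tied) with GP center and endpoint roles {G,G}, {G,S}, {S,S} |
| `two_path` | $\sum_k \binom{d_k}{2}$ — simple connectivity |
| `alt_two_paths` | $\lambda \sum_{i<j} \big(1 - (1 - 1/\lambda)^{L_{2,ij}}\big)$, $L_{2,ij}$ = common neighbours — multiple connectivity |
| `alt_stars` | $\lambda^2 \sum_i \big((1 - 1/\lambda)^{d_i} - 1 + d_i/\lambda\big)$ — degree spread |
| `activity` | $\sum_{i<j} y_{ij} (a_i + a_j)$ for a binary attribute (GP activity) |
| `match`, `mismatch` | ties between equal / unequal values of a categorical attribute |
| `dyadic_cov` | $\sum_{i<j} y_{ij} w_{ij}$, e.g. pairwise travel time in minutes |

Two definitional choices deserve justification:

* **Chain terms count strictly open two-paths.** An open triad is a
  two-path whose endpoints are not tied; counting all two-paths would
  conflate the open and closed cases that the closed-triad terms already
  separate. With this convention the identity
  *(open chains) + (closed two-path incidences) = (all two-paths)* holds
  per role pattern, and the change statistics of chain and triad terms are
  exactly complementary: closing an open chain trades one chain for one
  triangle. Some estimation software counts all two-paths; results are
  then linear combinations of ours.
* **`GGS_chain` has a GP center with endpoints {G,S}.** The variant with a
  specialist center is a different substantive configuration (a specialist
  brokering) and is not implemented.
* The alternating statistics use the standard geometrically weighted form
  with damping $\lambda > 1$, default $\lambda = 2$, overridable per term
  because larger $\lambda$ values are the usual remedy when dense regions
  impede convergence. As $\lambda \to \infty$, `alt_stars` converges to
  the two-path count (the tests assert this numerically at
  $\lambda = 10^6$).

Each term has an exact change statistic (the difference in the global
statistic from toggling one dyad), implemented in C++ and contract-tested
against brute-force global differences to $10^{-9}$.

## Estimation

`mple_fit()` maximizes the pseudo-likelihood — logistic regression of each
dyad's state on its change-statistic vector. It is exact for
dyad-independent models and is used as the initializer otherwise. Dyads
whose change statistics separate the response perfectly are reported as
non-estimable instead of returning a silently diverged coefficient.

`mcmcmle_fit()` solves the likelihood equation
$\mathbb{E}_\theta z(Y) = z_{\mathrm{obs}}$ by Robbins–Monro stochastic
approximation:

1. a pilot simulation at the initial $\theta$ estimates the statistic
   covariance $D$;
2. sub-phases iterate
   $\theta \leftarrow \theta - a_r\, \mathrm{diag}(D)^{-1} (z(Y_{\mathrm{sim}}) - z_{\mathrm{obs}})$
   with gain $a_r = a_0/r$ and sub-phase lengths doubling, ending each
   sub-phase with Polyak averaging. The diagonal preconditioner is
   deliberate: with nearly collinear statistics the full inverse
   covariance amplifies simulation noise and can launch the trajectory
   into degeneracy, while the diagonal scales each coordinate robustly.
   Single updates are clipped at `max_step` (default 0.5) as a further
   overshoot guard;
3. a long run at the final $\theta$ yields per-term convergence t-ratios
   $(\bar z_{\mathrm{sim}} - z_{\mathrm{obs}})/\mathrm{sd}_{\mathrm{sim}}$,
   and standard errors from the inverse simulated covariance of the
   statistics (the Fisher information of an exponential family).

A fit is declared converged when every $|t| \le 0.1$; otherwise phases 2–3
repeat (up to `max_rounds`) and a still-unconverged result is returned
flagged rather than hidden. Persistent simulation at empty or complete
graphs aborts with a degeneracy diagnostic, since no useful estimate
exists there. The paper-style tables report a significance star by the
Wald convention $|\hat\theta| \ge 2\,\mathrm{SE}$, the operational reading
of "significant at $p \le 0.05$" when no p-values are published.

**Fixed-density conditioning.** Models with strong structural terms often
converge only when the number of ties is held at its observed value.
Under `conditioning = "fixed_density"` all simulation uses *tie-swap*
proposals (delete a uniform tie, add a uniform non-tie — the edge count is
invariant by construction), the edge term is disallowed (its statistic
would be constant), and initialization is at zero because the
unconditional MPLE is not meaningful on the constrained space.

Sampler defaults scale with the dyad count $n(n-1)/2$: burn-in ten sweeps,
thinning one sweep, 1000 retained statistic vectors. All simulation is
driven by R's RNG, so every result is reproducible from a seed.

## Goodness of fit

`gof_report()` simulates networks at the fitted $\theta$ (respecting the
conditioning) and compares auxiliary statistics with the observed network
through $t$-ratios; $|t| < 2$ passes. The default auxiliary set is all
fourteen term statistics (role activity, specialty match/mismatch, each
supplied dyadic covariate), isolate count, triangle count, global
clustering, and the degree-distribution deciles. Statistics inside the
fitted model pass by construction of a converged fit; the informative rows
are the ones the model does *not* control. Degree deciles of small
networks are integer-valued and can have near-zero simulated spread, which
occasionally fails a decile row even under the generating model — worth
remembering when reading reports for networks of a few dozen nodes. A row
with zero simulated spread and a discrepant observation is flagged
degenerate rather than scored.

## The synthetic claims generator

The package is developed against confidential-style claims data that
cannot ship with it, so `generate_roster()` / `generate_claims()` produce
synthetic inputs with the statistical structure the analysis assumes.
Physicians are placed uniformly on a 20 km square; travel time is
Euclidean distance at 1.5 min/km (only relative distances matter for the
covariate effect). Each patient:

1. picks a home GP with probability
   $\propto \exp(-\text{decay} \cdot \text{travel time})$ — a softmax
   rather than nearest-GP assignment, so spatial structure is stochastic
   and the distance effect is recoverable by estimation;
2. makes $k \sim \mathrm{Poisson}(\text{mean specialist visits})$
   specialist visits, each chosen by the same softmax around the home GP,
   and each referral-mediated (referrer = home GP) with probability
   `p_referral`;
3. with probability `p_second_opinion` consults one additional GP without
   a referral.

Ground truth (home-GP map, per-encounter channel) is attached for
validation; the CSV writer drops it. Random draws are staged so that
changing `p_referral` alone re-thresholds the same uniforms, making the
set of referral rows monotone in `p_referral` under a fixed seed — a
property the tests exercise.

The defaults (113 physicians, 20% GPs, 3000 patients, decay 0.4/min, 2.5
mean specialist visits, `p_referral` 0.12, `p_second_opinion` 0.15) were
calibrated once so that the generated channels reproduce the qualitative
facts the analysis is designed around: a patient-induced network with
density near 40% and no isolates, and a much sparser physician-induced
network (roughly 5–6%) with isolated physicians. Within this mechanism the
two targets trade off — driving the referral channel denser removes its
isolates — so the defaults favour the density contrast. What the generator
does *not* emulate: fee-schedule or diagnosis coding, quarterly visit
timing, patient covariates, heterogeneous referral propensities, and
excluded service types (laboratory, emergency) are never emitted, so no
exclusion filter is modelled. Passing tests therefore certify the
*method* — projection, channel classification, statistics, estimation —
not distributional realism of German claims.

## Problem sizes and numerical choices

The test-suite and acceptance computations run at sizes chosen to give the
checks real teeth while staying comfortably interactive: exactness checks
on 7–16 node graphs (where brute-force triple loops are feasible as
independent oracles), sampler calibration at 30 nodes, parameter recovery
at 36 nodes, GOF self-consistency at 40 nodes with ten independent
generate–fit–report repetitions, and the descriptive pipeline at the full
113-physician scale. Matrix statistics use dense adjacency algebra —
appropriate for networks of at most a few hundred physicians.

Other numerical conventions: ill-conditioned statistic covariances are
ridge-regularized with a logged warning before inversion; the global
clustering coefficient is defined as 0 on graphs with no two-paths;
degree deciles use the type-1 (order-statistic) quantile; tie-swap
proposals may re-select the just-deleted dyad (a harmless identity move
that keeps the proposal symmetric).

## Known limitations

* Channel classification is a convention, not ground truth: patients
  influence referrals and physicians steer patients informally, so the
  two channels are approximations of agency.
* The estimator is for undirected binary networks only; $\lambda$ is
  fixed, not estimated (no curved-family estimation).
* MPLE standard errors understate uncertainty for dyad-dependent models;
  use the Monte Carlo fit for inference.
* Near the ERGM degeneracy boundary (strong positive closure effects) the
  sampler mixes between sparse and near-complete phases; the estimator
  aborts with a diagnostic rather than returning a number.

## A worked example

The README walks through this example with its printed output; the fit
takes on the order of twenty minutes at the full 113-physician scale.

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
ros <- generate_roster(cfg)
claims <- generate_claims(ros$roster, ros$travel_time, cfg)
channels <- split_channels(claims, ros$roster)
describe(channels$patient_induced)

nd <- 113 * 112 / 2
spec <- model_spec(
  term_spec("GGG_triad"),
  term_spec("GGS_triad"),
  term_spec("GSS_triad"),
  term_spec("SGS_chain"),
  term_spec("alt_stars", lambda = 8),
  term_spec("activity", attribute = "role"),
  term_spec("dyadic_cov", covariate = "travel_time"),
  conditioning = "fixed_density")
fit <- mcmcmle_fit(spec, channels$patient_induced, ros$roster,
                   covs = list(travel_time = unclass(ros$travel_time)),
                   control = sampler_control(thinning = 2 * nd,
                                             n_samples = 1500, seed = 2),
                   max_rounds = 6)
fit
gof_report(fit, channels$patient_induced, ros$roster,
           covs = list(travel_time = unclass(ros$travel_time)),
           control = sampler_control(n_samples = 100, seed = 3))
```

Two practical notes visible in this example: in the dense patient-induced
channel the $\lambda = 2$ alternating-star statistic is nearly constant
(at degrees in the forties, $(1/2)^{d}$ vanishes and the statistic is a
linear function of the fixed edge count), so a larger $\lambda$ restores
identifiability — the reason per-term $\lambda$ overrides exist; and the
synthetic referral channel is GP–specialist bipartite by construction
(every referral runs from a home GP to a specialist), so closed-triad
statistics are identically zero there and GP-activity is collinear with
the edge count — triadic models belong on the patient-induced or combined
channel for data from this generator.
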