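---
title: "Methods: multi-treatment evidence synthesis for ALK-inhibitor trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-treatment evidence synthesis for ALK-inhibitor trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `alkmeta`: the models
and their assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generators emulate (and do not), the
numerical choices, and the known limitations. The setting is the evidence
base for ALK-rearranged non-small cell lung cancer: a handful of
randomized trials comparing alectinib, ceritinib and crizotinib with
chemotherapy (or each other), surrounded by a larger set of single-arm
studies.

## The evidence network

`build_network()` forms the comparison graph from an arm-level trial
table: one node per treatment appearing in a multi-arm trial, one edge per
directly compared pair, edge weight the number of head-to-head trials, and
node weight the total randomized sample size. Chemotherapy regimens
(pemetrexed, docetaxel, platinum doublets) are collapsed to a single
`chemotherapy` node: the comparative question is drug class versus
targeted agent, the regimens are clinically exchangeable comparators here,
and a per-regimen split would disconnect the network. Multi-dose arms
(e.g. ceritinib 450/600/750 mg) are likewise one arm unless the input
splits them; dose is not modelled. Study-quality labels are stored
verbatim and never interpreted numerically.

The packaged table (`alk_trials_fixture()`) transcribes 33 trials with
5507 participants, 2042 of them in the 8 randomized trials that form a
connected 4-node network with 2 + 2 + 4 edges.

## Bayesian network meta-analysis

### Likelihoods

Two outcome kinds are supported, both for two-arm trials:

* `BINARY_ARM` — arm-level counts, binomial-logit:
  `r_ib ~ Bin(n_ib, plogis(mu_i))`,
  `r_it ~ Bin(n_it, plogis(mu_i + delta_i))`. Used for response, disease
  control and discontinuation odds ratios.
* `CONTRAST_NORMAL` — published log hazard ratios:
  `y_i ~ Normal(delta_i, se_i^2)`, with `se_i` recovered from the reported
  95% interval as `(log hi − log lo) / (2 × 1.959964)`. Used for
  progression-free survival, where arm-level event histories are not
  published but HRs are.

Trial effects are exchangeable, `delta_i ~ Normal(d_t − d_b, tau^2)`,
with basic parameters `d_k` relative to a reference (chemotherapy by
default) and the consistency relation `d_xy = d_y − d_x` supplying all
indirect contrasts. The inconsistency variant (`consistency = FALSE`)
replaces the relation with one unrelated mean effect per observed edge.
Every randomized trial in this evidence base is two-arm; trials with more
arms are rejected outright rather than mishandled (the multi-arm
covariance correction is deliberately not implemented), and trials missing
the outcome in one arm are dropped with a warning.

### Priors

The source analyses in this literature ran on OpenBUGS and never printed
their priors; we adopt the conventional vague choices for that era and
make them configurable in `nma_model_spec()`:

* `mu_i, d_k ~ Normal(0, 100^2)` (`mu_sd`, `d_sd`; effectively flat on the
  logit/log-HR scale),
* `tau ~ Uniform(0, 5)` (`tau_upper`; 5 on a log scale is far beyond any
  plausible between-trial spread, so the bound is inert while keeping the
  posterior proper).

### Sampler

`run_mcmc()` uses a random-walk Metropolis-within-Gibbs sampler written in
C++ (Rcpp): every scalar parameter gets a Gaussian proposal whose scale
adapts toward 44% acceptance in batches of 50 iterations **during burn-in
only**; adaptation is frozen afterward so the retained chain is a genuine
Markov chain satisfying detailed balance. Defaults follow the field's
standard configuration: 4 chains × 50,000 iterations, 20,000 burn-in,
thinning 10 → 3000 retained draws per chain. Chain *c* is seeded
`seed + c − 1` through R's RNG, so runs are bit-reproducible; initial
values are data-driven (empirical logits, least-squares basic parameters)
with per-chain overdispersion jitter so that the Brooks-Gelman-Rubin
diagnostic is meaningful. `psrf()` implements the BGR factor
`sqrt(((n−1)/n · W + B/n) / W)` per scalar parameter; constant chains
(zero within- and between-variance) return 1 with a warning rather than
NaN.

### Summaries

League tables summarize `exp(d_x − d_y)` draw-wise with the posterior
median and central 95% interval — the published tables say "pooled OR/HR
and 95% CI" without specifying mean or median, and the median is
transformation-equivariant, which keeps the table exactly reciprocal
(`cell(x,y) = 1/cell(y,x)`, enforced by filling mirror cells by
inversion) and exactly transitive at the draw level. Rank probabilities
sort each draw's effects versus the reference; the direction flag is
per-outcome: rank 1 = lowest hazard ratio for progression, rank 1 =
highest odds ratio for response/disease control, and — following the
published convention for the safety endpoint — rank 1 = *highest*
discontinuation odds, so rank 4 is the safest drug. Ties (measure zero
for continuous draws) break by alphabetical treatment id.

`compare_consistency()` reports per-edge posteriors under both models plus
the posterior-mean residual deviance of each. Two caveats discovered
while validating: in a loop-free network (the real 4-node geometry has no
closed loop) the two models estimate the same contrasts, and the
comparison is flagged as degenerate; and with random effects, conflict on
one edge of a loop is partly absorbed as inflated `tau` — so the test
suite checks both the interval separation on the conflicted edge *and*
the `tau` inflation, rather than relying on raw deviance, which the
extra heterogeneity can actually lower. `pairwise_vs_nma_check()` sets
each direct contrast's DerSimonian-Laird estimate against the network
posterior and flags non-overlapping intervals.

## Classical pooling

`cochran_heterogeneity()` computes Q against the fixed-effect pool,
`p` from the upper chi-square tail on `k − 1` df, and
`I² = max(0, (Q − df)/Q) × 100`. `select_model()` encodes the rule used
throughout: fixed effects iff `p > 0.1` **and** `I² < 50`; otherwise
random effects with the DerSimonian-Laird `tau²` (the default in the
STATA tooling this replaces; the estimator sits behind a single function
so alternatives can be added). Proportions are pooled on the logit scale
— chosen over the raw scale because single-arm response rates here
approach 100%, where logit pooling respects the [0, 1] boundary — with a
0.5 continuity correction added to both cells of boundary studies.
Reported medians (e.g. median PFS in months) are pooled by inverse
variance directly on the months scale with `se = (hi − lo)/3.92`; this
mirrors the published procedure but is methodologically fragile (medians
are not normal, follow-up differs between studies), so
`pool_medians()`'s documentation points users to reconstructed IPD
instead. All 95% intervals use `z = 1.959964`; displayed ratios round to
2 decimals and percentages to 1.

## Kaplan-Meier reconstruction

`clean_curve()` repairs digitizer output (clamp to [0, 1], deduplicate
times keeping the last reading, prepend (0, 1), isotonic non-increasing
projection). `reconstruct_intervals()` applies the survival-ratio
relation per at-risk interval: `d_j = round(n_j (S_j − S_{j+1})/S_j)`,
censored count `c_j = n_j − d_j − n_{j+1}` floored at zero with any
negative remainder re-allocated to events. Events are placed at the
digitized drop times (allocated across drops by largest-remainder
rounding of the relative falls), censorings at the interval midpoint —
this placement reproduces the input curve at interval boundaries when the
counts are exact, and is exactly invertible when the at-risk table is
per-event-time.

Two variants exist, switched by whether an at-risk table is supplied:

* **with at-risk rows** the censored counts are identified per interval —
  the reliable path (event-count error of ~1–2% on the synthetic
  generator's published-style tables, asserted in the suite);
* **without** (`total_n` only) zero within-interval censoring is assumed.
  Attrition invisible to the curve is then counted as events, so the
  event count is biased upward by roughly the pre-cutoff dropout
  fraction. This is the dominant source of reconstruction error and is
  asserted as such in the tests (error bounded by ~2× a 10% dropout
  rate, and ≤5% when censoring is purely administrative). Many source
  figures in this literature lack at-risk rows; conclusions from such
  curves inherit this bias.

`km_estimator()` wraps the product-limit estimator (Greenwood variance)
from the survival package. The median is defined as the **smallest time
with S(t) ≤ 0.5** — the convention of the SPSS-style outputs this
replaces — rather than the midpoint-interpolating convention some tools
use for flat-at-0.5 curves; its interval inverts the pointwise survival
band at 0.5 (Brookmeyer-Crowley), with the log-log transform by default
and the linear (`"plain"`) variant selectable to match SPSS defaults. A
curve that never reaches 0.5 reports "not reached" (`NA`). Pooled curves
concatenate per-trial pseudo-IPD per treatment — exactly the published
procedure, which ignores trial membership — and `logrank_test()` is
correspondingly **unstratified by default** to replicate it; the
stratified variant (`stratify_by_trial = TRUE`) is provided and is the
better analysis, since it compares treatments within trials.

## Publication bias

`egger_test()` regresses the standardized effect `y/se` on precision
`1/se` by OLS and t-tests the intercept on `k − 2` df, two-sided.
`begg_test()` computes Kendall's tau between variance-standardized
deviations from the fixed-effect pool and the study variances, with the
tie-corrected normal approximation and no continuity correction by
default (a flag adds it) — the literature is silent on both choices, so
the defaults mirror the original Begg-Mazumdar formulation. Both require
k ≥ 3. `funnel_coordinates()` emits points plus pseudo-95% guide lines
`pooled ± 1.959964 × se`.

## Synthetic-data generators

The generators exist so that every stage has a ground-truth oracle:

* `simulate_binary_network()` draws trial baselines
  `Normal(qlogis(p0), 0.3^2)`, trial contrasts
  `Normal(d + omega, tau^2)` and binomial arms. The default scenario
  copies the real geometry — 4 treatments, 2 + 2 + 4 trials with the
  published arm sizes — with true odds ratios of about 12, 8 and 6 versus
  chemotherapy (the magnitudes seen for response in this setting), a 30%
  chemotherapy response rate (typical of the comparator arms), and
  `tau = 0.2`, moderate heterogeneity on the log-odds scale. Per-edge
  `omega` offsets inject inconsistency for diagnostics testing.
* `simulate_survival_trial()` draws exponential event times, uniform
  dropout calibrated to a target censoring probability (default 10%, a
  realistic non-administrative dropout for these trials) plus
  administrative censoring at follow-up (24 months by default), and emits
  the digitizer's artifacts: the KM curve sampled on a fixed grid
  (0.5-month default, optional jitter, default sd 0.005 survival units)
  and at-risk rows every 3 months.
* `simulate_proportion_studies()` draws study logits around a true
  proportion with between-study spread.

Every generator is a pure function of its seed. What they do **not**
emulate: informative censoring, non-proportional hazards, dose effects,
reporting biases within trials, and digitization error beyond additive
jitter. Passing recovery tests on these generators therefore validates
the estimators under their own assumptions, not the assumptions
themselves against real trial data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: `Q = 0` defines `I² = 0`;
`tau²` truncates at 0; boundary proportions get the continuity
correction; a curve interval reaching S = 0 with patients still at risk
is an error; constant MCMC chains give PSRF 1 with a warning. The test
and acceptance workloads are sized for interactive runs: 200 replicates
at 5,000 iterations for credible-interval coverage, 2,000 null
simulations for the bias tests' type-I error, 40 replicates at 500
patients/arm for log-rank power, and one full-scale (4 × 50,000)
convergence run — a few minutes end to end on one CPU, thanks to the
compiled sampler.

## Known limitations

The exact posteriors of the published tables are not reproducible from
the published material alone (per-trial inputs and priors were not
printed); the suite therefore verifies internal coherence of those tables
and ground-truth recovery on synthetic data. Multi-arm trials, SUCRA
curves, node-splitting, meta-regression and Hamiltonian samplers are out
of scope; median pooling is supported but discouraged; the unstratified
pooled log-rank replicates the published procedure rather than best
practice.
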