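---
title: "Modelling gain/loss asymmetry in effort-based lottery choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gain/loss asymmetry in effort-based lottery choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Loss aversion — the tendency for losses to loom larger than equivalent
gains — is well established for money. Whether it extends to physical
effort is less clear: do people avoid *more* work more strongly than they
seek *less* work? `effortvalue` implements an analysis pipeline for
accept/reject decisions over 50:50 mixed gambles in which the outcomes are
levels of physical effort (the viscous damping coefficient *b* of a
resistive force field opposing an arm reach, in N·s/m) or dollar amounts.
A reference resistance of *b* = 35 N·s/m is framed as "0% more/less
effort"; reductions in effort are gains, increases are losses. Rejecting a
lottery means reaching at the reference; accepting means a coin flip
between the gamble's gain arm and loss arm.

The package provides: the lottery designs, a space of candidate
prospect-theory choice models, per-subject maximum-likelihood fitting,
group-level random-effects Bayesian model selection (BMS), a Monte-Carlo
confusion (identifiability) analysis, a synthetic-cohort generator, and
the descriptive statistics used to summarise choice behaviour.

## The design

Displayed percentages map linearly onto resistance,
`b = 35 * (1 + pct/100)`: the 10% steps from 100% less to 100% more effort
correspond to 0, 3.5, 7, ..., 70 N·s/m. (A coarser 7 N·s/m-spaced ladder —
0, 7, ..., 70 — is the 20%-spaced *training* grid and plays no role in the
lotteries.) Eleven gain levels crossed with eleven loss levels give 121
unique lotteries; with the standard three repetitions, a 363-trial session
in per-subject randomised order. The financial design is the same grid
over $0–$100 gains and $0–$100 losses.

```{r design}
library(effortvalue)
grid <- build_effort_grid(n_repetitions = 3, seed = 1)
nrow(grid)                     # 363
dplyr::n_distinct(grid$gain_pct, grid$loss_pct)  # 121
```

## The model

Each candidate model is an outcome **encoding**, a **value function**, and
a **choice rule**.

*Encoding.* An outcome is mapped to a signed subjective input X. The
reference-dependent effort encodings use
X = −(b^γ − 35^γ): reduced effort gives X > 0, increased effort X < 0,
and the reference maps to 0. γ is fixed at 1 (linear) or 2 (quadratic) in
the nested model families and free in the hybrid model. A
zero-effort-reference alternative treats all effort as a loss, X = b^γ,
valued as −X against a sure-bet utility of −35^γ. Money encodings act on
signed dollars: X = $, X = sign($)·|$|^γ, or — for the large-money
reference model — a translation by +$100 so that all outcomes are gains,
X = ($+100)^γ, against a translated sure bet of 100^γ.

*Value.* SV(X) = X^α for X > 0 and −λ(−X)^α for X < 0, with SV(0) = 0.
α is the value sensitivity (α < 1: diminishing sensitivity), λ the
loss-aversion coefficient (λ > 1: losses loom larger; λ < 1:
relief-seeking).

*Choice.* The 50:50 gamble's utility is U = 0.5·SV(X⁺) + 0.5·SV(X⁻), and
acceptance follows the logistic rule
P(accept) = 1/(1 + exp(−μ·(U − U_sure))), where μ ≥ 0 is the choice
stochasticity: μ = 0 is random choice, large μ deterministic utility
maximisation. The per-subject log-likelihood is the Bernoulli sum
Σᵢ rᵢ·log Pᵢ + (1 − rᵢ)·log(1 − Pᵢ) over trials.

The effort space (`eff_model_space()`) has eight candidates: symmetric
sensitivity (α, λ, μ), no sensitivity (λ, μ) and no loss aversion (μ),
each under linear and quadratic encodings, plus the zero-effort-reference
model (γ, μ) and the hybrid loss-aversion + nonlinear-encoding model
(λ, γ, μ with α ≡ 1 — with γ free, α and λ would trade off
non-uniquely, so α is pinned). The financial space (`fin_model_space()`)
has five: the three nested linear-money models, the large-money-reference
model, and the signed-power hybrid.

## Fitting

`fit_subject()` minimises the negative log-likelihood with a
derivative-free Nelder–Mead simplex on a logistic transform of the
parameters, which enforces the box bounds without penalties
(single-parameter models use bounded Brent search plus explicit endpoint
checks). Bounds are [0, 10] for α, λ, γ and [0, 20] for μ, applied
uniformly across models with one exception: the two power-of-money
encodings (`fin_large_money_reference`, `fin_hybrid`) allow μ up to 1e5,
because a fitted γ near 0 compresses X to order one and the maximising μ
scales inversely with X — population-typical fits for those encodings sit
around μ ~ 10⁴, far outside [0, 20].

Tolerances: relative function tolerance 1e-8, at most 2000 simplex
iterations per restart; default 20 restarts, best restart returned.
Restart initial points matter more than tolerances here: whenever μ is
large relative to the scale of the utilities, every choice probability
saturates and (after probability clamping) the likelihood is constant in
large regions of the box, so a simplex started there stalls immediately.
Restarts therefore draw μ log-uniformly across its bounds and the
remaining parameters uniformly, and the first restart is pinned at neutral
valuation (α = λ = γ = 1) with μ set to the reciprocal median |ΔU| — a
scale-matched start that lies in the informative basin for any outcome
encoding. Determinism: results are reproducible given (data, model,
restarts, seed), and cohort fits derive per-(subject, model) seeds from
the master seed by label hashing, so adding or removing a model leaves all
other cells unchanged.

Numerical conventions: choice probabilities are clamped to
[1e-12, 1 − 1e-12] before logs, keeping the likelihood finite under
near-deterministic parameters; 0^γ and 0^α are defined as 0 (continuous
extension) so the b = 0 and $0 arms are defined for all exponents; AIC =
2k + 2·NLL with k the number of free parameters.

## Group-level model selection

Per-subject log model evidence is approximated as −AIC/2. `rfx_bms()`
treats model frequencies r in the population as Dirichlet-distributed
(unit prior counts) with a latent per-subject model assignment, and runs
the standard variational scheme: responsibilities
g_nk ∝ exp(L_nk + ψ(α_k) − ψ(Σα)), counts α = α₀ + Σₙ g_n, iterated to a
1e-10 count tolerance (cap 500 iterations). Exceedance probabilities
(xp_k, the probability model k is the most frequent) are estimated from
10⁵ seeded Dirichlet draws. The Bayesian omnibus risk (BOR) is the
posterior probability of the null that all frequencies are equal, computed
from the variational free energy of the random-effects model against the
null's exact evidence Σₙ log(mean_k exp L_nk); protected exceedance
probabilities blend the two: pxp = (1 − BOR)·xp + BOR/K. The winner is the
highest-pxp model, ties broken to the lowest index and flagged.

Two structural identities are useful for testing and hold by construction:
the blending identity above, and (for K = 2, one subject) xp equal to a
Beta tail probability.

## The synthetic-cohort generator

The generator stands in for undeposited subject data. It emulates: the
121-lottery × 3-repetition design with per-subject randomised order;
Bernoulli choices from the logistic rule under per-subject parameters; and
across-subject heterogeneity as independent log-normals per parameter,
with median equal to an anchor value and log-scale spread chosen so the
quartiles match an anchor interquartile range (when the lower quartile is
0, the spread falls back to the median-to-upper-quartile distance). The
anchor table (`default_param_anchors()`) holds, per task and model, the
across-subject medians and IQRs representative of the study population
this generator emulates — e.g. for the winning effort-task hybrid model
λ = 0.71 [0.14, 0.99], γ = 1.61 [1.21, 4.21], μ = 0.064 [0.00, 0.338].
Point-mass mode (`distribution = "point"`) puts every subject exactly at
the anchor medians and is what the recovery checks use.

The generator also emits cosmetic `strength` labels (strong/weak by
thresholding |ΔU| at its within-subject median) and response times (a
decreasing noisy function of |ΔU|). Both exist for schema completeness
only: no response-time model is implemented, and neither column is ever
used in fitting.

What the generator does **not** emulate: trial-order or learning effects,
within-subject parameter drift between sessions, perceptual noise on the
displayed percentages, and any relation between choices and movement
kinematics. Passing recovery tests therefore show that the estimator and
model-selection machinery are correct and calibrated *under the model's
own assumptions*; they cannot show that real subjects satisfy those
assumptions.

## Confusion analysis and its prior

`confusion_analysis()` simulates cohorts from each generating model, fits
every candidate, runs BMS, and records the winner; identifiability means
recovering the generator on the diagonal. The generating parameters are
drawn from a prior. The default is the generator's own population model
(log-normal around the anchors, `anchor_param_prior()`). A box-uniform
prior over the fitting bounds (`uniform_param_prior()`) is available but
deliberately not the default: with λ and γ uniform up to 10, most draws
produce deterministic corner boundaries on the 11 × 11 grid (e.g. "accept
only zero-loss lotteries") that a two-parameter encoding reproduces
exactly, so AIC prefers the smaller model and *no* space is fully
identifiable under that prior — an informative fact about the prior, not
about the models.

## Descriptive statistics

`rejection_matrix()` gives exact per-cell rejection frequencies (missing
cells are NA, never imputed) and `rejection_marginals()` the
rejection-vs-gain and rejection-vs-loss curves. Monotonicity of those
curves is tested with `mann_kendall_trend()`, implemented from its
definition — S = Σ_{i<j} sign(x_j − x_i), tie-corrected variance
n(n−1)(2n+5)/18 − Σ_t t(t−1)(2t+5)/18, continuity correction, two-sided
normal p — because trend-test conventions vary across implementations.
All other inferential steps (Shapiro–Wilk, Wilcoxon signed-rank, Pearson
correlation, repeated-measures ANOVA) are thin delegations to the standard
routines in base R's stats package. `sv_by_condition()` and
`loss_gain_ratio()` evaluate a fitted value function over the ten nonzero
conditions per domain; the ratio is 1 exactly iff λ = γ = 1, and the 0%
condition is excluded (zero-valued arms have no defined ratio).

## Problem sizes used in the checks

The package's own acceptance checks use the sizes a desk-scale replication
would: 20 simulated subjects on the 363-trial design with 20 restarts for
each recovery and for the group BMS; 3 Monte-Carlo repetitions with 10
restarts for the scaled-down confusion analysis (the hybrid generating
row); 10⁵ Dirichlet draws for exceedance probabilities. With these sizes
the full acceptance script runs in a couple of minutes on one CPU.

## Known limitations

- **The (λ, γ) ridge.** With γ free and choices near-deterministic, many
  (λ, γ) pairs imply the same accept/reject boundary on the grid, so the
  pair is identified only up to a boundary-preserving region. Median
  recovery across 20 subjects is accurate, but *individual* estimates can
  sit far along the ridge (occasionally at a bound). One consequence:
  cross-session Pearson correlation of raw per-subject λ estimates from
  two simulated sessions with shared latent parameters is weak (~0.3–0.55)
  at the winning model's median stochasticity, even though directionality
  (λ above or below 1) is consistent for the large majority of subjects.
  Strong raw-value correlations observed in real subjects should not be
  expected to reproduce from this generative process.
- **AIC evidence.** Model evidence is the AIC approximation, not a
  marginal likelihood; BMS results inherit that choice (made for
  comparability, and because only point fits are computed — no Hessians,
  no hierarchical fitting).
- **Upward finite-sample bias** in α/μ-type trade-off parameters is
  visible at n = 363 (e.g. median recovered α ≈ 0.85 when generating at
  0.74); the recovery checks budget for it.
- The repeated-measures ANOVA report uses `stats::aov` error strata and
  expects complete balanced tables; it is a report-stage convenience, not
  a mixed-model analysis.
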