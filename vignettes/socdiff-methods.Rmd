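---
title: "Methods: order-of-acquisition diffusion analysis in socdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: order-of-acquisition diffusion analysis in socdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socdiff)
```

## The inferential problem

An open-diffusion experiment seeds a trained demonstrator into a group and
records three event streams on a common experimental-time axis (hours from
the start of the social phase; sessions are concatenated, since the order
likelihood below is invariant to any monotone re-mapping of the clock):
successful solves, observations of solves (an observer close enough to watch
a successful operation), and first manipulations of the apparatus. The
question is whether the order in which naive individuals acquire the skill
tracks their opportunities to learn socially.

## The acquisition model

Individual $i$'s hazard of acquiring at time $t$ is

$$r_i(t) = \lambda_0(t)\,\left[s_{g(i)}\, z_i(t)\, e^{\gamma' x_i} + e^{\beta' x_i}\right]$$

* $z_i(t)$ — exposure under a network variant. Four are implemented:
  the **absolute observation** network (count of solves observed), the
  **individuals observed** network (count of distinct solvers observed),
  the **single observation** indicator, and a static **group** network
  (informed same-group individuals), the last serving as a null that a
  diffusion may simply track group membership rather than who watched whom.
* $s_g$ — the social-transmission rate per unit connection, relative to the
  asocial baseline; constrained across groups by hypothesis
  ($s_1 \ne s_2$, $s_1 = s_2$, $s_2 = 0$, $s_1 = 0$, or all zero).
* $x_i$ — individual-level variables (sex 0/1 as recorded; age centred at
  the untrained individuals' mean; rank centred at their median). This
  coding makes $e^{\beta' x} = 1$ for a female of middle rank and average
  age, so $s$ reads directly as a rate multiplier per unit exposure for
  that reference individual, and `relative_rate(s, n) = 1 + n s` is its
  expected speed-up after `n` observed solves.

The order-of-acquisition likelihood conditions each acquisition event on
the naive untrained risk set, so $\lambda_0(t)$ cancels; only the order of
acquisition carries information. Trained demonstrators are informed at
$t = 0$ and never enter a risk set.

### Conventions and degenerate inputs

* **Strictly-before edges.** An observation at exactly the acquirer's solve
  time does not contribute to that event's exposure (causality; the
  boundary is otherwise arbitrary).
* **Ties.** Tied acquisition times are broken by event-log order and the
  tied blocks are reported as a diagnostic.
* **Non-learner windows.** In per-individual summaries a non-learner's
  observation window closes inclusively at the group's final solve; a
  learner's closes strictly before its own first solve. Rates are kept
  unrounded internally and rounded half-even to 2 decimals only for
  reports.
* **Empty risk sets** are data errors, not silent zeros; a flat likelihood
  in $s$ (no exposure contrast) yields the honest interval $(0, \infty)$.

## Fitting, profiling, %ST

`fit_oada()` maximizes the likelihood with bounded quasi-Newton
(`L-BFGS-B`, $s \ge 0$, convergence tolerance about $10^{-8}$ on the log
likelihood via the optimizer's relative-tolerance control) from a fixed
5-point multi-start $s \in \{0.01, 0.1, 1, 10, 100\}$ with coefficients
started at 0 — the likelihood in $s$ can be flat over orders of magnitude,
and the multi-start makes the fit deterministic and start-insensitive.

Profile CIs for $s$ solve $2[\ell_{max} - \ell_{prof}(s)] = \chi^2_1(0.95)$
with nuisance parameters re-optimized at each fixed $s$; the upper bound is
reported as $+\infty$ when the profile deviance stays under the threshold up
to a ceiling of $10^6 \hat s$ (or $10^6$ when $\hat s = 0$). When the truth
lies on the boundary $s = 0$, the likelihood-ratio statistic is a 50:50
mixture of $\chi^2_0$ and $\chi^2_1$, so the interval excludes zero in about
2.5% (not 5%) of purely asocial datasets — the profile interval is slightly
conservative there by construction.

`%ST` is computed by **event-wise attribution**: the fitted social fraction
$s z e^{\gamma'x} / r$ of the acquirer's rate, averaged over acquisition
events ($\times 100$). Interval endpoints re-optimize nuisances at the $s$
profile bounds; an infinite upper bound maps to the limiting attribution
(fraction 1 at every event with positive exposure). Attribution by forward
simulation from the fitted model is a possible alternative; the event-wise
choice is recorded in the pipeline's output metadata.

## Model selection

Candidate sets cross networks, hypotheses and ILV patterns. With three ILVs
the default enumeration toggles each ILV in or out of the model as a whole
(on both rates jointly; $2^3 = 8$ patterns per network-hypothesis cell) —
the most parsimonious scheme consistent with "every combination of the
three ILVs"; a fully independent per-rate scheme ($4^3$) is available via
`scheme = "independent"`, since the enumeration that produces exactly 16
models per set is not reconstructable. The group network is fitted only
under $s_1 = s_2$ (it exists as a comparison null, not a hypothesis
family). Asocial models drop the social coefficients (they multiply a zero
term).

AICc uses $n$ = the number of acquisition events, the count of independent
multiplicative contributions to the likelihood. Support shares sum Akaike
weights within a category and are renormalized over a *named* comparison
set; the asocial set is excluded from share comparisons by default (it has
structurally fewer models) — evidence against asocial learning comes from
the profile CI instead. Model-averaged estimates weight each model's
$\hat s$ (zero where fixed by constraint).

## The multistate extension

Two transitions — naive $\to$ interacting (first manipulation) and
interacting $\to$ informed (first solve) — are modelled with disjoint
parameter blocks on the interleaved, globally time-ordered event sequence:
stage-1 events condition on the naive risk set, stage-2 events on the
interacting risk set. Both stages take exposure from the absolute
observation network (observations of *successful* solves only; unsuccessful
attempts are not modelled). Because the blocks share nothing, the joint
maximum factorizes and the stages are fitted separately, which is also more
robust. A solve with no prior recorded manipulation is coerced — both
transitions at the solve time, manipulation ordered immediately before the
solve — with a diagnostic. The between-group contrast in stage 1 is
summarized by profiling the ratio $s_2/s_1$ (ratio fixed, everything else
re-optimized) on the $s_1 \ne s_2$ model.

## The observation-network GLMM

Who watches whom is modelled directly: every solve is expanded over its
same-group candidate observers (everyone but the manipulator — presence at
the apparatus is unobservable and not modelled) into binary outcomes, with
group-specific fixed effects for maternal kinship, the manipulator-minus-
observer age and rank differences (the difference coding matches the
directional question "are older/higher-ranked individuals watched more?"),
and a carryover indicator for having watched the previous manipulation;
crossed observer and manipulator random intercepts absorb individual
propensities to watch and be watched. Priors are the module's own and
config-overridable: fixed effects $N(0, 2.5^2)$ (weakly informative on the
log-odds scale), random-effect SDs half-$N(0,1)$.

Sampling is a self-contained adaptive Metropolis-within-Gibbs: scalar
random walks for fixed effects and log-scale SDs, and vectorized
one-at-a-time updates for the random effects (each individual's rows are
disjoint, so the block accepts componentwise). Scales adapt toward a 0.44
acceptance rate during burn-in only, preserving detailed balance in the
kept draws; chain $c$ runs from seed `seed + c - 1`. Convergence is gated
on rank-normalized split R-hat < 1.05; odds ratios are back-transformed
posterior means with highest-posterior-density intervals (narrowest sorted
window), and between-group ratios come from per-draw coefficient
differences.

## The simulator and what the tests show

`simulate_diffusion()` generates whole experiments by competing
exponentials in continuous time: informed individuals solve as Poisson
processes; each solve is observed by each same-group individual
independently with its attendance propensity; naive individuals acquire
with the model's own hazard (exposures updated at observation events), and
an acquirer's first solve is appended as a solve event. Hazards are
constant between events, so the generated acquisition order follows exactly
the likelihood the package fits — recovery tests are internally consistent.
$\lambda_0$ exists only here, as the config constant `baseline_rate`; the
likelihood cancels it.

Defaults emulate the motivating study: two groups of 33, one trained
mid/high-ranking adult female demonstrator per group, 39 two-hour sessions,
demonstrator solve rate 25/h (the scale of the study's demonstrators),
attendance Beta(0.5, 5) — most individuals watch rarely, a few watch a lot,
matching observation counts concentrated on a subset. What the simulator
does *not* emulate: ball logistics and spatial structure (attendance is an
independent coin per solve), within-session clustering of solves, kin- or
rank-biased attendance unless configured, and coding error. Passing
recovery tests therefore demonstrate correctness of the estimator under the
model's own assumptions, not robustness to these real-data features.

The calibration studies use a deliberately informative desk-scale design:
one group of 30, demonstrator solve rate 1/h, attendance Beta(1, 3),
`baseline_rate` 0.05/h, stopping at 20 acquisition events. The baseline
rate was chosen (by a small pilot sweep, before the checks were frozen) so
that acquisitions interleave with exposure growth: much smaller values let
exposures grow so large that the likelihood flattens above and the MLE
diverges; much larger ones end the diffusion before exposure contrast
exists. Under this design the median recovered $\hat s$ at truth 2 sits
within 25% of the truth (200 replicates) and profile-CI coverage is at its
nominal 95% within 5 points; under truth 0 the interval excludes zero at
the boundary-mixture rate of roughly 2-3% (300 replicates).

## Interfaces and problem sizes

The package's functions are its interface; `run_pipeline()` ties the stages
together from a config list or YAML file (exactly one of input paths or a
simulation block; explicit seeds; artifacts stamped with a config hash) and
surfaces warnings — ties, coerced states, non-convergence — in the final
report rather than only in logs. The test suite runs the likelihood oracles
on 4-6 individual toys (where brute-force enumeration is exact to 1e-12),
the recovery studies at the 30-individual design above, and the GLMM
calibration on 10-12 individual designs with 2 chains of 1000 kept draws —
sizes chosen so each property is measured with adequate replication while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* One diffusion per analysis; no pooling across experiments.
* No time-of-acquisition (TADA) variant — by design, the order-only model.
* Inference on $s$ is profile-likelihood only; no Hessian standard errors.
* The multistate likelihood is stage-factorized; a shared baseline across
  transitions (as some multistate formulations define) is not implemented.
* The GLMM's candidate set is fixed per event; mortality, absence, or
  spatial availability of observers is not modelled.
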