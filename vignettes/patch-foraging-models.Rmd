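---
title: "Models and methods for depleting-patch foraging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for depleting-patch foraging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchforage)
```

## The reward process

A patch's hidden events follow an inhomogeneous Poisson process with
exponentially decaying rate $\lambda(t) = \lambda_0 e^{-t/\tau}$, $t$
measured in seconds from patch entry. The integrated rate over an
interval is the exact integral

$$\Lambda(t, s) = \lambda_0 \tau\, e^{-t/\tau}\bigl(1 - e^{-s/\tau}\bigr),$$

including the $e^{-t/\tau}$ start-time discount (the zero-offset special
case $\Lambda(0,s) = \lambda_0\tau(1-e^{-s/\tau})$ is what one usually
sees quoted; the general form is required for interval likelihoods and
additivity, $\Lambda(t,s_1+s_2) = \Lambda(t,s_1) + \Lambda(t+s_1,s_2)$).

Each event carries a volume $V_0$ and every $L = V_r/V_0$-th event is
observed as a droplet of volume $V_r = 2\,\mu L$: an inhomogeneous gamma
process. Holding $r_0 = V_0 \lambda_0$ fixed (default $2.5\,\mu L/s$,
interpreted as volume per second) decouples timing noise from expected
income: $E[V(s)] = r_0\tau(1 - e^{-s/\tau})$ is invariant in the
stochasticity index $RSI = V_0/V_r \in (0,1]$ while
$\mathrm{var}[V(s)] = V_0\,E[V(s)]$ grows with it. Because the $L$-th
event rule presumes an integer $L$, environment construction requires
$1/RSI$ integral to within $10^{-9}$ and errors otherwise.

Event sampling uses inversion (time rescaling): cumulative sums of unit
exponentials below the total mass $\Lambda(0, d)$ are mapped through the
closed-form inverse $\Lambda^{-1}(g) = -\tau\log(1 - g/\lambda_0\tau)$.
This is exact for exponential rates and faster than thinning. One root
seed per session derives per-patch streams from (seed, patch index), so
logs are reproducible and patches can be regenerated independently.

## Expected future reward times

Sequence-based models must often extend a patch's reward ladder past the
observed leaving time. To avoid conditioning on one realized
continuation, the *expected* time of the $M$-th future event after time
$t$ is used. Its CDF is $F_{S_M}(s) = P(N(t,t{+}s) \ge M)$; because the
residual mass $\Lambda(t,\infty)$ is finite, the $M$-th event may never
occur, so the expectation is taken conditional on occurrence,
normalizing by $F_0 = \lim_{s\to\infty} F_{S_M}(s)$. The integrand
$s\,\tilde f_{S_M}(s)$ uses the $M$-th-event density
$f(s) = \lambda(t+s)\,e^{-\Lambda}\Lambda^{M-1}/(M-1)!$ (the algebraic
sum over Poisson counts telescopes to this single term), and adaptive
quadrature is truncated where $F_{S_M}$ has saturated: at
$\Lambda(t,s_{max}) = \min\{\Lambda(t,\infty)(1-10^{-14}),\,
M + 10\sqrt{M} + 30\}$, which keeps the truncated tail mass far below
the $10^{-9}$ relative tolerance even in the near-homogeneous limit.
Rewards with $F_0 < 10^{-10}$ are reported as unreachable (`NA`) and
flagged downstream rather than extrapolated.

The first future reward needs fewer than $L$ events because hidden
events accrue between the last observed reward and patch-leaving. Their
expected count $L_0$ is the mean of a Poisson distribution truncated
below $L$. Since the CDF argument must be an integer number of events,
the first future reward uses $M_1 = \max(1, \mathrm{round}(L - L_0))$;
subsequent rewards add $L$ events each. This rounding is the one place
the real-valued correction meets the integer event count; at $L = 1$ it
is exact ($L_0 \equiv 0$).

## Heuristic and MVT models

Per animal, `fit_heuristics` computes the mean residence (HEU-CT, the
null), the mean last-reward-to-leaving delay $\bar{\Delta t}$ (HEU-ETR;
rewardless patches contribute their whole residence), and the mean
reward count $\bar M$ (HEU-NR). HEU-ETR scans the observed-plus-expected
ladder for the earliest gap $\ge \bar{\Delta t}$, including the
entry-to-first-reward gap, with ties firing; the degenerate
$\bar{\Delta t} = 0$ criterion returns the first ladder time (the
earliest moment a leave-after-reward rule can fire). HEU-NR interpolates
linearly in time for fractional $\bar M$ (nearest-reward rounding is
available by flag). Ladders are capped at 50 rewards; predictions that
exhaust the cap or hit unreachable rewards fall back to the last ladder
time and are flagged.

The MVT-optimal residence solves
$e^{-t/\tau}(t^{(t)} + t + \tau) - \tau = 0$, which also maximizes the
overall gain rate $E[V(t)]/(t + t^{(t)})$ and is independent of
$\lambda_0$. The equation is scalar with a guaranteed bracket on
$[0, 50\tau]$, so we solve it with Brent iteration (`uniroot`) rather
than a quasi-Newton update; a grid-search oracle test pins the two to
within 0.01 s. Inside the MVT-IM loss the root is re-solved thousands of
times, so a damped-Newton path with implicit-differentiation gradients
is used there (it agrees with the bracketed solver to $10^{-8}$).

MVT-IM minimizes $\|\hat y - y\|_2^2 + \lambda\|\hat\theta - \theta\|_2^2$
per animal with one perceived $\hat\tau$ per experimental decay rate and
one perceived travel time per track. $\lambda$ defaults to 1 in squared
seconds (no value is prescribed; inputs are kept in natural units, and
the regularizer mainly guards identifiability when environments are
few). Optimization is quasi-Newton (L-BFGS-B, positivity bounds)
initialized at the experimental parameters; if the optimizer fails to
improve on that initialization, the initialization is returned with a
diagnostic, so the fitted loss never exceeds the loss at $\theta$.

## Likelihood, MLE and MAP

The IGP log-likelihood of reward sequences
$t_1 < \dots < t_K$ observed for a window $T$ is, per patch,
$-\Lambda(T) + \sum_k [(L-1)\ln\Lambda(t_{k-1},t_k) + \ln\lambda(t_k)]
- K\ln((L-1)!)$, additive over patches. Setting the partial derivatives
to zero profiles $\lambda_0$ out:
$\hat\lambda_0(\tau) = (L\sum_m K_m + \alpha_\lambda - 1)\,/\,
(\sum_m \tau(1 - e^{-T_m/\tau}) + \beta_\lambda)$, leaving one scalar
equation in $\tau$ (the likelihood case is
$\alpha = 1, \beta = 0$). Both stationarity equations were re-derived by
hand and are validated against central finite differences of the
implemented log-density to a relative $10^{-5}$ in the test suite — the
analytic-gradient check is the contract that the solver targets the
function we claim.

The scalar equation is solved by bracket expansion plus the Illinois
(regula-falsi) iteration in compiled code; with proper priors
($\alpha_\tau > 1$, $\beta_\tau > 0$) a sign change always exists
because the equation diverges to $+\infty$ as $\tau \to 0$ and tends to
$-\beta_\tau < 0$ as $\tau \to \infty$. The pure likelihood can lack an
interior root on near-homogeneous data; `mle_fit` then falls back to
direct 2-D Nelder-Mead maximization in log-parameters. Zero-reward data
make the MLE degenerate ($\hat\lambda_0 = 0$, flagged); predictive use
always goes through a prior.

Gamma priors are parameterized by mode and variance,
$\beta = (m + \sqrt{m^2 + 4v})/(2v)$, $\alpha = 1 + m\beta$, which
forces $\alpha > 1$ so a zero-data MAP returns the mode exactly. Prior
variances are interpreted as *relative* (variance $= v \cdot m^2$) by
default: it is the only dimensionless convention that treats the
rate prior (events/s) and the decay prior (s) symmetrically; absolute
units are available via `relative = FALSE`. The "very weak" prior that
breaks the zero-reward degeneracy in MLE-x uses relative variance
$10^4$; its influence on post-first-reward estimates is below $10^{-3}$
relative.

## Threshold-crossing prediction

`predict_leaving` evaluates the MAP estimate on a 100 ms grid (the bin
is configurable); at bin $t_i$ the current patch contributes the rewards
observed up to $t_i$ and an observation window of exactly $t_i$, plus
the full sequences of up to $N-1$ preceding patches. History depth is
denoted $N$ = number of patches *including* the current one, so $N = 1$
is current-patch-only. The predicted residence is the first bin with
estimate $\le \lambda^*$ (ties fire); if no crossing occurs within the
horizon (default 2.5 times the cell's maximum observed residence,
bounded to [30, 240] s) the horizon is returned and the patch flagged.
Thresholds come from the MVT-IM parameters,
$\lambda^*_k = \lambda_{0,k} e^{-\hat t_k/\hat\tau_k}$ (MAP-IM-L), or
are refit per animal and environment by Nelder-Mead on log-thresholds
(MAP-IM-GL). Because the rate estimate does not depend on the threshold,
each training patch's estimate trace is computed once and the simplex
search only rescans crossings, which keeps refitting orders of magnitude
cheaper than re-estimation; if the search fails to strictly improve the
training RMSE the initial thresholds are kept. The prior grid search
(`grid_search_priors`) scans relative variances and history depths with
the same reuse and is deterministic, so its argmin is invariant to
session ordering.

## Synthetic sessions

The generator stands in for animal data. Environments follow the task's
published ranges ($\tau \in \{3, 6, 12, 24\}$ s, $RSI \in \{0.05, 0.5,
1.0\}$, two travel-cost levels); cohort-level experiments here default
to $RSI = 0.5$ (moderate stochasticity: reward sequences vary enough to
separate local from global models), four environments crossing fast/slow
decay with short/long travel, and 8 animals × 10 sessions × 40 patches,
sizes at which the model-comparison and regression analyses resolve
their effects in well under typical laptop-minutes. One printed RSI
range for the high-stochasticity analyses conflicts with the index's
definition ($RSI \le 1$ by construction); the simulator enforces
$RSI \in (0, 1]$.

Five agent families mirror the model families. The deterministic leave
criterion is computed first (for MAP agents, by running the same
compiled estimator the predictive model uses, so closed-loop tests are
exact replays); multiplicative log-normal decision noise and a linear
time-on-task drift are applied afterwards. Log-normal noise matches the
roughly log-normal residence distributions the filters assume; linear
drift matches the linear detrending the analysis applies — the generator
deliberately realizes the assumptions the pipeline is built to remove,
so round-trip tests isolate pipeline defects rather than model
mismatch. Travel intervals are the task-relevant cost plus log-normal
excess (median 2 s), so the 10th-percentile travel estimator is
exercised nontrivially. Head-fixed sessions add a piecewise-constant
velocity profile (stationary below 0.5 cm/s in patch, a running epoch
crossing the 5 cm/s leave threshold once per patch) and Poisson lick
trains (8 Hz in patch, 0.05 Hz outside); no biomechanical realism is
attempted because only threshold crossings and lick counts feed the
pipeline.

What passing on these data does *not* show: real animals exhibit
strategy switching, satiety nonlinearities, cross-session learning and
non-log-normal outliers that the generator omits, so test results
certify the pipeline's correctness, not any behavioral claim.

## Preprocessing conventions

Filters run in the narrated order (minimum patches, log-normal residence
outliers, reward-latency patches, the 10% session rule, minimum
surviving patches; head-fixed: engagement and the 50% animal rule), each
with strict-inequality boundaries (a value exactly at threshold is
retained). The outlier fit uses log10 moments and refits on the data at
hand by default; a fixed global $(\mu, \sigma)$ can be supplied, which
also makes the filter exactly idempotent (under refitting, re-application
can shrink the SD and exclude more — the global option is the
reproducible choice for frozen analyses). The 10th percentile of travel
times uses linear interpolation between order statistics
(`quantile` type 7; the convention is stated because nothing pins it
down). Lick-rate smoothing renormalizes the Gaussian kernel inside the
patch window so short patches are not biased below the 0.5 Hz
engagement threshold. Detrending fits one line per animal of residence
against within-session patch number and removes the slope component
about its mean, preserving the animal's mean residence.

## Evaluation machinery

The cluster bootstrap resamples the environment → animal → session →
patch tree with the per-level minimum node count, giving balanced
replicates of size $N_1 N_2 N_3$ per environment group; groups are
pooled and Pearson's r against the numeric parameter value (a rank
option exists) is computed per replicate, with percentile intervals.
Cross-validation splits each session into five contiguous blocks so
every fold represents every session. The comparison table computes MAE,
RMSE and $R^2$ against the per-animal mean residence — the convention
that makes the constant-per-animal null exactly $R^2 = 0$ on its
training data — with percentile bootstrap intervals over the pooled
error set.

The rate-error regression uses the sign convention error = estimated −
true (overestimation positive, matching the intuition that
overestimating the rate prolongs residence), excludes points outside the
Mahalanobis ellipse at the $\chi^2_2$ 99th percentile fit on the
training folds only (refitting per fold avoids test leakage; a pooled
option exists), and reruns the identical pipeline on residences shuffled
within session as its control. The shuffled estimate re-truncates each
patch's recorded rewards at the shuffled residence. One caveat found
during validation and worth knowing: finite-window estimation leaves a
small positive mechanical correlation (r ≈ 0.1 at moderate noise) even
for decision-independent agents, visible in both the observed and
shuffled pipelines; inference should therefore always be made against
the shuffle control, not against zero.

## Numerical choices and limitations

Evaluation-bin ties fire the crossing; residence times are floored at
1 ms; truncated patches (criterion never fired within the horizon) are
flagged, never silently clamped. The package fits point estimates only —
no posterior sampling, no hierarchical priors across animals — and
delegates linear-mixed-model fitting to external packages via
`lmm_design_matrix`, which emits the [0, 1]-normalized design described
in the methods it mirrors. Audio stimulus synthesis is out of scope; the
reward-cue tone formula (`cue_frequency`, two semitones per reward) is
included as metadata only.
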