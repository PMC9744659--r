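---
title: "Interacting population rate functions: model, fitting, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interacting population rate functions: model, fitting, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iprf)
```

## The scientific problem

Simultaneous multi-electrode recordings from several brain areas show
transient intervals of high population firing — population bursts — whose
timing varies from trial to trial. If information propagates across areas
through these bursts, the trial-by-trial timing of a burst in one area should
covary with the timing of the corresponding burst in connected areas. Naive
estimates of single-trial peak times (smooth each trial's population rate and
take the argmax) are so noisy that real coupling can be completely masked.

`iprf` implements a hierarchical point-process model that estimates, for each
trial, how much each area's response peaks shift in time and how much its
overall rate scales, and then summarizes the cross-area covariance of those
trial features. Denoising happens through three channels: a condition- and
area-specific firing-rate *template* shared across trials, a restriction of
trial-to-trial variation to *peak-time shifts and a gain*, and a focus on the
subset of neurons that actually participates in the coordinated population
response.

## The model

For area $a$, condition $c$, trial $r$, and neuron group $g$, the merged
group spike train is an inhomogeneous Poisson process,

$$y_{g,a,r,c}(t) \sim \mathrm{Poisson}\big(N_{g,a,c}\,\lambda_{g,a,r,c}(t)\big),$$

with per-neuron log intensity

$$
\log \lambda_{g,a,r,c}(t) =
\begin{cases}
f^{\mathrm{pop}}_{a,c}\!\big(\varphi^{-1}_{a,r,c}(t)\big) + q^{\mathrm{gain}}_{a,r,c} & g = \mathrm{pop}\\[2pt]
f^{\mathrm{local1}}_{a,c}(t) & g = \mathrm{local1}\\[2pt]
f^{\mathrm{local2}}_{a,c} & g = \mathrm{local2.}
\end{cases}
$$

Each neuron belongs to one of the three groups through a categorical
indicator $z_{a,c}(n)$ with probabilities $p_{a,c}$. The templates
$f^{\mathrm{pop}}$ and $f^{\mathrm{local1}}$ are cubic penalized splines (100
equally spaced knots on the 500 ms window, 102 basis functions, second-
derivative roughness penalty with weight chosen by fivefold cross-validation
over trials); $f^{\mathrm{local2}}$ is a constant.

The warp $\varphi_{a,r,c}$ is piecewise linear through the join-points
$(0,0)$, $(t_{1L},t_{1L})$, $(t_{p1}, t_{p1}+q^{\mathrm{peak1}})$,
$(t_{1R},t_{1R})$, $(t_{2L},t_{2L})$, $(t_{p2}, t_{p2}+q^{\mathrm{peak2}})$,
$(t_{2R},t_{2R})$, $(T,T)$: it moves each template peak by a trial-specific
shift while pinning the domain boundaries. The per-area feature triples
$(q^{\mathrm{gain}}, q^{\mathrm{peak1}}, q^{\mathrm{peak2}})$ stack across
areas into a 9-dimensional vector $q_{\cdot,r,c} \sim N(0, \Sigma)$; the
36 pairwise correlations derived from $\Sigma$ are the scientific output.
Priors: $\Sigma \sim IW(\Psi_0, \nu_0)$ with $\nu_0 = 3A+1$ and
$\Psi_0 = 2\Phi_0$, $\Phi_0$ diagonal at the anticipated feature scales
(defaults 0.3 for gains, 6 ms and 30 ms for the two peaks);
$p_{a,c} \sim \mathrm{Dirichlet}(5,5,5)$.

### Discretization of the likelihood

All likelihoods are discretized point-process likelihoods on 2 ms bins. A
subtle but consequential choice is *where* the warp enters. We evaluate the
model in trial time: the warped template
$f(\varphi^{-1}(u_j))$ is computed at every trial-bin midpoint $u_j$ by
piecewise-linear interpolation of the template between its grid values, and
the raw binned counts are scored against
$\mu_j = N e^{f(\varphi^{-1}(u_j)) + q^{\mathrm{gain}}}\,\Delta$. This is the
direct discretization of the model's intensity and is smooth in the peak
shifts. Two tempting alternatives fail: re-binning warped *spike times*
against the unwarped template with a warp-independent integral embeds the
warp's time-compression factor into the spike term only, which biases shift
estimates toward zero; and reading the binned train off at warped times does
not conserve spike counts, so the "likelihood" can be improved by warps that
drop spikes. Both failure modes are easy to demonstrate by plotting the
expected log-likelihood profile of data generated at a known shift — only
the trial-time form peaks at the true shift. For the template M-step the
equivalent template-grid form (warp-aligned counts plus bin-time occupancy
weights on the integral) is used so that the update stays a penalized
Poisson GLM.

## Fitting

`iprf_fit()` runs three stages.

**Initialization** (`iprf_init`): neurons are ranked by total in-window
spike count (merged across conditions and trials) and split 25% / 50% / 25%
into pop / local-1 / local-2; templates are fitted from those groups by
penalized splines; warp landmarks are located on each initial population
template by grid search for the two dominant local maxima, with domain
boundaries where the rate falls to a configured fraction of the peak's local
prominence; all features start at zero.

**Hard EM** (`iprf_hard_em`): coordinate ascent over conditional posterior
modes — templates by penalized Poisson fits on warp-aligned trains, features
by per-trial 9-dimensional numerical optimization (Nelder–Mead, seeded on
early iterations by per-area one-dimensional grid searches because the
trial-blurred initial template makes the posterior nearly flat near zero),
memberships by conditional argmax, membership probabilities by the Dirichlet
mode, and the covariance by the inverse-Wishart conditional. Two departures
from a purely modal scheme proved necessary in moderate-information regimes:

* *Landmark re-location.* The initial template is blurred by the very
  trial-to-trial shifts the model is meant to estimate, which biases the
  landmark domains narrow. After two EM iterations — once the template has
  partially sharpened — the landmarks are re-located and the features are
  re-expressed relative to the new peak positions. They are frozen from then
  on, in particular throughout Gibbs sampling.
* *Laplace E-step correction.* The modal features are shrunk relative to the
  latent features; updating $\Sigma$ from modal cross-products alone
  compounds this shrinkage each iteration and can collapse the feature
  variance entirely. We therefore add each trial block's conditional
  covariance (inverse curvature at the mode: per-area finite-difference
  likelihood curvature plus the exact prior precision) to the cross-product
  matrix, restoring $E[qq^\top]$ to first order.

**Metropolis-within-Gibbs** (`iprf_gibbs`): cycles five blocks per
iteration.

* Template coefficients: random-walk MH with fixed proposal covariance
  $0.05\,Q$, where $Q$ is the inverse penalized observed information at the
  hard-EM mode (the $5.76/d$ rule at $d = 102$) and the target is the
  warped-data likelihood plus the roughness prior.
* Features: per-trial 9-dimensional MH with proposal covariance
  $(5.76/9)\,Q_q$, $Q_q$ the blockwise Laplace covariance at the EM mode.
  The $5.76/d$ scale is applied at the block's own dimension; applying the
  102-dimensional value (0.05) to this 9-dimensional block makes the walk an
  order of magnitude too short-stepped and the joint
  (feature-spread $\leftrightarrow$ covariance) mode mixes far too slowly
  for practical chain lengths. With probability 0.2 the proposal mean is
  recentred by half the across-trial feature mean — the identifiability
  device that stops template position and a shared shift from drifting
  jointly — with the exact non-symmetric Hastings correction; the remaining
  proposals are symmetric random walks. Using the recentred form on every
  draw collapses the acceptance rate as the trial mean fluctuates, because
  the implied displacement is large relative to the proposal spread.
  Proposals whose peak shifts leave the warp domain are rejected through the
  target (the warp is undefined there), which avoids box-truncated
  multivariate-normal normalizing constants while sampling the identical
  posterior.
* Memberships: exact categorical draws from the per-neuron group
  log-likelihoods plus $\log p_{a,c}$.
* Membership probabilities: exact Dirichlet draws with concentration
  $N_g + 5$.
* Covariance: exact inverse-Wishart draw
  $IW(\Psi_0 + \mathbf{q}^\top\mathbf{q},\ \nu_0 + RC)$.

Acceptance rates are logged per block and a message is emitted when a block
leaves $[0.2, 0.8]$.

## The synthetic-data generator

`simulate_iprf()` draws from exactly this generative model. The default
two-peak template mimics a strong evoked visual response: a sharp onset
transient (peak ~120 spikes/s per neuron at 57 ms, SD 13 ms), a sustained
plateau (~28 spikes/s from ~140 ms to ~430 ms) representing the continuing
stimulus drive, and a narrow second peak (~80 spikes/s, SD 18 ms) at 216 ms
riding on that plateau. The two-scale structure of the late response
matters: the narrow top is what carries per-trial information about the
peak-2 time, while the broad plateau is what makes the landmark domain wide
enough to contain realistic peak-2 shifts (SD 30 ms). A template whose
late peak is a single broad bump carries almost no per-trial timing
information, and one whose narrow peak lacks the plateau yields landmark
domains far narrower than the shift distribution. The local-1 template is a
slow, broad stimulus modulation without sharp bursts (rising to ~18
spikes/s near 150 ms), and local-2 is the 5 spikes/s baseline.

The default ground-truth feature covariance uses SDs (0.1, 5 ms, 30 ms) for
(gain, peak-1, peak-2) and cross-area correlations (0.3, 0.6, 0.85) —
calibrated to the variability and coupling reported for the mouse visual
data. Feature draws whose peak shifts leave the warp domains are
rejection-resampled; spikes are drawn per neuron as per-bin Poisson counts
at 2 ms with times placed uniformly within bins. `inject_neuron_noise()`
perturbs each neuron's log intensity by an independent smooth random spline
(coefficient SD 0.1 at scale 1, variance ×20 for the stress setting),
emulating intensity-shape diversity the population model does not capture.

What the generator does *not* emulate: non-Poisson spiking (refractoriness,
bursting), behavioral covariates (running, eye movements), condition-
dependent template shapes beyond what the fitted templates absorb, and
history dependence. Passing recovery tests on these data therefore
demonstrates correctness of the inferential machinery under the model's own
assumptions, not robustness to every feature of real recordings — the
noise-injection setting probes one structured violation.

## Study conditions and problem sizes

The parameter-recovery experiment (`recovery_experiment()`) uses 3 areas,
3 conditions, 15 trials per condition, 30 neurons per area with membership
probabilities (0.25, 0.50, 0.25) (about 7–8 interacting neurons per area and
condition), 20 replicates, hard EM (≤15 iterations) followed by 600 Gibbs
iterations with 200 burn-in. Three conditions were chosen from the sensible
3–4 range to keep a full experiment around a quarter of an hour on one CPU.
Posterior point estimates are medians; intervals are the (0.025, 0.975)
quantiles. The landmark prominence fraction is set to 0.25 for these data
so the peak-2 domain boundaries land on the plateau's rise and fall,
covering roughly ±2 SD of the true shift distribution.

Two caveats worth stating plainly. First, with 45 latent feature vectors
per replicate, the sampling floor of a correlation estimate is about
$1/\sqrt{42} \approx 0.15$ for weakly correlated pairs; recovery RMSE at
this scale cannot approach what is achievable with, say, 13 conditions
(195 trials). Second, at 7–8 interacting neurons the per-trial peak-time
information is modest (posterior SD of a peak-2 shift around 7–15 ms), so
point estimates of the strong peak-2 correlations remain noticeably
attenuated after short chains, and the posterior intervals are wide.

## Numerical choices

* Bins are half-open $[t, t+\Delta)$; a spike at exactly $T$ is dropped.
* Penalized Poisson fits use damped Newton iterations with step halving,
  stopping at relative objective change $10^{-8}$.
* The roughness penalty is integrated exactly (two-point Gauss–Legendre per
  knot interval; the integrand is piecewise quadratic).
* Cross-validation folds split trials with a deterministic seeded shuffle;
  the smoothing weight is selected on one representative area/condition and
  shared, since per-condition curves have comparable smoothness and counts.
* Activity ties in the neuron ranking break by neuron id; equal `t1R` and
  `t2L` (shared boundary) are allowed and deduplicated in the warp.
* Proposal covariances are regularized to positive definite by relative
  eigenvalue flooring at $10^{-8}$.
* Peak shifts are kept 2 ms (one bin) inside their open domains.
* Hard EM stops on relative objective change below tolerance or after the
  objective fails to increase three times in a row.

## Known limitations

* The inverse-Wishart update treats the feature prior as an untruncated
  normal although both the generator and the posterior restrict shifts to
  the warp domains; the missing normalizing-constant term biases the
  covariance scale slightly downward. The same simplification is inherent
  to the conjugate update itself.
* Membership label switching between `pop` and `local-1` is prevented only
  by initialization (activity ranking) and by the templates' distinct
  shapes, not by any ordering constraint.
* Landmarks are frozen after their one re-location; a template whose peaks
  move materially during sampling would leave the domains stale.
* Single-peak data cannot be fitted: landmark screening requires two local
  maxima by design.
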