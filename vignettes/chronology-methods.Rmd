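---
title: "Bayesian chronometric modelling with baychron: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian chronometric modelling with baychron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baychron)
```

# The problem

A radiocarbon laboratory reports a conventional radiocarbon age $x \pm
\sigma$ in ^14^C years BP. Because atmospheric ^14^C production varies,
the mapping from calendar age $\theta$ (years cal BP, before AD 1950) to
expected ^14^C age is the empirical calibration curve $\mu_c(\theta) \pm
\sigma_c(\theta)$ — IntCal20 for terrestrial samples, Marine20 for marine
samples. baychron implements the Bayesian machinery that archaeological
chronologies are built from: single-date calibration, multi-phase models
with boundary estimation and outlier handling, estimation of the local
marine reservoir offset $\Delta R$ from paired charcoal/shell dates, and a
non-monotonic age–depth regression for disturbed sediment cores. Every
estimator ships with a seeded simulator that generates data with known
truth, so recovery can be demonstrated rather than assumed.

# Single-date calibration

The calendar-age posterior on a grid with uniform prior is

$$p(\theta \mid x, \sigma) \propto
  \mathcal N\!\big(x;\ \mu_c(\theta),\ \sqrt{\sigma^2 + \sigma_c(\theta)^2}\big),$$

normalised over the grid cells. Marine samples add the local reservoir
offset: $\mu_c(\theta) + \Delta R$ in the mean and $\sigma_{\Delta R}^2$
in the variance. Numerical choices:

* grid step 1 yr for reported single dates; 5 yr inside MCMC summaries
  (the difference in point summaries on smooth curves is under 5 yr, which
  the tests assert);
* curve interpolation is piecewise linear in both $\mu_c$ and $\sigma_c$,
  exact at knots, with **no extrapolation** — a request outside curve
  support is an error, because silent extrapolation corrupts posteriors;
* highest-posterior-density sets collect grid cells by descending mass;
  cells tied with the cut density are all included (symmetric multimodal
  dates otherwise force an arbitrary choice);
* the mode of a calibrated density breaks ties toward the older age, for
  determinism;
* a date whose likelihood mass on the requested grid falls below 1e-300
  raises a degenerate-posterior error instead of returning noise.

The agreement index between a date's unmodelled calibration $p$ and its
modelled posterior $q$ on a shared grid is the OxCal-style overlap
$A = 100 \cdot \sum_i q_i p_i / \sum_i p_i^2$, with $A = 100$ for an
untouched date; $A < 60\%$ is the conventional screening threshold, and
the threshold is exposed as an argument rather than hard-coded.

# The phase model

Dated events $\theta_i$ are grouped into ordered depositional phases
delimited by start/end boundaries. Two boundary treatments are supported.

**Uniform boundaries.** Events are uniform on $[e_j, a_j]$ and excluded
outside. A naive flat prior on the boundaries makes the implied prior on
the span $s_j = a_j - e_j$ strongly informative once the $n_j$ uniform
densities $s_j^{-n_j}$ are included. We therefore apply a span
correction: with the boundaries confined to an overall range of width
$R$, the joint prior is

$$p(\theta, a_j, e_j) \;\propto\; \prod_{i \in j} U(\theta_i; e_j, a_j)
  \;\times\; (R - s_j)^{-1},$$

which makes the marginal prior of the span *exactly* Uniform$(0, R)$ for
every member count $n_j$ — the `prior_predictive_span()` operation samples
boundaries from the prior with the same MCMC machinery and the test suite
checks the span distribution against Uniform$(0,R)$ by a Kolmogorov–
Smirnov test. (The more commonly quoted correction factor $s^{-1}$ makes
the span prior flat only on an unbounded range; inside a finite range it
leaves a residual $s^{n-1}(R-s)$ tilt, so we prefer the form above, which
is exact. For spans well inside the range the two behave alike, and the
joint density still falls monotonically as a phase is widened at fixed
events, which is what makes phase spans identifiable.)

**Sigma boundaries.** Physical boundaries between depositional units are
fuzzy; a hard cut-off misreads dates that straddle them. The sigma
treatment replaces the indicator with a plateau on $[e_j, a_j]$ and
Gaussian tails of scale $\tau_j$ outside:

$$f(\theta) = \frac{1}{s_j + \sqrt{2\pi}\,\tau_j} \times
  \begin{cases} 1 & e_j \le \theta \le a_j\\
  \exp\!\big(-d(\theta)^2 / 2\tau_j^2\big) & \text{otherwise,}
  \end{cases}$$

with $d$ the distance to the nearest plateau edge and $\tau_j \sim$
half-Normal(100 yr) by default (`tau_scale`). The reported boundary is the
plateau edge. Abutting sigma phases may overlap through their tails;
contiguous models share one boundary between neighbours, so $K$ phases
have $K+1$ boundaries.

**The general outlier model.** Each date carries a prior probability
(default 0.05) of a heavy-tailed calendar shift: the measurement relates
to $\theta_i + \phi_i\, t_i 10^{u_i}$ with $\phi_i \sim$ Bernoulli(0.05),
$t_i \sim t_5$, $u_i \sim U(0, 4)$. Shifts from single years to ten
thousand years are therefore entertained, and the posterior mean of
$\phi_i$ is the date's outlier probability.

## Sampling

The posterior is explored by Metropolis-within-Gibbs:

* componentwise random-walk updates for event ages (vectorised over
  dates, which are conditionally independent given boundaries);
* per-boundary updates that alternate a random walk with an independence
  draw from the power-law shape $q(s) \propto s^{-n_j}$ of a uniform
  boundary's full conditional (inverse CDF computed in log space). The
  independence draw matters: when an outlier flag switches on, the
  phase span must collapse by hundreds of years at once, which a tuned
  random walk cannot do;
* log-scale random walks for $\tau_j$ and the residual scatter;
* a Gibbs flip of each $\phi_i$ from its full conditional, recorded in
  Rao–Blackwellised form (the full-conditional probability rather than
  the 0/1 draw — same expectation, far less variance);
* a measurement-preserving *switch* move that flips $\phi_i$ while
  translating $\theta_i$ by the shift, leaving $\theta_i + \text{shift}_i$
  (and hence the measurement term) invariant. Its acceptance ratio
  reduces to the prior odds times the phase-prior ratio at the translated
  age. Without this move the sampler cannot leave the mode in which a
  phase has widened to absorb a shifted date at face value; with it, the
  flag switches on, the independence boundary draw collapses the span,
  and the reverse switch becomes impossible — the chain settles into the
  outlier explanation when the data support it. The move is repeated
  three times per sweep because it costs no likelihood evaluations and
  productive shift proposals are rare.

Step scales adapt toward 44% acceptance during burn-in only, so a fixed
seed yields bit-identical draws. Chains (default 4 × 20,000; the examples
and tests use smaller, stated sizes) are summarised with split R-hat and
an autocorrelation-based effective sample size; R-hat > 1.05 on any
boundary flags the result rather than raising.

Initialisation uses single-date posterior medians for events and member
extremes ± 50 yr for boundaries, jittered up to 1000 times until the log
posterior is finite. The overall range defaults to the union of 99.9%
single-date supports padded by 500 yr and clipped to curve support.

# Reservoir offset estimation

Shells and charcoal from the same stratigraphic context share one event
age $\theta_c$; a single $\Delta R$ is shared across contexts
(a per-context $\Delta R$ is out of scope):

$$x^{terr}_{ck} \sim \mathcal N(\mu_I(\theta_c), \cdot), \qquad
  x^{mar}_{ck} \sim \mathcal N(\mu_M(\theta_c) + \Delta R, \cdot), \qquad
  \Delta R \sim U(-w, w).$$

The "wide restriction" halfwidth $w$ defaults to 1000 ^14^C yr. After a
first fit, samples whose agreement index is below 60% are listed as
excluded and the model is refitted once without them — mirroring a
screening step in which flagged samples are not carried into the next
modelling stage. For the marine agreement reference we calibrate each
shell with the current posterior mean ± sd of $\Delta R$ (the choice the
model itself implies; the screening outcome is insensitive to moderate
alternatives). Contexts whose terrestrial and marine supports cannot
overlap within the prior bounds raise a divergence error naming the
context.

# Age–depth regression without monotonicity

For a core with dated depths $d_i$:

$$\theta_i = \beta_0 + \beta_1 d_i + \varepsilon_i,\quad
 \varepsilon_i \sim \mathcal N(0, \sigma_\varepsilon), \qquad
 x_i \sim \mathcal N\big(\mu_c(\theta_i), \sqrt{\sigma_i^2 + \sigma_c^2}\big).$$

No ordering constraint is placed on the $\theta_i$. In high-energy
littoral settings, storms redeposit old material above young — the age
reversal count (`count_reversals()`, adjacent calibrated means by depth)
is the diagnostic — and a monotone age–depth model then becomes unduly
precise: it must explain reversed dates as tiny measurement errors. The
test suite demonstrates this on simulated disturbed cores, where the
regression's slope intervals stay calibrated while a monotone
interpolation baseline (isotonic fit ± calibration error, implemented
only as a test oracle) under-covers.

Latent ages are sampled explicitly so the calibration likelihood enters
exactly as in single-date calibration; $(\beta_0, \beta_1)$ get a
conjugate Gibbs draw, $\sigma_\varepsilon$ a log random walk. Priors
default to $\beta_0 \sim \mathcal N(\text{curve centre}, 10{,}000)$,
$\beta_1 \sim \mathcal N(0, 10{,}000\ \text{yr/m})$, $\sigma_\varepsilon
\sim$ half-Normal(1000 yr); all configurable. Samples are sorted by
(depth, lab code) before fitting, which makes the posterior — which is
exchangeable in the samples — reproducible regardless of input row
order. Imputation at an undated depth $d^*$ draws $\beta_0 + \beta_1 d^*
+ \varepsilon^*$ per retained draw, so predictive variance always
dominates the regression-line variance.

One behaviour of the latent-variable construction is worth knowing: the
observed scatter of a core decomposes as roughly $\sigma_\varepsilon^2 +
\sigma_{lab}^2$, so *overstating* the laboratory errors reallocates
scatter away from $\sigma_\varepsilon$ — its posterior shrinks, and the
line-plus-scatter imputation interval can narrow even though each latent
calendar age at a dated depth becomes (correctly) more uncertain. The
test suite asserts the latter, which is the well-posed direction of
calibration-error propagation.

# The simulators and what passing tests show

`sim_cal_curve()` builds curves as identity + sinusoid + smooth seeded
noise with constant knot error; `sim_phased_site()` draws event ages
uniform within phase truths, applies Student-t(5)-scaled shifts to an
outlier fraction (matching the inference family, so recovery tests are
well-specified), and maps through the curve with lab error;
`sim_paired_reservoir()` shares one age per context; `sim_core()` builds
a linear core with redeposited intrusions. Every generator is a pure
function of (config, seed): reruns are byte-identical and the caller's
RNG state is restored. Truth tables record every latent variable.

What the simulators do *not* emulate: real calibration-curve plateaus and
reversals at their observed positions, species- or pretreatment-specific
offsets, δ^13^C fractionation, and non-Student outlier mechanisms. Passing
recovery tests therefore show the estimators are correct and calibrated
under the stated generating processes — not that any particular field
dataset satisfies those processes.

## Reference study conditions

The validation studies fix these conditions once (chosen to mirror a
small coastal cave chronology) and the tests run them under fixed seeds:

* *Phase-start recovery*: single phase 8500–7500 cal BP, n = 30 dates,
  lab error 40 ^14^C yr, uniform boundaries, 100 replicates; 95% HPD
  coverage of the start is asserted within the binomial band [89%, 99%]
  and aggregate bias under 50 yr.
* *Outlier screening*: 20 dates on the same span. The detection arm
  injects a +1000-yr calendar shift into one date and uses uniform
  boundaries — the sharpest detector, since a hard edge cannot absorb the
  shifted date. The false-positive arm uses sigma boundaries, the
  boundary type of the site model whose published diagnostic this
  mirrors; their tails absorb ordinary lab-error flukes, keeping clean
  maxima low. The arms differ deliberately: one measures detection power,
  the other the quiet behaviour of the production configuration. (Under
  hard uniform boundaries a clean date at a phase edge with a ±2.5σ lab
  fluke is *genuinely* ambiguous with an outlier — long-run posteriors
  confirm values up to ~0.9 — so a uniform-boundary false-positive arm
  would measure that ambiguity, not estimator quality.)
* *ΔR recovery*: true ΔR 150 ^14^C yr, 5 contexts × (2 charcoal + 3
  shells), lab error 35, prior halfwidth 1000.
* *Age–depth*: β0 = 3000 cal BP, β1 = 1500 yr/m, σε = 100 yr, 12 depths
  0.25–3 m, 2 of 12 samples redeposited +800 yr, lab error 40.
* MCMC sizes in the studies are 2 chains × 1500–2600 iterations with
  burn-in 600–1000 — enough, with the independence boundary draws and
  Rao–Blackwellised outlier probabilities, for the coverage statistics to
  be dominated by the posterior rather than Monte Carlo error.

# Display conventions

Calendar ages are carried in years cal BP everywhere; `ka` is a
display-only unit equal to cal BP / 1000 rounded to 0.1 (so a start
boundary with posterior mean 8491 cal BP prints as 8.5 ka). Raw cal BP
values are always retained in tables.

# Known limitations

* Uniform and sigma phases cover the common depositional designs;
  sequences with internal ordering constraints beyond phase membership
  are not implemented.
* One shared ΔR per analysis; time-varying or species-specific offsets
  are out of scope.
* The samplers are tuned for desk-scale models (tens of dates, a handful
  of phases); thousands of dates would call for a compiled backend.
* Curve mixing for part-marine diets and post-bomb calibration are not
  supported.
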