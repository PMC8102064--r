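---
title: "Amortized likelihoods for sequential sampling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amortized likelihoods for sequential sampling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sequential sampling models (SSMs) explain choices and response times as the
first passage of a noisy evidence particle through decision boundaries. The
drift diffusion model (DDM) — constant drift $v$, symmetric bounds at $\pm
a$, relative start $w$, nondecision time $\tau$ — has a tractable
first-passage-time density, but nearly every scientifically interesting
variant (state-dependent drift, heavy-tailed noise, collapsing bounds, races
between more than two accumulators) does not. Fitting such models then
requires simulation-based ("likelihood-free") inference, and classical
approaches re-simulate tens of thousands of trials for every parameter
vector visited by a sampler.

`lanssm` amortizes that cost. It simulates the model once, on a broad
"trained region" of parameter space, converts the simulations into empirical
likelihoods, and trains a small neural network to interpolate them. The
trained network is then a drop-in log-likelihood evaluator: posterior
sampling for any observed dataset costs forward passes, not simulations, and
the same network serves single-subject, hierarchical and condition-split
analyses without retraining.

Two encapsulations are provided:

* **Pointwise (MLP)**: maps $(\theta, \mathrm{rt}, c)$ to the scalar
  log-likelihood $\log \hat\ell(\theta \mid \mathrm{rt}, c)$. Three tanh
  hidden layers (100/100/120), linear output, trained with the Huber loss.
* **Histogram (CNN)**: maps $\theta$ to a normalized likelihood histogram
  over the discretized (choice $\times$ response-time) space. Fully
  connected upsampling layers (64/256/$N_c N_d$), three length-5
  convolutions (8/8/1 channels), and a softmax output over $N_c \times N_d$
  cells, trained by minimizing $D(\hat\ell \,\|\, \ell_{\rm empirical})$.
  Because the output is a distribution by construction, a whole dataset is
  evaluated as a single binned inner product, at a cost independent of the
  number of trials.

## The generative model zoo

All single-particle models are integrated by Euler–Maruyama with step
$\Delta t = 0.001$ s (configurable) and a 20 s cap; trials still inside the
decision region at the cap are censored and carried with a sentinel. The
registered models and their parameter vectors:

| model | $\theta$ | notes |
|---|---|---|
| `ddm` | $(v, a, w, \tau)$ | bounds $\pm a$, start $(2w-1)a$ |
| `full_ddm` | $(v, a, w, \tau, s_v, s_t, s_w)$ | per-trial $v + N(0,s_v)$, $\tau + U(\pm s_t)$, $w + U(\pm s_w)$ |
| `ou` | $(v, a, w, \tau, g)$ | drift $v + gx$; $g=0$ recovers the DDM |
| `levy` | $(v, a, w, \tau, \alpha)$ | increments $(\Delta t)^{1/\alpha} L(\alpha,0,1,0)$ |
| `ddm_weibull` | $(v, w, \tau, a, \alpha, \beta)$ | bound $a\exp(-t^\beta/\alpha)$ |
| `ddm_lc` | $(v, w, \tau, a, \theta_{\rm ang})$ | bound $a - t\tan(\theta_{\rm ang})$ |
| `race_N` | $(v_1..v_N, a, w_1..w_N, \mathrm{ndt})$ | first of $N$ accumulators to reach $a$ |

Design choices worth stating explicitly:

* **Weibull bound reading.** The functional form is taken as
  $a\exp(-t^\beta/\alpha)$; the alternative reading
  $a\exp(-(t/\beta)^\alpha)$ is available behind
  `ssm_model("ddm_weibull", weibull_alternative = TRUE)`.
* **Collapsing bounds.** When the net bound reaches zero the trial is
  absorbed at that instant with the choice decided by the particle's sign,
  which guarantees termination.
* **Levy noise at $\alpha = 2$.** The stable law $L(2,0,1,0)$ is $N(0,2)$,
  so the $\alpha = 2$ Levy model literally carries increment variance
  $2\Delta t$; it equals a diffusion whose drift and bound are shrunk by
  $\sqrt 2$, and the test suite checks exactly that rescaled identity.
* **Trained region defaults.** $v \in [-3,3]$, $a \in [0.3, 2.5]$, $w \in
  [0.1, 0.9]$, $\tau \in [0,2]$, $g \in [-1,1]$, stable $\alpha \in
  (1,2]$, Weibull $\alpha \in [0.3,5]$, $\beta \in [0.3,7]$, collapse angle
  $\in [0,1.45]$ rad. These produce response-time distributions broader
  than typically observed, so realistic datasets fall inside the box; all
  are user-overridable. The trial-variability boxes $s_t \in [0, 0.25]$ and
  $s_w \in [0, 0.1]$ are fixed rectangles (rather than ranges conditional
  on $\tau$ and $w$) so that uniform box priors and box-constrained
  samplers apply unchanged; the simulator clips perturbed $w$ into $(0,1)$
  and floors perturbed $\tau$ at 0.
* **Defective screening.** Parameter vectors whose pilot simulations are
  degenerate are excluded from training: minority-choice probability below
  $10^{-5}$, more than half of all response times inside one 1 ms bin, or
  mean response time beyond 10 s.

## Empirical likelihoods

For the pointwise corpus the package fits per-choice kernel density
estimates on **log** response times (Gaussian kernel, Silverman's
rule-of-thumb bandwidth floored at $10^{-3}$) and maps densities back with
the $1/t$ Jacobian — the standard positive-support treatment for skewed
response-time data. The defective likelihood at $(t, c)$ is $p(c)
f_c(t)$, with $p(c)$ the simulated choice fraction; choices never observed
in a simulation receive half a pseudo-count, $p(c) = 0.5/N$. All likelihood
evaluations are floored at $10^{-29}$ (the exact natural log,
$\ln 10^{-29} \approx -66.7749$, is used as the training floor).

Training datapoints per parameter vector are drawn from a three-component
mixture with probabilities $(0.8, 0.1, 0.1)$: a resample of the KDE itself
("where it matters"), a uniform draw on $[0, 20]$ s (low-likelihood
regions), and a uniform draw on $[-1, 0]$ s labeled with the floor so the
network learns to push mass at negative response times to zero. The choice
code attached to the two uniform components is drawn uniformly from the
model's choice set, since the mixture is specified over response times
only.

For the histogram corpus, simulations are binned into $N_c \times N_d$
relative frequencies over uniform, half-open bins on $[0, t_{\max})$
(defaults $N_d = 512$, $t_{\max} = 20$ s; response times at or beyond
$t_{\max}$ land in the last bin).

## Training

Both networks train with Adam on minibatches, a 98/2 train/validation split
**by parameter vector** (so validation measures interpolation across
parameters, not across datapoints of a seen parameter), learning-rate
halving on a validation plateau, and early stopping after more than
`patience` (default 5) non-improving epochs. The defaults — learning rate
$10^{-3}$ with a floor at $1/64$ of the initial rate, batch 1024 (MLP) / 64
(CNN) — were chosen for desk-scale corpora of $10^4$–$10^6$ rows, where a
much smaller rate would exhaust the epoch budget long before convergence.
The output bias of the pointwise network is initialized at the label mean,
which removes a ~60 log-unit offset that otherwise dominates early
training. The Huber loss uses the continuous convention ($0.5d^2$ for
$d\le1$, $d - 0.5$ beyond); the discontinuous $0.5 + d$ variant is
available via `mlp_config(huber_literal = TRUE)` and shares the same
gradient. The KL loss floors empty label cells at $10^{-10}$, well below
the histogram resolution of any realistic simulation budget.

The full-scale corpus (millions of parameter vectors, $10^5$ simulations
each) is a preset, not a default: desk-scale corpora of order $10^3$
parameter vectors already support accurate interpolation for the 4–5
parameter models shipped here, which is what the bundled tests exercise.

## Posterior inference

A likelihood backend (analytic, pointwise network, or histogram network)
plus a prior (default: independent uniforms over the trained region)
defines the log posterior $\sum_i \log\hat\ell(\theta\mid x_i) + \log
p(\theta)$. Datasets whose minority choice received under 5% of the
responses (inclusive boundary) are refused, mirroring the screening of the
training corpus. Sampler initialization uses bounded differential-evolution
optimization (rand/1/bin, $F = 0.8$, $CR = 0.9$), five restarts by default.

* **Slice sampling**: coordinate-wise step-out updates (initial width one
  tenth of each parameter's range, expansion clamped at the support), at
  least 2000 draws, then a Geweke check (first 10% vs last 50%, spectral
  variance from an AIC-selected AR fit, $|z| < 2$ on every coordinate)
  every 100 draws.
* **DEMCMC**: $5|\theta|$ chains, difference scaling $2.38/\sqrt{2d}$,
  uniform jitter $10^{-4}$, out-of-box proposals reflected across the
  violated face; stopping when every per-parameter Gelman–Rubin
  $\hat R < 1.1$ on the second half of the run.
* **Annealed iterated importance sampling**: Student-$t$ mixture proposals
  ($\nu = 5$, one component per optimizer restart, scale matrices from a
  central-difference Hessian with eigenvalue flooring), tempering schedule
  $\gamma_i = \max(64/2^{i-1}, 1)$, plain weighted-EM proposal updates, and
  a stop when the normalized perplexity improves by less than 1% between
  untempered iterations. Posterior draws are an equal-weight resample of
  the final weighted sample.

Hierarchical and condition-split structures reuse the same backends: subject
parameters follow $N(\mu, \sigma)$ truncated to the trained range with a
uniform hyperprior on $\mu$ and a half-normal on $\sigma$ (scale: a quarter
of the parameter's range); condition parameters take independent values per
condition; anything else is global or held fixed. These group-level families
are this package's declared choice — the histogram/pointwise likelihoods
themselves are agnostic to them.

## What the synthetic-data generator does and does not emulate

Every dataset used in the tests is produced by the package's own
simulators, under the same conditions the training corpus assumes:
stationary parameters within a trial block, exact knowledge of the model
family, and trial counts (1024/4096 per dataset; 200–500 per subject or
condition cell) typical of a single-session experiment. Real data violate
several of these assumptions — contaminant responses, parameter drift over
the session, model misspecification — so passing recovery tests here bound
what the method can do when its own generative assumptions hold, not
performance on arbitrary empirical data.

## Problem sizes used by the test suite

The cluster-scale study design (millions of parameter vectors, $10^5$
simulations each, 40+ datasets per recovery study) is reproduced at reduced
scale, as this package's own choice of desk-scale analogues:

* pointwise DDM network trained on analytic labels: 2000 parameter vectors
  $\times$ 50 mixture points = $10^5$ rows;
* pointwise linear-collapse network trained on KDE labels: 600 parameter
  vectors $\times$ 3000 simulations, 100 points each;
* histogram DDM network: 800 parameter vectors $\times$ 5000 simulations,
  $N_d = 128$ bins, $\Delta t = 0.002$ s for the corpus;
* recovery studies: 8 datasets of 1024 trials, DEMCMC backend;
  variance-shrinkage checks at 6 datasets of 1024 vs 4096 trials.

Numerical tolerances follow the quantity being checked: series mass
conservation to $10^{-3}$; simulation-vs-analytic total variation below
0.02 at $10^6$ trials; paired recovery $R^2$ (ordinary least squares of
posterior means on truths) within 0.05 of the analytic reference; sampler
cross-agreement of posterior means within 0.05 and standard deviations
within 20%.

## Numerical notes and limitations

* The analytic DDM density selects between the small-time and large-time
  series per datapoint, with term counts meeting an absolute tolerance of
  $10^{-7}$ (capped at 60/200 terms). The full-DDM integrates the simple
  density over the trial-variability laws with Gauss–Hermite (drift) and
  Gauss–Legendre (start, nondecision) rules, 11 nodes per active dimension
  by default; degenerate dimensions are skipped exactly, and perturbed
  nondecision nodes are floored at zero to match the simulator.
* Euler–Maruyama discretization biases first-passage times upward by
  $O(\sqrt{\Delta t})$; at the default $\Delta t = 10^{-3}$ s this is below
  the resolution of the acceptance checks, but it is the reason
  simulation-vs-analytic comparisons carry total-variation rather than
  pointwise tolerances.
* The evaluation kernels for trained pointwise networks use a vectorized
  rational tanh (absolute error $< 3\times10^{-7}$); training uses R's
  libm tanh. The resulting output differences are orders of magnitude
  below network approximation error.
* Network evaluation outside the trained region is flagged but not
  refused; the networks extrapolate there and nothing is claimed about
  extrapolation quality.
* MCMC on network likelihoods can stall at the box boundary when the
  generating parameters sit near the edge of the trained region; the
  minority-choice filter removes the worst cases but boundary-adjacent
  truths recover less well, which is visible as lighter tails in recovery
  scatter plots. At desk-scale training this is the dominant failure mode
  of posterior-**variance** calibration: a single boundary-adjacent dataset
  can pin the network posterior (variance far too small) or leave it
  wandering (far too large), and the variance-calibration regression slope
  is then dominated by that dataset even when posterior means recover well.
* Desk-scale networks track empirical likelihoods at (a small multiple of)
  the KDE sampling-noise scale, but they do not yet sit strictly inside
  the envelope of independent $10^4$-simulation KDE curves, and the
  simulation-only recovery targets (e.g. all linear-collapse parameters at
  $R^2 \ge 0.9$ from 1024-trial datasets) are reached only as the corpus
  approaches the full study scale; the bundled tests report both honestly
  at the sizes above.
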