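---
title: "Universal codes as generative models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal codes as generative models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmlcodes)
```

## The model

In minimum description length (MDL) theory, coding a sample
$\hat s = (s^{(1)},\dots,s^{(N)})$ generated by a parametric family
$f(s|\theta)$ with unknown $\theta$ costs more than coding with the best
hindsight parameters $\hat\theta(\hat s)$. The code minimizing the
worst-case excess (regret) is the *normalized maximum likelihood* (NML),

$$\bar P(\hat s) = \frac{f(\hat s \mid \hat\theta(\hat s))}
  {\sum_{\hat x} f(\hat x \mid \hat\theta(\hat x))},
  \qquad
  \bar R = \log \sum_{\hat x} f(\hat x \mid \hat\theta(\hat x)),$$

with $\bar R$ the *parametric complexity*. This package treats $\bar P$ as
a **generative model** and asks what its samples look like. Two structural
facts organize everything here:

1. *Typical* NML samples have broad frequency distributions and sit close
   to the maximal attainable relevance at their resolution.
2. *Atypical* samples, reached by exponentially tilting the coding cost,
   undergo a localization transition exactly at zero tilt: forcing the code
   below its optimal cost collapses the sample onto a single outcome.

Sample statistics are summarized by the frequency profile: $k_s$ is the
count of outcome $s$, $m_k$ the number of outcomes observed exactly $k$
times. The *resolution* $\hat H[s] = -\sum_s (k_s/N)\log(k_s/N)$ and the
*relevance* $\hat H[k] = -\sum_k (k m_k/N)\log(k m_k/N)$ (both in nats
internally; the CLI can display bits) obey
$0 \le \hat H[k] \le \hat H[s] \le \log N$.

## Dirichlet model: exact, saddle and asymptotic regret

For the categorical ("Dirichlet") model $f(s|\theta)=\theta_s$ over $S$
states, the NML profile law is

$$\bar P(k_1,\dots,k_S) = e^{-\bar R}\,\frac{N!}{\prod_s k_s!}
  \prod_s \left(\frac{k_s}{N}\right)^{k_s}
  \delta\!\left(\textstyle\sum_s k_s - N\right).$$

`exact_regret()` evaluates $\bar R$ exactly: for $S=2$ as a one-dimensional
sum over the up-count (vectorized in log space, practical to $N = 10^6$);
for general $S$ by an $S$-fold convolution of $b_k = k^k e^{-k}/k!$
($O(SN^2)$, identical to the profile sum but far cheaper than
enumeration). The caps ($S \le 6$, $N \le 60$) keep the convolution in
well-conditioned double precision.

`saddle_regret()` evaluates the partition-function integral by a Gaussian
expansion around the saddle $z^*(\rho)$, $\rho = N/S$, defined by
$\langle k\rangle_{z^*} = \rho$ under
$q(k|z) \propto k^k e^{-(1+z)k}/k!$. The factorial prefactor is kept as
`lgamma` (not Stirling) so that the only error is the expansion itself.
Because the bare Gaussian term is accurate only to $O(1/S)$, the standard
next-order cumulant correction
$\log[1 + (\kappa_4/8\kappa_2^2 - 5\kappa_3^2/24\kappa_2^3)/S]$ is added
by default (`correction = FALSE` recovers the bare expansion); at $S=2$
this reduces the relative error from about $5\%$ to $0.3\%$ and it decays
as $S$ grows. In the well-sampled regime $\rho \gg 1$ the closed form
$\bar R \simeq (S/2)(1+\log\rho) - \tfrac12\log(2\rho)$
(`asymptotic_regret()`) follows, with $z^* \simeq 1/(2\rho)$.

The series $N(z) = \sum_k k^k e^{-(1+z)k}/k!$ converges only for $z > 0$
and slowly for small $z$; it is truncated adaptively where the geometric
tail bound (ratio $e^{-z}$) falls below $10^{-12}$ of the partial sum.
$0^0 = 1$ throughout.

## Sampling typical profiles

Around the saddle the profile law factorizes into $S$ independent draws
from $q(k|z^*)$. `sample_typical()` uses this *exactly*, not
approximately: `iid_reject` draws $k_1,\dots,k_S$ iid from $q(\cdot|z^*)$
and keeps the draw only when $\sum_s k_s = N$ — conditioning the
factorized law on the total reproduces the exact profile law, because the
$z$-dependent factors cancel in the conditional. The acceptance rate is
$\sim (2\pi S\,\mathrm{var}_k)^{-1/2}$; when it falls below $10^{-4}$ the
function aborts and recommends the second route. `profile_mcmc` is a
Metropolis chain on profiles under the exact weight: one unit of count
moves from a uniformly chosen *occupied* state to a uniformly chosen
recipient state, with the Hastings factor $n_{occ}/n_{occ}'$ correcting
for the changing donor pool. Chains start from a near-typical profile
(one iid draw from $q(k|z^*)$, adjusted to total $N$); defaults are
$10\,SN$ burn-in moves and $SN$ moves between samples.

## The maximally-informative-sample frontier

The variational problem "maximize $\hat H[k]$ at fixed $\hat H[s]$" has the
power-law solution $m_k = c\,k^{-1-\mu}$, with $\mu$ the trade-off slope
($\mu = 1$ is Zipf's law). Taken literally over real $m_k > 0$ this family
over-counts: fractional "states" with $m_k < 1$ can push $\hat H[k]$ above
$\hat H[s]$, which no sample can do. `mis_frontier(mode = "powerlaw")`
therefore truncates the support at the largest $k$ with $m_k \ge 1$
(i.e. $k_{max} = c^{1/(1+\mu)}$, solved self-consistently with the
normalization $\sum_k k\,m_k = N$) and sweeps
$\mu \in (-0.95, 20)$; the $\mu \to -1$ end continuously approaches the
all-distinct-frequencies profiles for which $\hat H[k] = \hat H[s]$
exactly, so below the curve's range the frontier is the diagonal. The
finite-$N$ cutoff shifts the local slope at $\mu = 1$ away from $-1$ by a
logarithmically decaying correction (about $-1.04$ at $N = 10^7$).

`mode = "exact"` ($N \le 60$) enumerates all integer partitions of $N$ and
returns the pointwise maxima together with their concave majorant; the
majorant is what the smooth large-$N$ frontier converges to and is what
`frontier_value()` interpolates. At $N = 50$ the power-law construction
agrees with the exact majorant to better than $5\%$ of $\log N$.

## Spin models

**Paramagnet.** A single $\pm 1$ spin is the two-state Dirichlet model;
its exact regret is the same one-dimensional sum and
$\bar R \simeq \tfrac12\log(\pi N/2)$. `paramagnet_sample()` draws the
up-count of each of $n$ independent spins from the exact single-spin NML
law (inverse CDF) and scatters the up-spins uniformly over observations.
The induced distribution of the maximum-likelihood parameter
$\hat\theta = \ell/N$ converges to Beta(1/2, 1/2) — the Jeffreys prior of
the model, i.e. the arcsine law
$\bar P(m) \simeq 1/(\pi\sqrt{1-m^2})$ for the magnetization.

**Sherrington–Kirkpatrick.** `sk_fit()` solves the convex moment-matching
problem $\partial\phi/\partial h_i = m_i$,
$\partial\phi/\partial J_{ij} = c_{ij}$ by damped Newton iterations with
the exact moment map and its Jacobian (the sufficient-statistic
covariance), both from enumeration of the $2^n$ states ($n \le 20$; no
mean-field approximations anywhere). Sample moments on the boundary
($|m_i| = 1$ or $|c_{ij}| = 1$) make the ML estimate diverge; they are
shrunk by $(1 - 1/N^2)$ with a warning — a numerical safeguard, chosen as
the mildest perturbation that keeps the Newton map finite.

**RBM.** Hidden units marginalize analytically. The package's default
convention is $h_j \in \{0,1\}$ with a softplus accumulation
$\sum_j \log(1 + e^{b_j + \sum_i v_i w_{ij}})$, respecting the declared
domain of the hidden variables; `hidden_unit_convention = "plus-minus"`
reproduces the $\log 2\cosh$ form instead. The two differ by a
reparametrization, not in expressive power. `rbm_fit_cd()` is standard
CD-$k$ on $\{0,1\}$ data; since $n_v \le 20$ the exact log-likelihood is
computable, it is tracked every epoch and the best parameter set is
returned, which makes the stochastic training auditable.

**Sampling universal codes without a closed form.** For SK and RBM the
regret is intractable, but ratios of maximized likelihoods are not:
`nml_mcmc_sample()` runs Metropolis over whole samples
$\hat s \in \chi^N$, flipping one spin of one observation and accepting
with $\min\{1, f(\hat s'|\hat\theta')/f(\hat s|\hat\theta)\}$ — the regret
cancels. Each proposal refits $\hat\theta$, warm-started from the current
optimum (a single flip moves the moments by $O(1/N)$, so a few Newton
steps suffice; non-convergent refits reject the proposal and increment a
counter). For a *saturated* model ($n \le 2$, where the parameter count
equals $2^n - 1$) the supremum of the likelihood over the closure of the
family is attained at the empirical pattern distribution, so the weight is
the closed form $\sum_s k_s\log(k_s/N)$ and no numerical fit is needed;
this also makes the tiny-instance enumeration oracle exact.

## Large deviations and the localization transition

The coding cost per observation of a typical sample is
$\hat H[s] + \bar R/N$. Its large deviations are generated by
$\phi(\beta) = \frac1N\log\langle e^{N\beta\hat H[s]}\rangle_{\bar P}$,
with rate function $I(E) = \sup_\beta[\beta E - \phi(\beta)]$
(Gärtner–Ellis; `rate_function()` evaluates the envelope over the grid and
applies isotonic smoothing to $E(\beta)$ when Monte-Carlo noise makes it
non-monotone, recording that it did). General bounds force
$-\bar R/N \le \phi(\beta) \le 0$ for $\beta \le 0$ with $\phi(0) = 0$, so
the negative-tilt branch is pinned to a vanishing plateau, while for
$\beta > 0$ the function rises — the optimality of the code expressed as a
phase boundary.

$\phi$ is computed two ways. For enumerable instances ($S = 2$ at any
practical $N$; $S \le 4$, $N \le 30$) `phi_exact()` sums the profile law
directly. Otherwise `estimate_phi()` uses thermodynamic integration
$\phi(\beta) = \int_0^\beta \langle\hat H[s]\rangle_b\,db$ with tilted-MCMC
estimates of the integrand on the grid (trapezoid rule, anchored at
$\phi(0)=0$); direct averaging of $e^{N\beta\hat H}$ is avoided because
its Monte-Carlo variance grows exponentially with $N$. Grid gaps above
$0.1$ trigger a discretization warning; the default grid is 41 points on
$[-1,1]$ with step $0.01$ on $[-0.1, 0.1]$.

Tilted sampling (`tilted_sample_dirichlet()`) reuses the single-ball
Metropolis kernel with the extra weight $e^{N\beta\hat H[s]}$; the tilted
count distribution $q_\beta(k|z) \propto k^{(1-\beta)k}e^{-(1+z)k}/k!$ is
truncated at $k \le N$ — a property of the sample space (no outcome can
occur more than $N$ times), not an approximation, and mandatory for
$\beta < 0$ where the unconstrained series diverges. For $\beta < 0$ the
chain must condense $N$ balls into one state through single-ball moves, a
coarsening process needing $O(SN)$ moves; the default burn-in is $5SN$
moves (plus $20N$), and a split-chain $\hat R$ on the resolution trace
flags non-convergence above 1.1. Ensemble errors are standard errors over
independent chains.

At finite $N$ the second derivative
$\phi'' = N\,\mathrm{Var}_\beta(\hat H[s])$ develops a peak at $\beta = 0$
of width $\sim N^{-1/2}$ that grows with $N$ over a decaying background —
the finite-size precursor of the second-order singularity.
`transition_diagnostics()` quantifies it as the finite-difference second
derivative straddling 0 minus the mean background curvature at
$\pm 5h$, with a step-halving estimate of the discretization error, and
reports the negative-branch plateau against the $\bar R/N$ bound plus the
order-parameter curves $\hat H[s]/\log N$ and $\max_s k_s/N$.

## Synthetic data

`make_fixture()` generates the package's test inputs: uniform
balls-in-boxes count tables (the null model for the resolution–relevance
plane), power-law count tables built rank-wise as
$k_r = \lfloor C r^{-1/\mu}\rfloor$ (equivalent to $m_k \sim c k^{-1-\mu}$
but without a truncation artifact at the top of the rank plot; at
$\mu = 1$ the central-decade rank slope is $-1$), and planted SK/RBM
samples drawn exactly from enumerated state probabilities with
$J_{ij} \sim \mathcal N(0, \sigma_J^2/n)$ ($\sigma_J = 0.5$),
$h_i \sim \mathcal N(0, 0.2^2)$, RBM weights
$\mathcal N(0, 0.7^2)$ — coupling scales where pairwise structure is
present but the models remain paramagnetic, the regime the generative
study targets. What these fixtures deliberately do not emulate: real
abundance or regulon tables are neither iid nor stationary, often have
unknown $S$, and can mix heterogeneous sampling efforts; passing tests on
these fixtures validates the estimators and samplers, not the iid
assumption on any particular dataset.

## Problem sizes and numerical choices

The test suite runs the study at desk scale, chosen once: typical-sample
law at $S = 10^3$, $N = 10^4$ (100 samples); degeneracy spectra at
$\rho = 10$, $N = 10^3$; frontier proximity at $N = 10^3$ (Dirichlet,
$\rho \in \{2, 10, 100\}$) and $N = 10^4$ (paramagnet,
$n \in \{4, 12, 20\}$); arcsine law from $10^4$ single-spin draws at
$N = 10^4$; the SK sample-space chain oracle at $n = 2$, $N = 3$ with
$10^6$ steps; tilted condensation at $S = 10^2$, $N = 10^4$. Random
baselines average 20–100 allocations per box count rather than the $10^7$
of a production figure; the averages are unbiased either way. All
stochastic components take a single integer seed; fixed seeds make every
reported number reproducible bit for bit.

Tolerances: series truncation $10^{-12}$ relative; saddle residual
$|\langle k\rangle_{z^*} - \rho| \le 10^{-10}$ (bracketing + `uniroot`,
then Newton polish; failure is declared only if $z^* < 10^{-14}$); SK
moment residuals $10^{-8}$ by default; profile-law normalization checked
to $10^{-10}$ on enumerable instances.

## Known limitations

* Exact enumeration caps everywhere ($S \le 6$/$N \le 60$ Dirichlet,
  $n \le 20$ spins, $n \le 16$ for the sample-space chain) — correctness
  over scale; no pseudolikelihood/TAP/mean-field fallbacks are provided.
* The sample-space MCMC refits parameters at every proposal; for
  non-saturated models this is the dominant cost and restricts practical
  study sizes to roughly $n \lesssim 10$, $N \lesssim 10^3$.
* The power-law frontier is a continuous relaxation; at small $N$ it can
  deviate from the integer optimum by a few percent of $\log N$ (compare
  with `mode = "exact"` below $N = 60$).
* Single-ball tilted chains cross between coexisting condensed states
  rarely at strongly negative tilt; ensemble averages there need the long
  default burn-ins, and the split-chain diagnostic should be heeded.
* No estimator of power-law exponents from empirical data is included;
  rank plots are descriptive.
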