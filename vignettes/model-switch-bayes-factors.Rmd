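---
title: "Direct Bayes factor estimation between phylogenetic models"
author: "pathstone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct Bayes factor estimation between phylogenetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bayesian model selection compares two models through the Bayes factor
$B_{10} = p(Y \mid M_1) / p(Y \mid M_0)$, a ratio of marginal likelihoods
$Z_i = \int f(Y \mid \theta, M_i)\,\Pi(\theta \mid M_i)\,d\theta$. For
parameter-rich models of sequence evolution these integrals are far beyond
quadrature, and the popular harmonic mean estimator (HME), which only needs
posterior samples, is severely biased upward for high-dimensional models: a
posterior sample essentially never visits the low-likelihood region, so the
estimator cannot see the dimensional penalty. `pathstone` implements the
family of *path-based* estimators that fix this, in their *model-switch*
form: instead of estimating each $Z_i$ separately along a prior-to-posterior
path and taking a ratio, a single path of power posteriors

$$q_\beta(\theta) =
  \left[f(y \mid \theta, M_0)\,\Pi(\theta \mid M_0)\right]^{1-\beta}
  \left[f(y \mid \theta, M_1)\,\Pi(\theta \mid M_1)\right]^{\beta},
  \qquad \beta \in [0, 1],$$

connects the two posteriors directly, and the log Bayes factor
$\log(c_1/c_0)$ is estimated from MCMC samples collected while $\beta$
traverses the grid. The direct path matters when the difference of the two
log marginal likelihoods is small compared to their magnitudes — exactly
the regime of substitution-model comparison — and, as the package's
variance analysis shows, it is also the lower-variance route.

## Estimators

With the potential
$U(\theta) = \log f(y\mid\theta,M_1) + \log\Pi(\theta\mid M_1) -
\log f(y\mid\theta,M_0) - \log\Pi(\theta\mid M_0)$, the identity
$\log Z_1 - \log Z_0 = \int_0^1 E_\beta[U]\, d\beta$ underlies path
sampling (thermodynamic integration): `ps_estimate()` applies the trapezoid
rule to the single $U$ value saved before each $\beta$ update,
$\hat\mu = \sum_k (\beta_{k+1}-\beta_k)\,\tfrac12(U_k + U_{k+1})$, and
`ps_mean_estimate()` replaces each $U_k$ by the mean of all samples
collected at $\beta_k$ (one every `save_interval` update cycles).

Stepping-stone sampling (`ss_log_bf()`) instead writes the ratio as a
telescoping product $c_1/c_0 = \prod_k c_{\beta_k}/c_{\beta_{k-1}}$ and
estimates each factor by importance sampling from the previous power
posterior,
$\hat r_k = \tfrac1n\sum_i \exp\{(\beta_k - \beta_{k-1})\,\ell_i\}$ with
$\ell_i$ the sampled log kernel ratios. Every step is computed after
factoring out the largest sampled term $\eta_k = \max_i \ell_i$, an exact
algebraic rearrangement that avoids overflow. On the natural scale
$\hat r = \prod_k \hat r_k$ is unbiased (a product of independent unbiased
factors); the log transform introduces a bias that shrinks as $K$ grows —
both facts are verified by the test suite on conjugate toys with
closed-form Bayes factors.

`hme()` and `shme()` (the delta-mixture stabilized variant, iterated to a
fixed point with `delta = 0.01`, tolerance $10^{-10}$, at most 1000
iterations) are provided as baselines; the package's own experiments show
their upward bias on the conjugate-normal toy.

### Error diagnostics

Three diagnostics accompany every run:

* **Discretization error** (`discretization_error()`): for a monotone
  $E_\beta[U]$, the worst-case quadrature error
  $\sigma_d = \left|\sum_k \tfrac12 (\beta_{k+1}-\beta_k)
  (E_{\beta_{k+1}}[U] - E_{\beta_k}[U])\right|$.
* **Sampling variance**: for the trapezoid estimator,
  $V = \tfrac14\bigl[\sum_k d_k^2 (V_k + V_{k+1}) +
  2\sum_{k=1}^{K-1} d_k d_{k-1} V_k\bigr]$, inflated by the decorrelation
  time $\tau = K/K_\mathrm{eff}$ when samples are serially correlated. The
  $\tfrac14$ multiplies both sums; re-deriving the expression from the
  variance of the trapezoid weights confirms this placement, and the
  worked $K = 2$, unit-variance value $0.375$ is pinned in the tests. For
  stepping-stone, the delta-method form
  $\widehat{\mathrm{Var}}(\log\hat r) \approx
  \sum_k \widehat{\mathrm{Var}}(\hat r_k)/\hat r_k^2$ is computed in log
  space.
* **Bidirectional error (BDE)**: the path is traversed both ways —
  *annealing* ($0 \to 1$) and *melting* ($1 \to 0$) — and the integral is
  split into subintervals ($[0,1] = \bigcup_i [\alpha_i, \alpha_{i+1}]$,
  20 by default in distributed runs). The BDE is the sum of absolute
  annealing-vs-melting differences of the per-interval contributions; the
  mean of the two directional estimates is the reported bidirectional
  estimate. Because $E_\beta[U]$ increases in $\beta$ (its derivative is
  $\mathrm{Var}_\beta(U) \ge 0$), a chain that lags behind the moving
  $\beta$ underestimates during annealing and overestimates during
  melting ("thermic lag"); the package flags that direction.

## Schedules

The grid matters as much as the estimator. `constant_schedule()` gives
$\beta_k = k/K$; `flexible_schedule()` gives piecewise-constant increments;
`sigmoid_schedule()` maps the step index through a rescaled logistic
$g(u) = 1/(1 + e^{-\alpha(2u-1)})$, normalized so $\beta_0 = 0$,
$\beta_K = 1$ and symmetric under $k \mapsto K-k$. Large $\alpha$
concentrates grid points near both endpoints, where one of the two models
is sampled essentially from its prior and the power posterior changes
fastest; shapes around $\alpha = 9$–$12$ work best in our runs, and
$\alpha \to 0$ recovers the constant grid. The sigmoid maps *step index to*
$\beta$ (the grid is exposed in `schedule$betas` for inspection). The
shape sweep is a runner (`run_cli("sweep", ...)`), not an optimizer.

## The two substitution models

Model 0 is the general time-reversible (GTR) model: 5 free
exchangeabilities (the sixth fixed at 1 as scale reference) and 3 free
base frequencies, the rate matrix scaled to one expected substitution per
site per unit time, likelihood by Felsenstein pruning with tip gaps as
missing data.

Model 1 is a first-order context-dependent model: $\psi(x \to z \mid wy)$
is the probability that base $x$ mutates to $z$ in one unit of time given
left/right neighbors $w, y$ — 16 contexts with 12 free probabilities each
(192 parameters; 96 under strand symmetry
$\psi(x \to z \mid wy) = \psi(x^c \to z^c \mid y^c w^c)$). The
no-substitution completion is $1 - \sum_{z \ne x}\psi$, and any factor
involving a gap is 1. Because site factors are coupled through neighbors,
the likelihood is evaluated against explicitly augmented ancestral
sequences, whose root row is scored by an inhomogeneous Markov chain of
order 0, 1 or 2. Per context the probabilities are calibrated so that one
change per base is expected per unit time:
$\sum_x \sum_{z \ne x} f_{wxy}\, \psi(x \to z \mid wy) = 1$ (the
$z \ne x$ range is the only reading that is not vacuous). The context
frequencies $f$ are *derived* from $\psi$ as the stationary distribution
of each context's substitution chain — that quantity is invariant to the
calibration scale, which both makes the normalization idempotent and keeps
the free-parameter count at exactly 192/96; an explicit $f$ can be
supplied for testing. Each context is normalized independently.

Priors: branch lengths i.i.d. Exponential with mean $\mu$;
$\mu \sim$ Inv-gamma(2.1, 1.1) (standard density
$\propto \mu^{-(\alpha+1)} e^{-\beta/\mu}$); flat Dirichlet on every
probability simplex ($\Gamma(4)$ on 4-simplices, $\Gamma(12)$ on each
context's $\psi$ block). The GTR exchangeabilities carry i.i.d.
Exponential(1) priors — a proper, weakly informative default chosen
because the model's prior specification covers only simplex blocks.

### The joint model-switch space

The two models' substitution blocks are disjoint; branch lengths and $\mu$
are shared; every block carries its own prior under *both* endpoint
kernels, so $q_0$ and $q_1$ are proper densities over the same space and
the extra blocks integrate to one, leaving the Bayes factor untouched. The
augmented ancestral sequences have no density under GTR (pruning
marginalizes internal states), so they are given a uniform reference
distribution ($1/4$ per non-gap site) under the GTR kernel — again a
factor that integrates to one. At $\beta = 0$ the context block and the
ancestral sites are sampled from their priors, at $\beta = 1$ the GTR
block is; this is intrinsic to model-switch paths and is why the sigmoid
schedule concentrates effort near the endpoints.

Further modeling choices the formulation leaves open:

* **Branch transitions for the context model.** $\psi$ is a per-unit-time
  probability; over a branch of length $t$ we use $t\,\psi$ per row with
  truncation (rescaling) if a row's substitution mass would exceed 1,
  keeping rows substochastic (`max_row_prob`, configurable). Branches are
  not partitioned into discrete time slices, and neighbors are held fixed
  at the parent across a branch.
* **Sequence boundaries.** The first and last site have no left/right
  neighbor; the missing neighbor is treated as a gap, so boundary sites
  contribute factor 1 — the same convention the gap rule forces
  elsewhere.
* **Ancestral gap pattern.** An internal node is a gap at a site exactly
  when all descendant tips are; gap sites are never resampled and
  propagate unchanged in simulation. `N` is read as a gap.
* **Root-chain boundary.** The first one or two positions lack full
  conditioning history; they use explicit lower-order initial
  distributions with their own flat Dirichlet priors, keeping the chain a
  proper distribution over sequences.

## MCMC

One update cycle touches every model parameter, every branch length and
every ancestral site: log-scale multiplier proposals for the
exchangeabilities, branch lengths and $\mu$ (with Jacobian), Dirichlet
perturbation proposals for every simplex block (concentration
`psi_conc`/`freq_conc`/`root_conc`, with a small floor so near-boundary
blocks remain reachable), and uniform single-site resampling of ancestral
states. Under strand symmetry, proposals act on one representative per
complementary-context orbit; the four self-paired contexts are proposed on
their 6-dimensional reduced simplex so the internal tie is exact. The
ancestral sweep updates sites in the three residue classes mod 3 in
parallel: two sites three apart never share a factor (each factor involves
positions $j-1, j, j+1$, and root-chain windows of order $\le 2$), so the
vectorized accept/reject decisions are exact Metropolis steps. Acceptance
for an ancestral site only involves the context kernel weighted by
$\beta$, so at $\beta = 0$ the ancestral sites correctly mix over their
uniform reference.

A traversal equilibrates `n_equil = 10 * Q` cycles at its starting
endpoint, then runs `Q` cycles per grid point, saving the last state
(classic path sampling) and, in `"mean"`/`"ss"` modes, one sample every
`save_interval` cycles (default 10), skipping the saves in the first
`save_interval` cycles after a $\beta$ switch when `Q` is large enough
(`Q > 2 * save_interval`) — for dense grids the previous power posterior
is an excellent importance distribution, so early samples are usable and
only a minimal burn-in is discarded. Identical seeds give bit-identical
traces.

## Toy models and what the tests do (and do not) show

Two conjugate toys with closed-form marginals anchor every estimator: the
beta-binomial (Beta prior on a binomial success probability; the default
acceptance toy, 1-dimensional and fast) and the conjugate normal (known
observation SD, normal prior on the mean; used for the HME bias
demonstration and the shared-prior variance comparison, where the two
models differ in likelihood dispersion). A `marginal_pair()` replaces
model 0 by the bare prior, turning the model-switch machinery into a
prior-to-posterior marginal-likelihood estimator — used for the
ratio-of-marginals comparison and for the thermic-lag experiment, whose
steep $E_\beta[U]$ profile makes the lag visible at `Q = 5`.

The sequence simulator inverts the two substitution models exactly as the
likelihood reads them (GTR via the transition matrix; context model via
per-branch probabilities with parent-fixed neighbors, the same
approximation the model itself makes). Simulated data therefore validate
the *estimators* and the *implementation*, not the model's adequacy for
real genomes: alignments are generated without among-site rate variation,
indel processes, selection or alignment error, and passing tests say
nothing about those. The GTR-vs-context experiment checks a sign: on data
simulated under GTR the context model's 96 extra parameters must be
penalized, so the stepping-stone log Bayes factor should be non-positive
on average.

## Problem sizes and numerical choices

The shipped experiments run at desk scale, chosen to finish in minutes on
one core: the beta-binomial oracle comparison uses $K = 50$, $Q = 200$,
$\alpha = 10$, ~100 samples per step; unbiasedness uses 500 one-step
replicates; the variance ordering 100 replicates at $K = 10$; the
GTR-vs-context experiment 5 taxa, 2000 sites, 10 replicates at $K = 30$,
$Q = 5$. At such small $K$ the stepping-stone estimate of the
phylogenetic comparison is strongly biased downward (adjacent power
posteriors are far apart and the log-scale bias is large) — the sign is
trustworthy, the magnitude is not; accurate magnitudes need $K$ in the
thousands, which is the method's documented cost on real data. All
products of ratios are accumulated in log space with $\eta$ factoring
always on; simplex blocks are validated to $10^{-12}$; degenerate inputs
(zero-width steps, constant series, all-gap columns, zero-mass contexts)
are handled explicitly and tested.

## Limitations

Fixed rooted topology only (no tree search); no among-site rate variation,
codon models, or second-order contexts; no generalized stepping-stone with
working priors (the natural next step for shortening the path); proposal
scales are fixed rather than adapted. Split intervals are run as
independent chains with their own equilibration — exactly what
distribution across nodes requires — so a split run spends more total
cycles than a single traversal of the same schedule.
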