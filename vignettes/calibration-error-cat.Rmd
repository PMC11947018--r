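---
title: "Accounting for item calibration error in adaptive testing: models, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for item calibration error in adaptive testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(calicat)
```

## The problem

Computerized adaptive testing (CAT) treats the item parameters estimated in a
calibration study as known constants, both when selecting the next item and
when estimating a test-taker's ability. With small calibration samples those
estimates carry substantial sampling error, and two things go wrong. First,
the reported standard errors of the final ability estimates are too small,
because a genuine source of uncertainty is ignored. Second — and more
damaging — maximum-information item selection *capitalizes* on calibration
error: the information function is quadratic in the discrimination parameter,
so items whose discrimination happens to be overestimated look more
informative than they are and get selected preferentially. The result is
conditional bias in the final ability estimates that is concentrated at the
extremes of the ability scale.

`calicat` implements, under the two-parameter logistic (2PL) model

$$P(u_{ij}=1 \mid \theta_j, a_i, b_i) =
  \frac{\exp(a_i(\theta_j - b_i))}{1 + \exp(a_i(\theta_j - b_i))},$$

three remedies and the Monte Carlo machinery to compare them against the
conventional procedure:

* **cWLE** — a measurement-error bias correction of Warm's weighted
  likelihood estimator (WLE);
* **cWLE + BMI** — the same estimator combined with a Bayesian version of
  the maximum-information selection criterion that averages Fisher
  information over normal pseudo-draws of item and ability parameters;
* **Bayes** — a fully Bayesian sequential engine that marginalizes
  item-parameter uncertainty over stored calibration draws and carries an
  empirical normal prior from one item to the next.

## Estimators

### WLE and the bias function

The WLE maximizes $L(\theta)\sqrt{I(\theta)}$, where
$I(\theta)=\sum_i a_i^2 P_i(1-P_i)$ is the test information of the items
administered so far. `wle()` solves the weighted score equation by
safeguarded root finding on $[-6, 6]$ (tolerance $10^{-6}$), falling back to
a grid-bracketed direct maximization when the score has no interior sign
change; all-correct and all-incorrect patterns therefore return finite
estimates.

When the administered items' parameters are estimates with biases
$(\delta_{a_i}, \delta_{b_i})$ and error covariances
$\Sigma_i = \begin{pmatrix}\sigma_{a_i}^2 & \sigma_{a_ib_i}\\
\sigma_{a_ib_i} & \sigma_{b_i}^2\end{pmatrix}$, the WLE acquires an
approximate bias $B(\theta) = [D(\theta) + J(\theta)]/I(\theta)$, where
$D$ collects the first-order bias terms and $J = J_1 + J_2 + J_3$ the
second-moment terms weighted by $\sigma_{a}^2+\delta_a^2$,
$\sigma_b^2+\delta_b^2$ and $\sigma_{ab}+\delta_a\delta_b$ respectively.
`bias_function()` implements these term by term; we validated it against a
direct Monte Carlo ensemble (items perturbed by errors with known covariance,
WLE bias measured over thousands of replications), which reproduces both the
sign and magnitude of $B(\theta)$ across the ability range. The corrected
estimator is $\hat\theta_{cWLE} = \hat\theta_{WLE} -
\hat B(\hat\theta_{WLE})$, applied once, with two safeguards:

* the correction magnitude is capped at 2.0 — early in a session the test
  information in the denominator is tiny and the raw correction can be
  arbitrarily large;
* the corrected estimate is clipped to the working range $[-6, 6]$.

Note a subtlety: because $J_2$ carries $\delta_b^2$, a *constant* difficulty
bias $c$ across items yields $B = c + O(c^2)$, not exactly $c$; the exact
constant shift holds only in the small-bias limit.

### The sequential Bayesian engine

After each response, the ability posterior is proportional to
$N(\theta;\hat\mu_{t-1},\hat\sigma^2_{t-1}) \cdot
S^{-1}\sum_s f(u_t \mid \theta, \xi^{(s)})$ — the item-parameter integral is
evaluated as an average over the $S$ stored calibration draws of that item.
The new draw set replaces the old one and is summarized into the next normal
prior with divisor-$S$ moments (a variance floor of $10^{-4}$ keeps the
carried prior proper). The start prior is $N(0, 1.5^2)$; we read the "1.5"
of the start prior as a standard deviation — a mildly diffuse start relative
to the $N(0,1)$ calibration metric — while acknowledging a variance reading
is also possible.

The default sampler evaluates the posterior on a deterministic 2001-point
grid over $[-6,6]$ and resamples $S$ draws by inverse-CDF with within-cell
interpolation. This targets the stated density exactly (up to grid
resolution), is fully reproducible, and makes a desk-scale study fast
because the draw-averaged response curves of the whole pool can be cached
once (`marginal_likelihood_grid()`). A random-walk Metropolis mode with a
split-$\hat R < 1.05$ gate is provided as well; both samplers are held to
the same quadrature oracles in the test suite.

**Accuracy of the normal carry.** Summarizing each posterior as a normal
discards skewness. Propagating the full density on the grid (exact carry)
reproduces the one-shot joint posterior to numerical precision; the
normal-summary engine tracks the exact carry with a mean absolute
posterior-mean deviation of a few hundredths at $|\theta| \le 2$ and
reference-scale draw counts ($S = 10{,}000$). Individual sessions with extreme
response strings (a testee failing nearly every item) can deviate by more
— 0.1 to 0.2 — because the discarded tail is exactly where the information
lives in those sessions. Two Monte Carlo effects add to this at smaller $S$:
each carried mean has standard error $\sigma_t/\sqrt S$, and these
accumulate over a session as a random walk (about 0.05 SD at $S = 2000$ for
a 20-item test).

### Item selection

`select_mi()` maximizes $a^2P(1-P)$ at the provisional point estimate.
`select_bmi()` maximizes the draw-averaged information
$S^{-1}\sum_s I_i(\theta^{(s)}; a_i^{(s)}, b_i^{(s)})$ with ability and
item draws paired by draw index. Exact criterion ties are broken uniformly
at random (deterministic first-index tie-breaking would bias item exposure);
the RNG is consumed only when a tie actually occurs, so tie-free sessions
are reproducible independent of the tie-break stream. For the cWLE + BMI
track the ability draws are refreshed after every response from
$N(\hat\theta_{cWLE}, 1/I(\hat\theta_{cWLE}))$ and the item pseudo-draws are
generated once per pool from independent normals around the point estimates
with SDs equal to the standard errors; discrimination draws below 0.01 are
resampled.

## Calibration

### Pool and linked design

The synthetic pool draws discriminations from a lognormal with log-mean 0
and log-SD 0.5 (we read "logN(0, 0.25)" as a log-variance, the common
parameterization, giving a central 95% range of roughly 0.4–2.7) and
difficulties from a standard normal. The calibration design randomly
partitions 300 items into 20 clusters of 15; form $f$ is the union of
clusters $f$ and $f+1$ with the last form wrapping around to cluster 1, so
there are exactly 20 forms and every item sits in exactly two of them. Each
form receives $n/2$ respondents with $\theta \sim N(0,1)$, giving every item
exactly $n$ responses.

### MML with bootstrap errors

`fit_2pl_mml()` is a Bock–Aitkin EM over all forms at once (structural
missingness ignorable), 61 quadrature nodes on $[-6,6]$, tolerance $10^{-4}$
on the maximum parameter change, at most 500 cycles. Three numerical
choices matter in the small-sample regime this package targets:

* **Bounded estimation.** Estimates are constrained to $a \in [0.05, 10]$,
  $b \in [-6, 6]$ (the working ability range). Without bounds, weakly
  identified items — hard items answered by a calibration sample centred at
  0 — excurse along the $a$–$b$ likelihood ridge, and their bootstrap
  standard errors blow up to several times the true sampling SD, which in
  turn destabilizes the cWLE correction. With the bounds, such items park at
  a bound and the bootstrap covariance stays close to the true sampling
  covariance (we checked against fresh-calibration replications).
* **Monotone M-steps.** The per-item M-step is Newton with box projection
  and step-halving guarded on the expected complete-data log-likelihood,
  with an exact constrained solve when a bound binds — a projected joint
  Newton step at a binding bound can otherwise *decrease* the likelihood
  and trap the EM in a limit cycle.
* **Acceleration.** Geometric EM tails are extrapolated (Aitken-type, every
  third cycle, reverted if the marginal likelihood drops), and items still
  crawling after that are finished by exact per-item conditional
  maximization. Typical full fits converge in 10–30 cycles.

Standard errors and per-item $(a, b)$ error covariances come from the
empirical cross-product approximation to the observed information, block
diagonal by item. For the cWLE tracks these are superseded by
`bootstrap_item_errors()`: respondents are resampled with replacement within
their form, the model refit (warm-started) per replication, and
$\hat\Sigma_i$ and $(\hat\delta_a, \hat\delta_b)$ estimated as the
replication covariance and mean-minus-full-fit deviation. The desk-scale
default is 200 replications; the replication count is a parameter.

### Hierarchical Bayes

`fit_2pl_bayes_hier()` targets the hierarchical 2PL in which
$(\log a_i, b_i)$ is bivariate normal with grand means
$\mu_a \sim N(0,1)$, $\mu_b \sim N(0,2)$ (we read the 2 as a variance),
scales $\tau_a, \tau_b \sim$ half-Cauchy(0,1) and an LKJ(4) prior on the
$2\times2$ correlation (density $\propto (1-\rho^2)^3$); abilities and the
implicit item z-scores are standard normal. The sampler is adaptive
random-walk Metropolis-within-Gibbs in the *centred* parameterization:
vectorized ability updates, per-item $(\log a, b)$ updates with per-item
proposal covariances learned during warmup, and hyperparameter sweeps whose
conditionals need no data pass. We chose the centred form because with 100
or more responses per item the data dominate the hierarchy and non-centred
z-score updates mix poorly (split-$\hat R \approx 1.2$ where the centred
sampler reaches $< 1.05$); the posterior is identical. Desk-scale default:
4 chains of 1250 iterations (half warmup) for small pools; the study runner
uses 2500 iterations for the 300-item pool. Split-$\hat R \geq 1.05$ for
any item parameter raises a warning naming the offenders.

## The study runner and its scale

`simulate_study()` reproduces the comparison end to end at desk scale. The
generating conditions are fixed: 300 items, the linked design above, 100
responses per item (the highest-error condition), 500 testees at each of
$\theta = -3$ and $+3$, responses always generated from the *true* item
parameters. Test length is a cell factor: the reproduction script runs the
three lengths 20, 30 and 40 and summarizes "most extreme case" reductions
as the maximum over ability levels and cells, which is how such headline
numbers are defined for a factorial simulation. A single run uses a single
calibration realization per condition — as the original design does — so the
cell-level bias values carry realization noise on top of the testee-level
Monte Carlo error; the reduction maxima inherit both. Two scale parameters were set once for a
single-CPU budget and are stated here as the package's choices: $S = 1000$
stored draws (the reference scale is 10,000) and 200 bootstrap replications
(reference 5000). The Monte Carlo error of the reported bias-reduction
percentages is dominated by the 500-testee design and the single calibration
realization per run, not by $S$ or the replication count.

One scientific observation from building this: the Bayes track's good
extreme-ability behaviour *depends on using the hierarchical posterior
draws*. The hierarchy shrinks poorly determined extreme difficulties toward
the centre, and at extreme abilities that shrinkage offsets the inward pull
of the start prior. Feeding the engine unshrunken joint-normal draws centred
at the MML estimates leaves an inward bias of about 0.3 at $|\theta| = 3$
and collapses the bias reduction. `simulate_study()` therefore defaults to
`bayes_draws = "hier_mcmc"`; the normal approximation remains available for
experimentation.

What the generator does *not* emulate: model misfit (every response follows
the 2PL exactly), respondent-level dependence, missingness other than the
structural design, item exposure control, and variable-length stopping.
Passing tests therefore demonstrate correctness of the procedures under the
model, not robustness to violations of it.

## Degenerate inputs and edge policies

* Items answered all-correct or all-incorrect by everyone who saw them are
  excluded from MML calibration (with a warning) and are an error for the
  Bayesian sampler; bootstrap replications that create such items are
  redrawn up to a retry cap.
* An exhausted item pool raises a typed condition
  (`calicat_pool_exhausted`).
* A zero test information makes $B(\theta)$ undefined and raises a typed
  condition rather than returning `Inf`.
* All randomness flows through explicit `seed` arguments applied locally
  (`withr`); nothing mutates the caller's RNG state, and per-session seeds
  in `run_condition()` derive deterministically from the master seed.

## Known limitations

* The cWLE correction is a first-order expansion; with the very large
  per-item error variances that arise at $n = 100$ for off-centre items it
  is noisy, and the cap at 2.0 is a blunt guard. This mirrors the method
  itself rather than the implementation.
* The normal-summary Bayesian carry deviates from the exact posterior in
  sessions with extreme response strings (see above).
* Fixed test length only; no exposure control or content constraints.
* The three-way ANOVA-style decomposition of the full factorial design is
  out of scope; `run_condition()` exports raw per-session tables so any
  statistics package can do that downstream.
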