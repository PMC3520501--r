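---
title: "Sequential stopping for high-throughput group comparisons"
author: "seqhts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential stopping for high-throughput group comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design problem

High-throughput group-comparison experiments (microarray, RNA-seq, RPPA)
accrue samples in batches, and the question after every batch is the same:
is it worth paying for one more? `seqhts` answers it decision-theoretically.
Experimentation earns one unit of reward per correctly reported
differentially expressed (DE) gene and pays a cost $c$ per batch, so the
utility of stopping after $t$ batches with decisions $d_1,\dots,d_n$ is

$$ u = \sum_i \delta_i d_i \; - \; c\,t, $$

where $\delta_i \in \{0,1\}$ is the unknown DE indicator of gene $i$.  The
cost $c$ has a direct elicitation: the minimum number of new true positives
that justifies one more batch.  Terminal decisions are not optimized
jointly; they follow a fixed rule that controls the posterior expected
false discovery rate (FDR), which keeps the reported gene list
interpretable to practitioners.

# Probability models

Posterior quantities must be recomputed inside millions of simulated
futures, so both models keep every per-gene computation closed form (or a
single deterministic 1-D quadrature) conditional on hyperparameters
$\omega$ that are estimated once and then fixed.

**Gamma–gamma (GaGa).**  $x_{ij} \sim Ga(\alpha_i,
\alpha_i/\lambda_{i z_j})$ (shape–rate, mean $\lambda$), with conjugate
hierarchy $\lambda \sim IGa(\alpha_0, \alpha_0/\nu)$ on each group mean and
$\alpha_i \sim Ga(\beta, \beta/\mu)$; $\omega = (\alpha_0, \nu, \beta, \mu,
\pi)$.  The gamma sampling distribution captures the asymmetry of raw
expression scales.  Given $\alpha_i$ the group means integrate analytically;
$\alpha_i$ itself is integrated by fixed-node Gauss–Legendre quadrature (64
nodes by default, configurable) on $\log\alpha$ over the prior's
$10^{-4}$–$(1-10^{-4})$ quantile range.  The node count is validated in the
test suite against much finer rules and against brute-force 2-D grid
quadrature.

**Log-normal–normal (NN).**  $\log x_{ij} \sim N(\mu_{i z_j}, \sigma_i^2)$
with $\sigma_i^2 \sim$ Scaled-Inv-$\chi^2(\nu_0, \sigma_0^2)$ and, by
default, the *generalized variance* mean prior $\mu_{ik} \mid \sigma_i^2
\sim N(\mu_0, \tau_0^2 \sigma_i^2)$; $\omega = (\mu_0, \tau_0, \nu_0,
\sigma_0, \pi)$.  This is fully conjugate, so EE and DE marginal
likelihoods are closed-form multivariate-t densities evaluated through
sufficient statistics — the workhorse for large simulations.  Whether the
mean prior should scale with the gene variance is genuinely open; the
variance-independent variant $\mu_{ik} \sim N(\mu_0, \tau_0^2)$ is
available behind `NNHyperParams(..., scaledMeans = FALSE)` and falls back
to 1-D quadrature over $\sigma^2$.

Each gene is DE with prior probability $\pi$; EE genes have their two group
means tied exactly.  The posterior DE probability is

$$ v_i = \frac{\pi\, m_{DE}(x_i)}{\pi\, m_{DE}(x_i) + (1-\pi)\,
m_{EE}(x_i)}, $$

computed in log space with log-sum-exp throughout.  NN marginals are
evaluated on the log-data scale; the Jacobian is common to both patterns
and cancels from $v_i$.

# Empirical-Bayes estimation

`fitHyperParams()` maximizes $\sum_i \log[\pi m_{DE} + (1-\pi) m_{EE}]$ by
EM with $\delta_i$ as missing data.  Details the model statement leaves
open were fixed as follows: the E-step uses the current $v_i$; $\pi$
updates in closed form as $\bar v$ (kept off the boundary at $10^{-6}$ for
stability); the remaining hyperparameters update by Nelder–Mead on a log
scale (60 inner iterations), accepted only when the expected complete-data
objective improves — a generalized EM step, so the marginal log-likelihood
is non-decreasing, which the tests assert on the recorded trace.
Convergence is declared at a relative log-likelihood change below $10^{-6}$
or 200 iterations.  Genes with non-finite values or zero variance across
all samples are rejected with their identities listed, and a minimum of 50
genes is required.

Moment-based initial values can overestimate $\pi$.  `adjustPi()` replaces
$\pi$ by the maximizer of the profile marginal likelihood in $\pi$ with all
other hyperparameters held fixed (a 1-D `optimize` on $[0,1]$ with both
endpoints checked).  Profile likelihood was chosen as the adjustment
because it needs no extra tuning constants and has a clean fixed-point
property: an already-adjusted $\pi$ is returned unchanged.

# Terminal decisions and the monitoring statistic

`bayesTerminalDecision()` sorts genes by $v_i$ and reports the largest
prefix whose running mean of $1 - v_i$ stays at or below the FDR level
(0.05 by default).  Ties in $v_i$ share a fate — a tied block enters only
whole, and only if the constraint still holds.  With nothing reportable the
posterior expected FDR is defined as 0, keeping the rule well-defined on
null-looking data.  The rule is verified against exhaustive search over all
$2^n$ decision vectors in the tests.

The sequential statistic is the one-step-ahead expected gain in true
positives,

$$ \Delta_t(TP) = E\left[ \textstyle\sum_i d_i' v_i' - \sum_i d_i v_i
\,\middle|\, x_{1:t} \right], $$

the expectation running over the posterior predictive of the next batch;
$\Delta_t U = \Delta_t(TP) - c$.  `deltaTPOneStep()` estimates it by Monte
Carlo: draw the next batch (composition sampling — $\delta_i \sim
Bern(v_i)$, gene parameters from their conditional posterior, then new
observations), recompute the terminal decision, average the increment.
With no data the posterior predictive *is* the prior predictive, and the
sampler reduces exactly to `sampleFromPrior()` on the same seed path.  For
the GaGa model the conditional posterior of $\alpha_i$ is drawn on the
quadrature grid (a discrete approximation; the conjugate draws of
$\lambda$ given $\alpha$ are exact).

# Stopping boundaries by forward simulation

Exact backward induction over all future data trajectories is
computationally prohibitive, so stopping is restricted to linear boundaries
on the statistic: continue while $\Delta_t(TP)$ lies strictly above $b_0 +
b_1 t$ (ties stop — conservative on cost), with two overrides at the
horizon: at $t = T-1$ the one-step-optimal myopic rule $\Delta_{T-1}U > 0$
replaces the boundary, and at $t = T$ stopping is forced.  Two special
cases anchor the family: $b = (c, 0)$ reproduces the myopic rule at every
step, and the sentinel $b_0 = -\infty$ never stops before the horizon —
fixed-sample designs.  Both equivalences are asserted exactly on shared
trajectory sets in the tests.  Note the sentinel retains the final myopic
check, so a "fixed" design still declines a provably worthless last batch.

`forwardSimulate()` draws $B$ complete futures $x_{t+1:T}$ from the
posterior predictive (gene parameters drawn once per trajectory, then
batches generated from them), recomputing the posterior summary after every
simulated batch.  Along a trajectory the recorded $\Delta_k(TP)$ is the
realized single-draw increment; trajectory-level noise averages out over
$B$ in the grid search, while live monitoring uses the inner-$m$ Monte
Carlo average where the statistic is a genuine expectation.
`optimizeBoundary()` evaluates the expected utility of every grid boundary
(defaults: $b_0 \in [0, 3c]$, $b_1 \in [-c, c]$, 21 steps each) on the
shared trajectory set and returns *all* boundaries within one Monte Carlo
standard error of the maximum — several are often statistically
indistinguishable — designating as representative the optimum with the
smallest expected stopping time, i.e. the cheapest among equals.
Re-running on accumulated data (recomputation) is supported by simply
calling the same functions again.

Randomness follows one root seed with deterministic substreams per
trajectory, replication and monitoring step, so results are reproducible
and independent of evaluation order, and paired design comparisons
(`compareDesigns()`) share every stream between arms.

# What the simulations emulate — and what they do not

`sampleFromPrior()` generates exactly the hierarchical truth the analysis
models assume, including misspecification scenarios where the generating
DE proportion differs from the analysis prior
(`scaledMicroarrayScenario(piScale = 0.5)` or `2`).  The default NN
settings (`defaultHyperParams("nn")`: $\mu_0 = 7$, $\tau_0 = 1$, $\nu_0 =
6$, $\sigma_0 = 0.6$, $\pi = 0.05$) mimic log-intensity microarray data
with gene-specific variances around $0.36$ and standardized effect sizes
$|\mu_{i1} - \mu_{i0}|/\sigma_i \sim |N(0, 2\tau_0^2)|$ — a mix of easily
detected and borderline genes.  The GaGa defaults put mean expression near
500 with moderate shape heterogeneity.

The scaled-down study scenario (`scaledMicroarrayScenario()`: 1000 genes,
analysis $\pi = 0.3$, $\tau_0 = 1.25$, $c = 50$, batches of 2 + 2 up to
$T = 10$ with one pilot batch) was calibrated once so that the expected
one-step gain starts *above* the per-batch cost and decays through it
within the horizon.  That is the regime in which sequential stopping is a
live decision; with a desk-scale gene count and the cost held at 50, a
rarer DE fraction would put the whole experiment below cost from the first
batch and every design would trivially stop immediately.  The eventual-
stopping check uses a deliberately saturating regime ($\tau_0 = 2.5$,
3 + 3 per batch, 30 future batches) in which the supply of discoverable
genes is exhausted within the horizon, making the asymptotic decay of
$\Delta_t(TP)$ visible at desk scale.

Because the generator and the analysis share the same parametric family,
passing simulations demonstrate internal coherence (calibration of $v_i$,
FDR control, adaptation of stopping times) — not robustness to the
misspecifications real data bring: correlated genes, batch effects,
heavy-tailed measurement error, normalization artifacts.
`posteriorPredictiveCheck()` compares quantiles of per-gene mean, spread
and skewness between data and model replicates for exactly that reason,
and the positivity `shiftTransform()` is the only pre-processing the
package performs; everything else (normalization, batch correction,
covariate adjustment by partial residuals) is assumed done upstream.

# Numerical choices and degenerate inputs

* Quadrature: Gauss–Legendre on the log scale of the integrated parameter,
  64 nodes, prior quantile range $[10^{-4}, 1-10^{-4}]$; non-finite results
  raise errors carrying the gene and grid range.
* All mixture arithmetic in log space; posterior odds clipped at
  $e^{700}$ to avoid overflow at $v_i \to 0$.
* $\pi = 0$ or $1$ short-circuit to $v \equiv 0$ or $1$ (no marginals
  evaluated), making degenerate-prior behavior exact.
* Constant genes are permitted in marginal evaluation (the conjugate
  algebra remains proper) but rejected by the fitter.
* Monitoring at $t = 0$ with no data uses $v_i = \pi$ for every gene.
* Stopping-time comparisons are deterministic given the trajectory set, so
  grid-search results are exactly reproducible and permutation-invariant.

Problem sizes used by the packaged checks — 5000 genes for EM recovery,
2000 genes and 250 replicates for FDR calibration, 1000 genes and 50
replicates per misspecification scenario, 60 trajectories over 30 batches
for the decay property — were chosen as the smallest sizes at which the
Monte Carlo error bands in those checks are decisively narrower than the
effects they measure.

# Limitations

Two groups only ($n_z > 2$ is an extension point, not implemented); no
MCMC and no covariate regression inside $\omega$; no effect-size-weighted
utility; boundaries are linear in $t$ and act on a single statistic; the
GaGa shape posterior draw is grid-discrete; and the exact dynamic-
programming solution the boundary family approximates is out of scope by
design.
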