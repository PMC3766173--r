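---
title: "Network-adjusted expression analysis with over-shrinkage ridge regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-adjusted expression analysis with over-shrinkage ridge regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osrr)
```

## The problem

Small expression experiments — ten case-control pairs, a couple dozen
time-course arrays — are the norm in clinical transcriptomics, yet each gene's
expression is embedded in a co-expression network of thousands of other genes.
That network is both a nuisance (it correlates the per-gene test statistics,
so "null" p-values are not uniform and type-I error is poorly controlled) and
an opportunity (most of a gene's variance is predictable from other genes, so
removing it sharpens the condition signal). Large public expression databases
measure the same transcriptome hundreds of times and can be used to learn the
network once, offline, and carry it into each new small study.

`osrr` implements that two-stage program:

1. **Network stage (database).** For each gene $g$, regress its (centered)
   log expression on all other genes of a large training matrix
   $Y_D$ ($G \times N_D$), with a ridge penalty and the gene itself excluded:
   $$ \hat\beta_g = \arg\min_\beta \|y_{Dg} - \beta Y_{D,-g}\|^2
      + \lambda \|\beta\|^2 . $$
   The rows $\hat\beta_g$ form a $G \times G$ coefficient matrix $B$ with zero
   diagonal — a global co-expression model $Y = BY + E$ in which each gene is
   a weighted sum of the rest.
2. **Rescaling stage (experiment).** In the new experiment $Y$, form the
   network prediction $\hat y_g = \hat\beta_g Y$ and estimate a single
   per-gene coefficient $\nu_g$ by least squares,
   $\hat\nu_g = \langle y_g, \hat y_g\rangle / \langle\hat y_g, \hat y_g\rangle$.

The penalty is chosen *much* larger than prediction-optimal — hence
*over-shrinkage*. Two properties motivate this. First, heavy ridge penalties
*equalize* the coefficients of correlated predictors, sharing predictive
weight across a co-expressed block instead of concentrating it arbitrarily in
one member, which makes the learned rows stable across data splits and
platforms. Second, the attendant bias of the fitted values toward zero is a
roughly common scale factor per gene, and the second-stage $\nu_g$ removes it.
When the trained network simply does not transfer to the new data, $\nu_g$
converges to zero and the adjustment gracefully disappears — the model never
forces a foreign network onto an experiment it does not fit.

The rescaled prediction then enters ordinary per-gene linear models as a
covariate:

* differential expression: $y_g = \nu_g \hat y_g + \delta_g x + \varepsilon$,
  testing $H_0: \delta_g = 0$ (with $x$ the 0/1 condition indicator) — the
  condition effect *conditional on the gene's network*;
* network disruption: adds $\gamma_g (\hat y_g \times x)$; $\gamma_g \neq 0$
  means the gene's dependence on its network differs between conditions;
* rhythm detection: $y_g = \nu_g \hat y_g + a_g\cos(T + b_g) + d +
  \varepsilon$ with $T$ the sample time in radians.

Because everything downstream of the network fit is a linear model with one
extra column, the method needs only one more degree of freedom than a t-test
and works at $N = 10$–$20$.

## Fitting the network: the dual form

The per-gene system is $(X^\top X + \lambda I)\beta = X^\top y$ with
$X = Y_{D,-g}^\top$, a $(G-1) \times (G-1)$ solve — prohibitive at
$G \sim 5000$ and wasteful since $N_D \ll G$. `fit_network()` instead solves
the equivalent dual system in sample space,
$\beta = X^\top (X X^\top + \lambda I)^{-1} y$, which is $N_D \times N_D$.
The dual Gram matrix for gene $g$ is the all-gene Gram
$S = Y_D^\top Y_D$ minus the rank-one self-contribution $y_g^\top y_g$, so a
single factorization of $S + \lambda I$ plus one Sherman–Morrison downdate
per gene fits the whole network in $O(G N_D^2 + G^2 N_D)$. The test suite
verifies the downdated solution against naive per-gene refits that physically
delete the gene, and against the primal closed form on small instances.

Self-exclusion matters: without it each gene would predict itself perfectly
and the network would be an identity in disguise. The diagonal of the
coefficient matrix is exactly zero by construction.

## Choosing the penalty

`select_lambda()` scores a candidate grid (default $10^2 \dots 10^6$) on a
single seeded half-split of the database samples:

* **(i) out-of-sample prediction** — per gene, the correlation between
  predictions trained on one half and observations in the other (both
  directions, averaged), summarized by the median across genes;
* **(ii) coefficient stability** — per gene, the correlation between the two
  half-fits' coefficient rows (self-entries excluded), averaged;
* **(iii) target prediction** — when the small experiment is supplied, the
  median per-gene correlation of full-database predictions with it.

The chosen penalty maximizes (i); (ii) and (iii) are reported for inspection
only, because using the experiment to tune the penalty would reuse the data
the hypotheses are tested on. Ties prefer the smaller penalty (less bias).
Median aggregation is the default — the across-gene correlation distribution
is long-tailed, with a noise floor of genes the network cannot predict — but
mean and max are selectable. Genes with zero variance in a half are skipped.
One random split, not K-fold, keeps the cost at two network fits per grid
point; the split seed is recorded in the report.

Because the second stage rescales per gene, the *scale* of the chosen penalty
matters far less than for prediction-optimal ridge: all three criteria are
correlation-based and invariant to per-gene scaling, which is why a sparse
grid of decades suffices.

## Inference details

**Intercepts.** Gene rows are centered (never variance-scaled — the
magnitude of log-scale variability is biologically meaningful and is assumed
to transfer across platforms), but the condition indicator is not, so each
per-gene model includes an intercept. This makes the naive reduction exact:
with the network term removed and no pairing, the $\delta_g$ test *is* the
pooled-variance two-sample t-test, reproduced in the tests to 1e−12.

**Paired designs.** Case-control pairs (e.g. patient and same-sex parent)
are modeled either with per-pair fixed intercepts or with a per-pair random
intercept fitted by REML via `lme4`. Wald t-tests under the random intercept
use residual degrees of freedom $N - (\text{fixed effects}) -
(\text{pairs})$; when the pair variance component is estimated at the zero
boundary the model is refit as plain OLS, whose inference is then exact.

**Degenerate predictors.** A constant network prediction (an isolated or
zero-variance gene) cannot carry a rescaling coefficient; such genes fall
back to the naive model and are flagged, so the results table always has one
row per gene. An interaction fit additionally requires the prediction to
vary within each condition group; otherwise the interaction column is
collinear and only flagged, never silently dropped.

**Invariance.** Rescaling any coefficient row by $c > 0$ multiplies
$\hat\nu_g$ by $1/c$ and leaves fitted values, $\hat\delta_g$ and its p-value
unchanged ($\hat\gamma_g$ rescales by $1/c$ with an unchanged test). This
exact invariance — verified to 1e−10 in the tests — is what makes the method
robust to the arbitrary overall shrinkage level of stage one.

**Cosinor test reference.** The sinusoid $a\cos(T+b)$ is linearized as
$\alpha\cos T - \beta\sin T$, so amplitude and phase come from a linear
model, with phase reported in $(-\pi, \pi]$. The time test is the Gaussian
likelihood-ratio statistic of $\alpha = \beta = 0$ (2 df). Its asymptotic
chi-square reference is noticeably anti-conservative at circadian sample
sizes: the analytic level of the 5% chi-square cutoff is 0.073 at $N = 24$
and 0.063 at $N = 38$. Since the model is linear-Gaussian, the statistic has
an exact monotone F transform, and the package uses that exact reference by
default (`test = "lrt"` restores the asymptotic one; the two order genes
identically). The period is fixed by supplying times in radians — no period
search. When a network prediction is present it is kept in the null model,
so the test isolates the time terms.

**Multiple testing.** Benjamini–Hochberg by default; Storey-style q-values
with $\hat\pi_0 = \min(1, \overline{I(p > 0.5)}/0.5)$ optionally.

## Calibration tools

**Beta-uniform mixture.** A p-value histogram is modeled as
$f(p) = \pi + (1-\pi)\, a\, p^{a-1}$ with $a \in (0,1)$: uniform for null
genes, a Beta$(a,1)$ spike near zero for signal. The ratio $\pi / f(p)$ is
an empirical-Bayes estimate of the false-positive rate at p-value $p$. The
family is not identified at the uniform boundary — as $a \to 1$ the beta
component is itself uniform and the weight arbitrary — so when the fitted
mixture fails a 2-df likelihood-ratio comparison against pure uniform, the
fit collapses to the canonical $\pi = 1$ solution. Optimization is by BFGS
on logit-transformed parameters with five fixed starts.

**Permutations.** `permutation_null()` re-assigns condition labels and
recomputes the full per-gene analysis, by default 100 times. In a paired
design the labels are swapped *within* pairs — the exchangeable relabelings
of a paired experiment; when $2^{\#\text{pairs}}$ does not exceed the
requested count all distinct relabelings are used exactly once, otherwise
distinct ones are sampled. Unpaired designs permute the label vector. A
fixed seed makes the result bit-identical; permutations are used for
histogram-level calibration, not per-gene adjusted p-values.

## The synthetic benchmarks

The generators are first-class, tested code; their defaults are the study
conditions under which the package's claims are verified.

`simulate_study1()` — the *equalization* benchmark: one outcome,
$N = 201$ samples, two independent compound-symmetric predictor blocks of
$G = 100$ (variance 1, $\rho = 0.9$), every member of a block carrying the
same true coefficient ($+1$ and $-1$), unit outcome noise. Ridge with
$\lambda = 10^4$ plus one rescaling coefficient recovers the within-block
mean coefficients at their generative values (the acceptance script
recomputes these as its two reported quantities), while the within-block
spread shrinks monotonically in $\lambda$.

`simulate_de_study()` — the *differential expression* benchmark: a database
of $G = 200$ genes by $N_D = 100$ samples with two compound-symmetric blocks
of 100 ($\rho = 0.8$, unit variance), and an experiment of $N = 20$ samples
(10 control, 10 treated) sharing that structure. Each gene is truly
differentially expressed with probability 0.2; affected genes have $\pm 1.0$
added to the treated samples, with an independent fair-coin sign. Setting
`expt_rho = 0` breaks the link between database and experiment — the
configuration used to verify that $\hat\nu$ centers at zero and the
adjusted test keeps its nominal size when the network cannot transfer.

Compound-symmetric draws use the closed-form factor construction
$\sqrt{\rho}\,f + \sqrt{1-\rho}\,e$ — exact, fast, and easy to test against
target moments. All generators take one master seed and are bit-reproducible.

What these generators deliberately do *not* emulate: heavy-tailed and
platform-specific noise, mean–variance dependence, scale-free network
topology, and probe-level artifacts. Passing benchmarks therefore demonstrate
the estimator's statistical mechanics — equalization, rescaling, calibration,
power gain from network adjustment — not performance on any particular array
or sequencing platform.

## Problem sizes and numerical choices

The shipped tests run the full pipeline (penalty selection over five decades,
network fit, prediction, both tests) on 20 replicates of the 200-gene
benchmark, 20 replicates of the 201-sample regression study, 4000
null gene-tests for size, 50-seed recovery checks for the interaction,
cosinor and mixture estimators, and byte-identity checks of seeded reruns —
a couple of minutes end to end. On this benchmark the selected penalty is
consistently $10^3$ and the network-adjusted test rejects more truly
affected genes at $p < 0.05$ than the t-test in essentially every replicate,
with uniform null p-values.

Numerical guards worth knowing about: ridge requires $\lambda > 0$ (the
dual downdate additionally requires the factor $1 - y_g^\top (S+\lambda
I)^{-1} y_g$ to stay positive, which holds for any $\lambda > 0$); exact-zero
p-values are clamped to the smallest positive double before BUM fitting; a
perfectly fit or perfectly constant series in the cosinor model short-circuits
to $p = 0$ / $p = 1$ rather than forming 0/0 ratios; and tie-breaks on the
penalty grid prefer the smallest candidate.

## Limitations

* One global penalty for all genes by design; per-gene penalties would cost
  a grid search per gene and destabilize exactly the small-sample setting
  the method targets.
* The network is a linear, undirected co-expression summary — coefficients
  are not causal edges, and no sparsity or topology is imposed or reported.
* Gene matching across platforms is exact string equality of identifiers
  (after whitespace trimming); no alias resolution. Duplicate spots and
  replicate arrays are averaged; missing values are rejected rather than
  imputed.
* A single database network is carried into the experiment; mixing several
  candidate networks in one model is not supported.
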