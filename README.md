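# osrr — over-shrinkage ridge regression for network-adjusted expression analysis

Small expression experiments (ten case-control pairs, a handful of
time-course arrays) test thousands of genes that are tangled in a shared
co-expression network. That dependence both inflates and correlates the
per-gene test statistics — null p-values stop being uniform — and it wastes
signal, because most of a gene's variance is predictable from other genes.
`osrr` learns the network once from a large public expression database and
carries it into each small study as a per-gene covariate, giving
network-adjusted tests of differential expression, of condition-dependent
network *disruption*, and of rhythmic (circadian) time dependence.

The estimator is two-stage. On the database \(Y_D\) (genes × samples,
log scale, centered per gene), each gene is ridge-regressed on all other
genes with one deliberately oversized penalty \(\lambda\):

\[ \hat\beta_g \;=\; \arg\min_\beta \;\|y_{Dg} - \beta\,Y_{D,-g}\|^2
   + \lambda\,\|\beta\|^2 , \]

giving a global coefficient matrix \(B\) (zero diagonal: genes never predict
themselves). Heavy penalization *equalizes* the weights of correlated genes,
which makes the rows stable across data splits and platforms at the price of
shrinking the fitted values toward zero. In the new experiment \(Y\) the
prediction \(\hat y_g = \hat\beta_g Y\) is therefore rescaled by a single
least-squares coefficient \(\hat\nu_g\) — the "over-shrinkage" correction —
which also vanishes when the trained network does not transfer, so a foreign
network can never hurt. The per-gene tests are then ordinary linear models:

\[ y_g = \nu_g\,\hat y_g + \delta_g\,x + \gamma_g\,(\hat y_g \times x)
   + \varepsilon , \]

with \(H_0\!: \delta_g = 0\) the network-adjusted differential-expression
test and \(H_0\!: \gamma_g = 0\) the network-disruption test; a cosinor
variant \(y_g = \nu_g \hat y_g + a_g\cos(T+b_g) + d + \varepsilon\) detects
rhythms. Ridge systems are solved in the \(N_D \times N_D\) dual form with a
rank-one self-exclusion downdate per gene, so a full network fit is two
matrix factorizations, not \(G\) of them. Beta-uniform mixture modelling of
p-value histograms, permutation null calibration, and seeded synthetic
benchmarks with ground truth round out the toolkit.

## Worked example

Simulate the package's differential-expression benchmark (database of 200
genes × 100 samples in two correlated blocks, experiment of 10 control + 10
treated samples, 20% of genes truly shifted by ±1), select the penalty,
fit the network, and compare the adjusted test with the plain t-test:

```r
library(osrr)

study <- simulate_de_study(seed = 42)
study
#> simulated_study: database 200 x 100, experiment 200 x 20 (10 treated), 46 true-DE genes

db     <- center_genes(study$database)
report <- select_lambda(db, grid = 10^(2:6), seed = 42)
report
#>  lambda  pred_cor coef_stability target_cor
#>   1e+02 0.8926360      0.2151540         NA
#>   1e+03 0.8934416      0.8843837         NA
#>   1e+04 0.8898865      0.9714680         NA
#>   1e+05 0.8877222      0.9753863         NA
#>   1e+06 0.8878501      0.9756982         NA
#> chosen lambda: 1000
```

Out-of-sample prediction (`pred_cor`) barely distinguishes the penalties —
the second-stage rescaling makes prediction nearly scale-free — while
coefficient stability (`coef_stability`) climbs steeply with \(\lambda\):
the equalization effect. The chosen penalty maximizes prediction; stability
is reported for inspection.

```r
net  <- fit_network(db, report$chosen)
expt <- center_genes(study$experiment)
pred <- predict_network(net, expt)

res_osrr  <- run_de_analysis(expt, pred, study$covariates)
res_naive <- run_de_analysis(expt, NULL, study$covariates)
head(res_osrr[, c("gene_id", "nu_hat", "delta_hat", "p_delta", "q_delta", "direction")], 3)
#>   gene_id    nu_hat   delta_hat   p_delta   q_delta direction
#> 1    g001 0.9910948 0.003646158 0.9881701 0.9881701        up
#> 2    g002 0.9209949 0.086719983 0.5921660 0.8167807        up
#> 3    g003 0.9214353 0.071619084 0.7135680 0.8919599        up
```

`nu_hat` near 1 says the database network transfers almost perfectly here
(by construction); `delta_hat` is the condition effect conditional on each
gene's network. Scoring both methods against the generator's ground truth:

```r
metrics <- evaluate_methods(list(osrr = res_osrr, naive = res_naive), study$truth)
subset(metrics, cutoff == 0.05)
#>   method cutoff     power      type1   ks_stat       ks_p
#> 1   osrr   0.05 1.0000000 0.06493506 0.0758789 0.33787769
#> 5  naive   0.05 0.7826087 0.02597403 0.1249301 0.01634278
```

The adjusted test finds every truly shifted gene at \(p < 0.05\) where the
t-test finds 78%, and its null p-values are compatible with uniformity
(KS \(p = 0.34\)) while the t-test's are not — the co-expression the t-test
ignores both costs it power and distorts its null. The p-value histogram's
beta-uniform decomposition gives an empirical-Bayes false-positive rate at
any cutoff:

```r
fit <- fit_bum(res_osrr$p_delta)
fit
#> bum_fit: uniform weight 0.503, beta shape 0.218 (loglik 160.76)
fpr_at(fit, 0.05)
#> [1] 0.3087944
```

The same pipeline runs from the shell on delimited files — see
`system.file("cli", "osrr.R", package = "osrr")`:

```sh
Rscript inst/cli/osrr.R simulate --study de --seed 1 --out sim/
Rscript inst/cli/osrr.R fit-network --db sim/database.tsv --lambda 1000 --out net/
Rscript inst/cli/osrr.R predict --network net/network.tsv --expt sim/experiment.tsv --out pred/
Rscript inst/cli/osrr.R diffex --expt sim/experiment.tsv --covariates sim/covariates.tsv \
    --prediction pred/prediction.tsv --out de/
```

Every output directory contains a `manifest.json`; reruns with the same seed
are byte-identical.

## Documentation

The methods vignette (`vignettes/osrr-methods.Rmd`) describes the model and
its assumptions, the penalty-selection criteria, inference details (paired
designs, degrees of freedom, degenerate predictors, test references), the
calibration tools, what the synthetic generators do and do not emulate, and
known limitations.
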