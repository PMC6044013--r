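# batchfx

Empirical Bayes batch-effect adjustment and moment-based batch diagnostics
for gene-by-sample matrices of log-scale expression values.

Expression data produced in several processing batches (different days,
labs, reagent lots, platforms) carry systematic non-biological signal that
confounds real group differences when batches are pooled. `batchfx` is for
analysts who need to combine such batches — and in particular for biomarker
work, where a signature trained on one batch must stay *frozen* while new
batches keep arriving.

## The model

Per gene *g*, batch *i*, sample *j*:

    Y_ijg = alpha_g + X_ij beta_g + gamma_ig + delta_ig * eps_ijg,
    eps_ijg ~ N(0, sigma_g^2)

with additive (`gamma`) and multiplicative (`delta`) batch effects on the
standardized scale `Z_ijg = (Y_ijg - alpha_g - X_ij beta_g)/sigma_g`.
Per-gene estimates of `(gamma, delta^2)` are shrunk across genes with
parametric empirical Bayes priors (normal for `gamma`, inverse-gamma for
`delta^2`, hyperparameters by method of moments) and removed. Three modes:

| mode | what it does | when |
|------|--------------|------|
| `original` | removes mean and variance effects against a pooled background | severe batch effects, comparable batches |
| `mean_only` | removes additive effects; within-batch variances pass through bit-exactly | diagnostics show mean differences only |
| `reference` | adjusts every batch to one designated batch's mean/variance profile; the reference batch is returned bit-identical | frozen biomarkers, sequentially arriving batches, one high-quality batch |

Moment diagnostics test mean, variance, skewness and excess kurtosis of `Z`
across batches, in a sample-wise view (moments over genes per sample) and a
gene-wise view (moments over samples per gene and batch), each with a
standard one-way F test and a robust variant that divides F by
`max(1, M/n0)` to keep huge numbers of gene-level estimates from driving
every p-value to zero. A built-in simulation suite reproduces a two-batch
pathway-signature study (k-means signature recovery) and a two-batch
differential-expression study (type-I error / power under three
batch-effect regimes).

See `vignettes/batch-adjustment-methods.Rmd` for the full model, the
estimation scheme, and the reasoning behind every tunable default.

## Worked example

```r
library(batchfx)

# two-batch pathway study: clean 200x6 perturbation experiment (batch 1)
# plus a noisy 200x600 patient-like cohort (batch 2)
study <- simulate_pathway_study(seed = 1)
study
#> simulated_study: 200 genes x 606 samples, batches: batch1 n=6, batch2 n=600 (seed 1)

diag <- batch_diagnostics(study$expression, study$design)
diag
#> Batch-effect diagnostics (adjustment: None)
#>   level   moment statistic    p_value statistic_robust p_value_robust
#>  sample     mean 5.250e-01  4.690e-01        8.664e-02      7.691e-01
#>  sample variance 5.919e+02  1.183e-91        9.767e+01      2.172e-16
#>  sample skewness 5.207e-01  4.708e-01        8.592e-02      7.701e-01
#>  sample kurtosis 8.711e-01  3.510e-01        1.437e-01      7.054e-01
#>    gene     mean 1.631e+01  6.466e-05        4.077e+00      4.621e-02
#>    gene variance 5.287e+06  0.000e+00        1.322e+06     3.458e-204
#>    gene skewness 1.052e+00  3.057e-01        2.629e-01      6.093e-01
#>    gene kurtosis 2.581e+03 4.547e-176        6.454e+02      6.559e-45
#> Recommendation (alpha = 0.05): mean/variance
```

The variance tests reject decisively in both views (the two batches differ
in spread by two orders of magnitude), so mean-only correction would be
insufficient here — the report recommends the full mean/variance
adjustment. With batch 1 as the frozen training set, reference mode is the
right tool:

```r
design <- study$design
design$reference_batch <- "batch1"
adj <- combat(study$expression, design, mode = "reference")
identical(adj$adjusted[, design$batch == "batch1"],
          study$expression[, design$batch == "batch1"])
#> [1] TRUE
```

The benchmark quantifies what each adjustment does to signature recovery
(k-means over genes, accuracy 0.5 = chance, 1.0 = perfect):

```r
run_pathway_benchmark(seed = 1)
#>   adjustment   subset accuracy
#> 1       none   batch1    1.000
#> 2   original   batch1    0.510
#> 3  reference   batch1    1.000
#> 4       none   batch2    0.555
#> 5   original   batch2    0.530
#> 6  reference   batch2    0.775
#> 7       none combined    0.555
#> 8   original combined    0.515
#> 9  reference combined    0.775
```

Reading the table: batch 1 alone separates its 100 signature genes
perfectly (1.000); pooling it with the noisy cohort destroys the separation
(0.555); original-mode adjustment inflates batch 1's variance toward the
cohort's and ruins the clean batch too (0.510); reference-mode adjustment
leaves batch 1 intact (1.000, structurally) and recovers much more of the
combined separation (0.775).

## Command line

```sh
CLI=$(Rscript -e 'cat(batchfx::batchfx_cli_path())')
Rscript $CLI diagnose --expression expr.tsv --metadata meta.tsv --batch-col batch --out-dir diag/
Rscript $CLI adjust   --expression expr.tsv --metadata meta.tsv --batch-col batch \
                      --mode reference --reference-batch train --out-dir out/
Rscript $CLI simulate --seed 1 --out-dir sim/
Rscript $CLI benchmark --seed 1 --out bench.tsv
```

Subcommands exit 0 on success and use distinct nonzero codes per error
family (input parsing, design problems, model fitting); logs go to stderr
as structured `timestamp level event` lines.

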