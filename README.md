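# radbench

Benchmarking gene-expression signatures of cellular radiosensitivity
against resampled-control and null models.

## The problem

Transcriptomic signatures are regularly proposed as predictors of how
sensitive tumour cells are to ionising radiation — their
*radiosensitivity* (RS), measured in vitro by the clonogenic assay and
summarised through the linear-quadratic survival model

    S(D) = exp(−αD − βD²)

as either **SF2** (surviving fraction at 2 Gy, a fraction in (0, 1]) or
**MID** (mean inactivation dose, ∫₀^∞ S(D) dD, in Gy). But raw accuracy
numbers are misleading: random gene sets predict many phenotypes
surprisingly well, because co-expression, proliferation and
tissue-of-origin structure pervade the transcriptome. `radbench` is for
researchers who want to know whether a candidate RS signature carries
information *beyond* that baseline. It evaluates each signature with
cross-validated mean absolute error (MAE) and out-of-sample R², compares
it against

- ensembles of **size-matched control signatures** resampled with
  replacement from all measured genes (median-accuracy control per
  size),
- an **intercept-only** null model (training-mean prediction), and

tests formal **equivalence** between candidate and matched control with
a paired two one-sided tests (TOST) procedure on per-cell-line absolute
errors (default bounds ±0.1, alpha 0.003 = 0.05/16), plus
tissue-stratified error analyses. A bundled synthetic radiogenomic
generator (latent-factor expression, linear-quadratic endpoints, tissue
heterogeneity, optional planted signal) makes the whole workflow
runnable and testable with no external downloads.

## A worked example

Simulate a 2000-gene × 120-cell-line panel whose endpoint carries a
planted 6-gene signal (70% of log-α variance), then benchmark the
planted signature against 50 size-matched resampled controls under one
shared 3-fold plan:

```r
library(radbench)

cfg <- synthetic_config(seed = 42,
                        effect_size = effect_size_for_r2(0.7, synthetic_config()))
d <- generate_dataset(cfg)

plan <- make_folds(d$rs$sample_id, 3, seed = child_seed(42, "folds"))
cand <- cross_validate(d$em, d$rs, d$planted, plan, family = "pcr")
cand
#> rs_benchmark: pcr of 'planted_seed42' (size 6) on 120 cell lines (3-fold CV, seed 74497685)
#>   MAE = 0.1252 [0.1094, 0.1410], out-of-sample R2 = 0.409

ens <- build_control_ensemble(d$em, d$rs, d$planted$size, plan,
                              n_draws = 50, seed = 42)
ens
#> control_ensemble: 50 resampled signatures of size 6
#>   MAE range [0.1351, 0.1786]; median signature MAE = 0.1616 [0.1419, 0.1812]

tost_paired(cand$samples$ae, ens$median_result$samples$ae,
            delta = 0.1 * sd(d$rs$value), alpha = 0.003)
#> Paired TOST: mean AE difference -0.0364 (n = 120), bounds +/- 0.0199251
#>   p_lower = 0.935, p_upper = 3.74e-07, p_tost = 0.935 (alpha = 0.003)
#>   90% CI [-0.0542, -0.0185]; not equivalent
```

Read: the planted signature's cross-validated MAE (0.125 SF2 units) is
well below the median control's (0.162), its out-of-sample R² is 0.41,
and TOST correctly *refuses* to declare it equivalent to a random
control — the mean paired AE difference (−0.036) lies decisively below
the lower equivalence bound. Re-running with `effect_size = 0` (the
null mode) produces a signature that is declared equivalent to its
controls and an R² near zero.

For file-based inputs (expression TSV, RS CSV, signature GMT) the same
workflow runs through `run_benchmark()` / `run_equivalence()` or the
command-line wrapper in `inst/scripts/radbench`, writing tidy CSV
tables and plots. See the vignette
(`vignettes/signature-benchmarking.Rmd`) for the model families, the
TOST conventions and the generator's design rationale.

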