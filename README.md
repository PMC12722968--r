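# pdfuzz

`pdfuzz` predicts Parkinson's disease (PD) risk from tabular dysphonia
(voice) features — jitter and shimmer perturbation measures,
noise-to-harmonics ratios, and nonlinear measures such as pitch period
entropy (PPE), spread1 and D2 — the kind of table produced by
sustained-vowel voice studies (one row per recording, a binary `status`
label: 0 = healthy, 1 = PD). It is aimed at biostatisticians and ML
practitioners who want the full method as composable, tested R functions
rather than a black box.

## The method

Four stages, each an exported function, orchestrated by `run_pipeline()`:

1. **Preprocessing** (`preprocess()`): per-feature mean $M$ and population
   SD $s$ over present records; z-scores $z = (x - M)/s$ (with $z = x - M$
   when $s = 0$); rows with excessive missingness dropped, remaining gaps
   mean-imputed, rows with any $|z| > 4$ removed as irrelevant; min-max
   scaling of the z-scores to $[0, 1]$. Statistics are fitted on the
   training partition and frozen for validation/test.
2. **DASR weighting** (`dasr_weights()`): per feature, the
   pooled-standard-error standardized class-mean difference
   $B_j = |m_1 - m_0| / \sqrt{v_0/n_0 + v_1/n_1}$, normalized to weights
   $W_j = B_j / \sum_k B_k$, plus a finest-feature score mixing $W_j$ with
   an assumed error rate.
3. **LDEFS selection** (`ldefs()`): label entropy $H(Y)$ and per-feature
   information gain under equal-frequency binning; gains standardized and
   passed through a logistic sigmoid; features scoring $\ge 0.85$ selected
   (top-4 fallback); the selected set ordered by mutual information with
   the label.
4. **Fuzzy neural network** (`mfnn()`): Gaussian fuzzification
   $\mu = \exp(-(x - c)^2 / 2\sigma^2)$, product-t-norm rule firing,
   linear rule consequents aggregated by normalized firing strength, a
   softmax class head; trained by full-batch momentum gradient descent
   ($\Delta_t = -\tau g_t + \alpha \Delta_{t-1}$, learning rate
   $\tau \in [0.4, 0.8]$, default 0.6) on cross-entropy with early
   stopping. Predicted PD probability is stratified into low / medium /
   high risk (`assign_risk()`).

Evaluation (`confusion_matrix()`, `classification_metrics()`,
`compare_models()`) reports precision, recall, F1, accuracy and the false
rate on the percentage scale, with explicit `NA` for undefined
denominators. A synthetic generator (`generate_pd_dataset()`) plants
informative features at a stated Cohen's d among correlated noise so every
stage is verifiable against ground truth without downloading any dataset.

## Worked example

```r
library(pdfuzz)

tab <- generate_pd_dataset(n_rows = 400, n_informative = 4, n_noise = 18,
                           effect_size = 3, seed = 1)
res <- run_pipeline(tab, seed = 1)
res
#> Parkinson's voice-feature pipeline run (seed 1)
#> Selected features: PPE, D2, spread1, MDVP:RAP
#> Held-out (n = 80): accuracy 100.0%, precision 100.0%, recall 100.0%, F1 100.0%, false rate 0.0%
res$risk
#> # A tibble: 3 × 2
#>   risk_class n_rows
#>   <ord>       <int>
#> 1 low            40
#> 2 medium          0
#> 3 high           40
```

400 synthetic recordings carry 4 planted informative features (Cohen's
d = 3) among 18 correlated noise features. The pipeline splits 60/20/20,
fits preprocessing on the 240 training rows, and the selector recovers
exactly the 4 planted dysphonia features (PPE, D2, spread1, MDVP:RAP).
On the 80 held-out recordings the fuzzy network classifies all of them
correctly and assigns every healthy speaker low risk and every PD
recording high risk — on this strongly separated synthetic signal the
classes are essentially non-overlapping, so perfect held-out metrics are
the expected outcome, not a typical clinical result.

The stage tables are ordinary tibbles: `tidy(res)` gives the per-feature
DASR weights joined with the LDEFS gains/scores, `glance(res)` the one-row
run summary, `autoplot(res)` the held-out confusion matrix, and
`autoplot(res$model)` the training curves. On the bundled 12-recording toy
table:

```r
make_worked_toy() |> preprocess() |> dasr_weights()
#> # A tibble: 4 × 4
#>   feature     b_a     w_g     f2
#>   <chr>     <dbl>   <dbl>  <dbl>
#> 1 PPE     11.8    0.501   0.482
#> 2 spread1 11.4    0.484   0.466
#> 3 NHR      0.261  0.0110  0.0228
#> 4 DFA      0.0950 0.00402 0.0163
```

The two planted features (PPE, spread1) absorb almost all of the
separation weight; the noise features (NHR, DFA) are near zero.

A thin command-line wrapper lives at `inst/scripts/pdpipe.R`
(`synth` and `run` subcommands over CSV in, JSON report out).

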