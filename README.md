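# methyldx

Tissue- and disease-specific CpG site screening, and Transformer-based
disease diagnosis, from DNA methylation beta-value matrices.

## The problem

DNA methylation at CpG sites is strongly tissue-specific in healthy people,
and age-related diseases (breast, kidney and lung cancer, Alzheimer's,
Parkinson's) disturb those patterns in the affected tissue. Given a
450K-style beta-value matrix (samples × CpG sites, values in [0,1]) with
per-sample tissue and health-status labels, `methyldx` answers two
questions: *which sites carry tissue- and disease-specific signal*, and
*how well do those sites diagnose the disease*.

The pipeline has three stages:

1. **Tissue screen.** On healthy samples only, each site's beta values are
   discretised into equal-width bins (default 10) and tested against tissue
   of origin with a Pearson chi-square contingency test,
   χ² = Σ (O − E)²/E; sites with p < τ_p (default 0.01) are kept.
2. **Disease ranking.** Per tissue, an L2-regularised logistic regression
   P(y=1|x) = 1/(1 + e^−(β₀ + xᵀβ)) of health status on the retained
   (standardised) sites is fitted; sites are ranked by |β_j| descending and
   the top K (default 400) form the diagnostic panel.
3. **Diagnosis model.** A Transformer encoder over the panel vector,
   followed by a sigmoid-gated *dynamic residual* layer
   T = H·W_fc + b_fc, G = σ(H·W_gate + b_gate), O = G⊙T + (1−G)⊙H,
   and a softmax classifier — implemented from scratch in R (analytic
   backprop, Adam, gradient-checked against finite differences), with an
   ablation switch (`use_dynamic_residual = FALSE`) for the plain baseline.

Evaluation is stratified k-fold cross-validation (accuracy, recall, F1,
pooled ROC/AUC) with classical baselines (logistic regression, SVM, random
forest, gradient-boosted trees, k-NN) run through the same folds. A
synthetic cohort generator with planted effects makes the whole pipeline
testable without any external data.

## Worked example

```r
library(methyldx)

# a six-tissue cohort: 50 healthy + 50 disease samples per tissue,
# 2000 sites, 200 planted tissue-specific, 20 disease-specific per tissue
co <- generate_cohort(cohort_config(seed = 1))
co$betas
#> methyl_matrix: 600 samples x 2000 CpG sites (0 missing values)

# stage 1: chi-square tissue screen on healthy samples
scr <- screen_tissue_specific(co$betas, co$metadata, tau_p = 0.01)
scr
#> tissue_screen: 2000 sites tested, 216 selected at p < 0.01 (10 bins)

# stage 2: ridge-logistic disease ranking within brain
rk <- rank_disease_sites(co$betas, co$metadata, "brain",
                         scr$selected_sites, top_k = 50)
rk
#> disease_ranking (brain): 216 candidates, top 50 selected (|coefficient| ranking)

# panel summary, printed the way disease-panel tables usually are
head(site_summary_table(co$betas, co$metadata, "brain",
                        rk$selected_sites[1:3]))
#>      site_id tissue       H_M       D_M magnification        H_SE        D_SE
#> 1 cg00000556  brain 0.7441571 0.9698661     1.3033083 0.008002010 0.003554391
#> 2 cg00000756  brain 0.9448224 0.7452712     0.7887951 0.003972236 0.008189345
#> 3 cg00000907  brain 0.6530449 0.8595995     1.3162946 0.008317587 0.007197338

# stage 3: train + cross-validate the diagnosis model on that panel
cv <- crossval_evaluate(co$betas, co$metadata, "brain", rk$selected_sites,
                        model_spec = list(name = "transformer",
                                          model = list(heads = 2),
                                          train = list(epochs = 40,
                                                       patience = 8)),
                        k = 5, seed = 1)
cv
#> cv_metrics: 5 folds | accuracy 1.000 | recall 1.000 | F1 1.000 | AUC 1.000
```

The screen keeps 216 of 2000 sites — all 200 planted tissue-specific sites
plus 16 false positives, consistent with the 1% level on 1800 null sites.
The ranking's per-site summaries show fold changes on both sides of 1
(hyper- and hypomethylated disease sites), and the model separates the
planted 0.2 mean shift perfectly — as it should on a cohort built to
contain exactly that signal. (`heads = 2` because the 50-site panel must be
divisible by the head count.)

An end-to-end driver (`run_pipeline()`, or the `inst/scripts/methyldx.R`
command-line wrapper with `simulate` / `screen-tissue` / `screen-disease` /
`summarize` / `train` / `predict` / `evaluate` / `run` subcommands) writes
every intermediate table, a run log, and a JSON manifest, reproducibly from
one root seed.

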