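# gdlnet — genome deep learning for variant-based cancer classification

`gdlnet` classifies samples by phenotype — a specific cancer type versus
healthy, any cancer versus healthy, or one of several cancer types — using
nothing but the presence or absence of point mutations. It is an R
implementation of the genome deep learning (GDL) approach for whole-exome
variant profiles, aimed at researchers who have per-sample VCFs and class
labels and want a reproducible, fully seeded pipeline from variant files
to evaluated classifier.

## The method in brief

1. **Mutation Collection.** Pool the cohort's point mutations, count for
   each site the number of distinct samples carrying it, and rank sites by
   that occurrence, high to low (ties broken by genomic order). Keep the
   top *k* sites (specific models; 10,000 at full scale) or every site
   with occurrence strictly greater than *m* = 2 (pooled cancer panels).
2. **Binary encoding.** Sample → vector `x ∈ {0,1}^d` with `x_j = 1` iff
   the sample carries the *j*-th panel site; labels are one-hot.
3. **Classifier.** Fully connected network, four ReLU hidden layers and a
   linear output into a softmax: `y = f(Σ_i w_i x_i + b)`,
   `f(x) = max(x, 0)`, `p_i = e^{y_i} / Σ_j e^{y_j}`. Loss is
   cross-entropy `H(p, y′) = −Σ_i y′_i log p_i` plus an L2 penalty
   `λ Σ w²` (biases excluded).
4. **Optimization.** Minibatch gradient descent with exponentially decayed
   learning rate `R = r·d^{g/s}` (optionally staircased), and a shadow
   copy of every parameter maintained as `S = d·S + (1−d)·V` after each
   step; inference always uses the shadow (sliding-average) parameters.
5. **Evaluation.** Threshold-rule accuracy/sensitivity/specificity,
   threshold-sweep ROC and trapezoidal AUC, predicted-by-true confusion
   matrix, top-N accuracy, shared-dimension analysis between panels, and
   mean ± sample-SD aggregation across model batteries.

A built-in simulator generates cohorts with the structure the method
assumes — per-class recurrent signature sites at high within-class
frequency over a long tail of low-frequency background sites, healthy
samples drawn from background only — so the entire pipeline is testable
without any external data.

## Worked example

```r
library(gdlnet)

# simulate a small cohort: two cancer-like classes plus healthy controls
cfg <- sim_config(classes = c("TUM_A", "TUM_B"), n_per_class = 60,
                  n_signature = 100, penetrance = 0.9,
                  n_background = 2000, bg_rate = 0.02,
                  signature_overlap = NULL, seed = 1)
sim <- simulate_cohort(cfg)

# specific model: TUM_A versus healthy, on the top-200 panel of TUM_A sites
labels <- vapply(sim$profiles, function(p) p$label, character(1))
exp <- gdl_experiment(sim$profiles[labels %in% c("TUM_A", "HEALTHY")],
                      mode = "specific", case_class = "TUM_A",
                      top_k = 200, seed = 1, hidden = c(32L, 16L, 8L, 4L),
                      config = gdl_config(max_steps = 300L, batch_size = 32L,
                                          seed = 1L))
exp
#> <gdl_experiment> mode 'specific': 96 train / 24 test, 200 site(s)
#> accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  (threshold 0.5)
#>   tp=12 fn=0 tn=12 fp=0
#>   AUC 1.0000

summary(exp$model)
#> Genome deep learning classifier
#>   input dimensions : 200
#>   hidden layers    : 32, 16, 8, 4
#>   classes          : TUM_A, HEALTHY
#>   parameters       : 7142
#>   steps trained    : 300
#>   final loss       : 0.0355 (batch CE 0.0295) at lr 0.09408

# the panel really is the planted signature: recovery of the 100 true sites
mean(sim$truth$signatures$TUM_A %in% exp$collection$sites[1:100])
#> [1] 1
```

Reading this output: the 24 held-out samples (12 cases, 12 controls) are
all classified correctly at threshold 0.5, the ROC is perfect, and the
top of the frequency-ranked panel contains every planted signature site —
the behaviour expected when within-class recurrence (penetrance 0.9)
stands far above the background rate (0.02). A warning notes that some
healthy samples encode to all-zero rows against the case-derived panel;
for controls that *is* the informative signal.

Real cohorts enter through `read_manifest()` / `load_cohort()` (a TSV of
`sample_id`, `path`, `label` pointing at one VCF per sample), then the
same `build_collection()` → `encode_cohort()`/`assemble_binary_task()` →
`split_dataset()` → `gdl_fit()` → `gdl_evaluate()` chain, or simply
`gdl_experiment()`.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/gdl.R simulate --out cohort/ --seed 7
Rscript inst/cli/gdl.R build-collection --manifest cohort/manifest.tsv \
    --class BLCA --top-k 1000 --out blca_panel.tsv
Rscript inst/cli/gdl.R train --manifest cohort/manifest.tsv --mode specific \
    --case BLCA --top-k 1000 --seed 7 --out run/
Rscript inst/cli/gdl.R evaluate --model run/model.rds \
    --manifest cohort/manifest.tsv --out eval/
```

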