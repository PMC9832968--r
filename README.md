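# prognet

Semi-supervised multimodal 5-year cancer prognosis classification with
Bayesian variational autoencoders, in R.

## The problem

Predicting whether a cancer patient will survive five years from a gene
expression panel and clinical covariates is hard for reasons that compound:
the binary label only exists for patients with an observed event before the
horizon or follow-up past it, so early-censored patients are unlabeled;
clinical tables have missing values; and labeled cohorts are small while
unlabeled ones are much larger. prognet is for computational researchers
who want a classifier that uses *all* of those patients — labeled,
unlabeled, and partially observed — without imputing anything.

## The model

Patients are partitioned by data completeness: Type I (expression +
complete clinical + label), Type II (no label), Type III (expression only),
Type IV (label, partially missing clinical). A class-conditional Gaussian
VAE models the expression modality: encoder q(z | x, y), decoder
p(x | y, z) with a direct label-to-gene-mean skip, and variational-dropout
Bayesian weights throughout. Two subnetwork classifiers — one reading the
VAE's learned gene-profile representation, one reading the masked clinical
vector with observedness flags — vote through a learnable shared output
layer: logit(ỹ) is the equal-weight mean of the available weighted logits
w_i · logit(ŷ_i), so prediction works with either modality alone or both.

Labeled patients contribute the supervised class-conditional evidence
lower bound plus α-weighted cross-entropies of all three votes; unlabeled
patients contribute the label-marginalized bound
U(x) = Σ_y q(y|·) L(x, y) − H(q(y|·)). Losses are dispatched by patient
type, every KL term is closed-form, and training (a compact reverse-mode
autodiff tape, Adam, supervised warmup of the unlabeled term) is
bit-reproducible under a seed. Evaluation covers AUROC, AUPRC, macro-F1,
accuracy and Harrell's concordance with percentile-bootstrap CIs, mean
bootstrap ROC/PRC curves on a fixed 100-point grid, and Kaplan–Meier /
log-rank stratification of predicted groups. Interpretation uses the
connection-weights algorithm and partial-dependence profiles. A synthetic
cohort generator with known ground truth (latent risk classes, censored
exponential survival, Type II/III/IV missingness) makes every stage
testable at desk scale.

## Worked example

```r
library(prognet)

cfg    <- synthetic_config(n_labeled = 600, n_unlabeled = 1200, seed = 7)
gen    <- generate_cohort(cfg)
cohort <- split_cohort(gen$cohort, c(train = 0.5, validation = 0.2, test = 0.3), seed = 8)
summarize_cohort(cohort)
#> Labeled splits:
#>       split   n good poor good_pct poor_pct imbalance_ratio median_survival
#>       train 300  146  154    48.67    51.33            1.05        57.04125
#>  validation 120   58   62    48.33    51.67            1.07        57.42398
#>        test 180   88   92    48.89    51.11            1.05        58.86599
#> Unlabeled pool by patient type:
#>  ptype    n pct
#>     II 1080  90
#>    III  120  10
#>     IV    0   0

tc  <- train_config(epochs = 120, batch_size = 4000, learning_rate = 0.01,
                    alpha = 3, hidden = 16, patience = Inf,
                    unlabeled_warmup = 48, seed = 9)
fit <- train_prognet(cohort, tc)

test <- which(cohort$split == "test")
pred <- predict(fit, cohort, rows = test)          # y1_hat, y2_hat, y_tilde, class
y    <- as.integer(cohort$label[test] == "poor")
bootstrap_report(pred$y_tilde, y,
                 cohort$survival$time_months[test],
                 cohort$survival$event[test], n = 1000, seed = 10)
#> Metrics with 95% percentile-bootstrap CIs (1000 replicates, 0 skipped):
#>   auroc               68.96% [ 61.49,  76.62]
#>   auprc               67.71% [ 58.27,  78.54]
#>   macro_f1            62.11% [ 54.30,  69.33]
#>   acc                 62.22% [ 54.44,  69.44]
#>   concordance_index   63.23% [ 58.52,  67.70]
```

The Bayes-optimal ceiling for this cohort — the true class posterior under
the generative model, scored against the noisy 5-year labels — is 76.98%
AUROC, so the trained model recovers most of the attainable signal from
300 labeled training patients. The predicted groups stratify survival
(log-rank chi-square 8.23, p = 0.004; median survival 47.0 months in the
predicted-poor group vs 85.2 in the predicted-good group), and the
connection-weights ranking puts a truly informative panel gene first:

```r
strat <- km_logrank(cohort$survival$time_months[test],
                    cohort$survival$event[test], pred$predicted_class)
cw <- connection_weights(fit$model, "microarray")
head(cw[order(-abs(cw$importance)), ], 3)
#>   feature   modality importance rank
#> 1 gene_01 microarray  0.6604182    1
#> 7 gene_07 microarray  0.3487612    2
#> 2 gene_02 microarray  0.2994495    3
```

Packaged experiments reproduce the method's qualitative claims on demand:
`ssl_gain_experiment()` (test AUROC grows with the unlabeled pool under
fixed labels), `ablation_experiment()` (full model ≥ no-unlabeled-losses ≥
no-VAE) and `ensemble_variance_experiment()` (logit-averaged seed ensembles
are an order of magnitude more stable than single models).

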