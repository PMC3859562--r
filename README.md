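# bpmsig

Construction, training and validation of the **BACH1 pathway metastasis
signature (BPMS)** — a seven-component gene-expression classifier that
flags breast tumours (triple-negative tumours in particular) at high risk
of distant metastasis.

## The problem and the model

The signature encodes the RKIP → let-7 → BACH1 signalling cascade:
suppression of the metastasis suppressor RKIP releases the let-7 axis and
activates BACH1, HMGA2 and the downstream effectors MMP1, CXCR4 and OPN.
Because let-7 (a microRNA) and BACH1 activity cannot be read from single
transcripts, both are represented by **meta-genes** — weighted averages of
12 let-7 target genes and 13 experimentally derived BACH1 target genes —
so the signature spans 30 distinct genes in 7 components.

On median-centered, gene-z-scored expression, each component *i* compares
its feature *xᵢ* with a threshold *τᵢ*:

    dᵢ(xᵢ) = 1[xᵢ < τᵢ]   for RKIP (active when suppressed)
    dᵢ(xᵢ) = 1[xᵢ > τᵢ]   for the six other components

    score  = Σᵢ dᵢ ∈ {0, …, 7};   BPMS-positive  ⇔  score = 7

Thresholds are trained, not set at medians: candidate vectors minimize the
frugal cost

    C(τ) = ⌈log₁₀ max(p, p_floor)⌉ − w · m/N

(*p* the log-rank p-value of the candidate positive cohort, *m/N* its
fraction) by many seeded Nelder–Mead restarts; solutions significant in
both a training and a cross-validation half are retained and averaged.
The package ships the published signature (`canonical_bpms()`: thresholds
−0.27 RKIP, −0.020 meta-let-7-TG, −0.15 meta-BACH1, −0.20 HMGA2, −0.23
MMP1, −0.19 CXCR4, 0.19 OPN) plus the full training machinery, survival
statistics (Kaplan–Meier, log-rank, Yates-corrected 2×2, Cox with
likelihood-ratio ANOVA), a random-signature Monte-Carlo null, a
frozen-reference single-sample predictor, and a synthetic-cohort
generator with a planted high-risk subpopulation so every stage is
testable without downloads.

## Worked example

Train thresholds on a synthetic cohort with a planted 5 % high-risk
subpopulation (hazard ratio 3), then classify and test the stratification
(in-sample, for illustration):

```r
library(bpmsig)

canon  <- canonical_bpms()
cohort <- generate_cohort(synthetic_config(n_samples = 600,
                                           hazard_ratio = 3, seed = 1))

trained <- train_signature(cohort$expression, cohort$survival,
                           canon$signature, canon$metagenes,
                           cost_config(), n_restarts = 100, split_seed = 1)
trained
#> <trained_signature> 33/100 solutions retained (p < 0.05 in train and CV)
#>         RKIP meta_let7_TG   meta_BACH1        HMGA2         MMP1        CXCR4
#>       0.1920       0.0056      -0.1692      -0.3514      -0.5521       0.2724
#>          OPN
#>      -0.1407

X        <- zscore_genes(cohort$expression)
features <- assemble_feature_matrix(X, canon$signature, canon$metagenes)
labels   <- classify(features, trained$thresholds, canon$signature)
table(labels$label)
#>   0   1
#> 580  20

S5 <- right_censor(cohort$survival, 60)      # 5-year convention
logrank_test(S5, setNames(labels$label, labels$sample_id))
#> Log-rank test: chi2 = 5.2185, df = 1, p = 0.02235

tidy(cox_fit(S5, data.frame(sample_id = labels$sample_id,
                            bpms = labels$label)))
#> # A tibble: 1 × 7
#>   term  estimate std.error hazard_ratio conf.low conf.high p.value
#> 1 bpms     0.663     0.296         1.94     1.09      3.47  0.0249
```

Of 100 restarts, 33 threshold solutions were significant in both halves;
their average classifies 20/600 samples BPMS-positive, and that minority
shows significantly worse metastasis-free survival (log-rank p = 0.022,
Cox hazard ratio 1.94, 95 % CI 1.09–3.47).

Results objects have `tidy()`/`glance()` methods and `autoplot()` figures
(`km_estimate()` curves, retained-threshold densities, arm-comparison
densities). A command-line wrapper with `simulate` / `train` / `apply` /
`validate` / `null` / `compare-random` subcommands is installed at
`system.file("cli", "bpms.R", package = "bpmsig")`.

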