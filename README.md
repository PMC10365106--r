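# dpanet

Deep phase attention (DPA) networks for predicting **early recurrence (ER)
of hepatocellular carcinoma** after surgical resection, from three-phase
contrast-enhanced CT tumor ROIs (non-contrast / arterial / portal-vein)
fused with routine clinical variables.

HCC recurs within a year of resection in roughly 40% of patients, and early
recurrence carries markedly worse survival. Two preoperative data sources
carry signal: the multi-phase CT appearance of the tumor and a small panel
of routine clinical variables. `dpanet` implements, end to end:

- **Clinical pipeline** — dichotomization of 17 routine variables at
  clinical cutoffs, Pearson chi-square screening against the outcome
  (no continuity correction, df = r − 1, selection at p < 0.05), and
  encoding of the seven retained variables (age, tumor size, portal vein
  invasion, N/L ratio, total bilirubin, AFP, BCLC stage) as a 9-element
  binary vector c₁…c₉, with BCLC coded (c₇,c₈,c₉) ∈
  {(0,0,0)=0, (0,0,1)=A, (0,1,0)=B, (1,0,0)=C}.
- **Image pathway** — three independent residual CNN branches (one per
  phase; depths 18/50 plus a desk-scale `"small"` variant), an
  **intra-phase attention** module per branch (squeeze-excite channel
  attention and CBAM-style 7×7 spatial attention in parallel, summed) and
  an **inter-phase attention** module that averages the three phases'
  channel vectors and spatial maps, applies the shared ones to each
  phase's map, and sums all six products into one fused map.
- **Fusion head** — global average pooling → FC to a 30-dim image feature
  S(I); FC lifting the clinical vector to a 30-dim feature T(c);
  concatenation and a final 2-neuron softmax layer
  p_k = exp(z_k)/Σ exp(z_k), z_k = W_kᵀ[S(I) ⊕ T(c)] + b_k.
- **Joint loss** — L = ¼·L_image + ¼·L_clinical + ½·L_combine, each term a
  two-class cross-entropy (auxiliary softmax heads on both pathways), with
  a combined-only mode for the ablation.
- **Evaluation** — patient-stratified 10-fold cross-validation (with
  65 ER/102 NER and k = 10: 6–7 ER and 10–11 NER per fold), central-slice
  selection (largest tumor cross-section ± 2 neighbours), rank-statistic
  AUC and accuracy as mean ± sd over folds.
- **Synthetic cohort generator** — a seeded simulator of the study's
  statistical structure (38.9% ER prevalence, 3–7 slices/patient,
  class-conditional clinical frequencies from the published contingency
  tables, class-dependent arterial rim enhancement / portal-vein washout /
  boundary irregularity), so the entire pipeline is testable without
  access to protected patient data.

The convolution/pooling/batch-norm primitives are implemented in C++
(RcppArmadillo) with hand-derived backward passes, finite-difference
checked in the test suite.

## Worked example

```r
library(dpanet)

## 1. Chi-square screening on the published cohort's contingency counts
ref <- hcc_reference_counts()
pearson_chi_square(ref$age)
#> $statistic
#> [1] 5.645427
#> $df
#> [1] 1
#> $p_value
#> [1] 0.01750095          # prints as 0.018

## 2. Synthetic study: generate, then cross-validate the fusion model
coh <- generate_cohort(cohort_spec(n_patients = 200, seed = 101))
print(coh)
#> Synthetic cohort: 200 patients (88 ER / 112 NER, 44% ER), 999 slices

fit <- cross_validate(coh, k = 10, seed = 101, variant = "fusion",
                      loss_mode = "joint", epochs = 10)
print(fit)
#> 10-fold CV (fusion, joint loss, slice-level): accuracy 77.4% +/- 5.9, AUC 0.816 +/- 0.07
```

The per-fold table (`fit$per_fold`) carries accuracy, AUC and the exact
seed of each fold's model, so any fold can be replayed. The AUC is the
probability that a randomly chosen ER slice outscores a randomly chosen
NER slice; ~0.82 on this synthetic cohort means the model recovers most of
the planted arterial/portal-vein/clinical class structure (for reference,
the clinical vector's Bayes AUC alone is 0.83, and the image-only ablation
on the same seed reaches 0.787). These numbers describe the synthetic
generator only — the published cohort is private and its headline metrics
are not reproduction targets.

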