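# emat

Metastasis-risk stratification of breast cancer expression cohorts with an
epithelial–mesenchymal–amoeboid transition (EMAT) gene signature.

Cancer cells metastasize through distinct motility programs: the
epithelial-to-mesenchymal transition (EMT) and, under microenvironmental or
xenobiotic stress, the mesenchymal-to-amoeboid transition (MAT). Signatures
built on EMT alone have repeatedly failed to stratify breast cancer
prognosis; considering both programs jointly is what makes the stratification
prognostic. This package implements that analysis as a reusable, tested
pipeline for lymph node-negative (LNN) cohorts — the patients whose metastasis
risk is most often underestimated:

1. **Signature derivation** — a gene enters a motility signature when it is
   up- or downregulated at least *f*-fold (ratio ≥ *f* or ≤ 1/*f*) in at
   least *k* independent perturbation experiments (defaults *f* = 1.5,
   *k* = 2); EMT and MAT lists are merged into the combined EMAT signature.
2. **Subtype discovery** — Ward variance-minimization clustering of samples
   over z-scored signature genes; the cluster number is chosen by average
   silhouette under cosine, Euclidean and correlation distances; clusters are
   named EMAT1..EMATK in decreasing order of Kaplan–Meier survival at 10
   years.
3. **Single-sample classification** — a nearest-centroid classifier using
   Spearman rank correlation, so cross-platform monotone intensity
   distortions cannot change a sample's label; a k-NN variant is included.
4. **Survival statistics** — Kaplan–Meier, log-rank (global and pairwise),
   Cox proportional hazards with Efron ties and single-ordinal subtype
   encodings (EMAT1..4 → 1..4, PAM50 → 0..4, joint ER/HER2 status → 1..4),
   and Harrell's concordance index (C-index).
5. **Cross-validation benchmark** — repeated random half/half splits; the
   training half is re-clustered, outcome-named and transferred to the test
   half by centroid classification; Cox models per feature set are compared
   by paired test-half C-index, summarized as PIF (percentage of improved
   folds, strict wins) and a one-sided Wilcoxon signed-rank p (exact for
   ≤ 20 informative pairs).
6. **Cluster characterization** — hypergeometric enrichment against clinical
   categories, min–max-scaled Spearman similarity to a stem-cell reference
   profile, marker profiles (CDH1, VIM, RHOA, JUP), per-gene univariable Cox
   association, Bonferroni-corrected cluster-vs-rest t-tests for
   transcription factors, and Jaccard concordance between clusterings.
7. **Synthetic cohorts** — a generator planting K expression clusters with
   tunable separation, clinical covariates optionally confounded with the
   clusters, proportional-hazards survival with cluster-dependent hazard
   ratios and analytically tuned independent censoring, so every stage of
   the pipeline is testable without patient data.

Patient-level datasets are deliberately out of scope: callers supply
gene-symbol-keyed expression matrices (TSV), clinical tables and survival
tables, or use the synthetic generator. Small synthetic stand-ins for the
published gene lists (253 EMT genes, 138 MAT genes, 3 shared, 388-member
union) ship under `inst/extdata/` — they preserve the published counts and
marker genes but are not the original lists.

## Worked example

```r
library(emat)

set.seed(1)
cohort <- generate_cohort(cohort_spec(n_samples = 400), seed = 1)
res <- run_full_pipeline(
  cohort$expression, cohort$signature,
  surv = cohort$survival, clinical = cohort$clinical,
  covariates = cohort$covariates, seed = 1)
res
#> emat pipeline run
#>   chosen K: 4
#>   cluster sizes:
#>
#> EMAT1 EMAT2 EMAT3 EMAT4
#>    72   193   100    35
#>   log-rank p across clusters: 2.29e-07
res$cox_univariable
#> Cox model: n = 400, events = 287, LRT p = 5.44e-08
#>  term  coef   hr hr_lo hr_hi        p
#>  emat 0.399 1.49  1.29  1.72 3.48e-08
```

The pipeline z-normalizes the expression, selects K = 4 by average
silhouette, names the clusters by 10-year survival (EMAT1 best, EMAT4
worst), and the ordinal EMAT covariate carries a hazard ratio of 1.49 per
step — the planted cluster-dependent hazards recovered from expression
alone. `run_cv_comparison()` then quantifies how much the re-derived EMAT
labels add to clinical parameters on held-out halves:

```r
cv <- run_cv_comparison(
  subset_to_signature(z_normalize(cohort$expression), cohort$signature),
  cohort$covariates, cohort$survival,
  list(feature_set("CP", c("age", "size", "grade")),
       feature_set("CP+EMAT", c("age", "size", "grade"),
                   includes_emat = TRUE)),
  n_repeats = 50, K = 4, seed = 1)
cv$comparisons
#>   candidate baseline pif p_signed_rank
#> 1   CP+EMAT       CP  96   7.12607e-10
```

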