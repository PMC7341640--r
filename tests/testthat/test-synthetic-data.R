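test_that("perturbation simulator plants a recoverable signature", {
  # noiseless background: derivation recovers exactly the planted set
  sim0 <- simulate_perturbation_experiments(n_genes = 300, planted = 40,
                                            noise_sd = 0, seed = 61)
  sig0 <- derive_signature(sim0$folds, 1.5, 2)
  expect_setequal(sig0$gene, sim0$truth)
  expect_true(all(sig0$direction[match(sim0$truth, sig0$gene)] ==
                    sim0$directions[sig0$gene]))

  # determinism: same seed, identical table
  a <- simulate_perturbation_experiments(seed = 62)
  b <- simulate_perturbation_experiments(seed = 62)
  expect_identical(unclass(a$folds), unclass(b$folds))

  # moderate noise: F1 of recovery stays high across seeds
  f1s <- vapply(1:20, function(s) {
    sim <- simulate_perturbation_experiments(n_genes = 500, planted = 60,
                                             noise_sd = 0.2, seed = s)
    called <- derive_signature(sim$folds, 1.5, 2)$gene
    tp <- length(intersect(called, sim$truth))
    prec <- tp / max(length(called), 1)
    rec <- tp / length(sim$truth)
    2 * prec * rec / max(prec + rec, 1e-12)
  }, numeric(1))
  expect_gte(mean(f1s), 0.9)

  expect_error(simulate_perturbation_experiments(fold_range = c(0.5, 2)),
               "above 1")
})

test_that("cohort generator respects its spec invariants", {
  expect_error(cohort_spec(mixing = c(0.5, 0.5, 0.5), K = 4), "sum to 1")
  expect_error(cohort_spec(hazard_ratios = c(1, -1, 1, 1)), "positive")
  expect_error(cohort_spec(censoring_rate = 1), "censoring_rate")
  expect_error(cohort_spec(n_samples = 2, K = 4), "exceeds")

  spec <- cohort_spec(n_samples = 100, n_genes = 200, signature_size = 50)
  c1 <- generate_cohort(spec, seed = 63)
  c2 <- generate_cohort(spec, seed = 63)
  expect_identical(unclass(c1$expression), unclass(c2$expression))
  expect_identical(c1$survival$time, c2$survival$time)
  expect_equal(ncol(c1$expression), 100L)
  expect_equal(nrow(c1$expression), 200L)
  expect_equal(length(c1$labels), 100L)
  expect_equal(nrow(c1$signature), 50L)
})

test_that("zero separation produces structureless expression", {
  cc <- generate_cohort(cohort_spec(n_samples = 400, n_genes = 300,
                                    signature_size = 100, separation = 0,
                                    mixing = rep(0.25, 4)), seed = 64)
  m <- subset_to_signature(z_normalize(cc$expression), cc$signature)
  labels <- ward_cluster(m, 4)$labels
  expect_lt(abs(mclust::adjustedRandIndex(labels, cc$labels)), 0.05)
})

test_that("flat hazards yield calibrated (non-significant) log-rank tests", {
  ps <- vapply(1:20, function(s) {
    cc <- generate_cohort(cohort_spec(n_samples = 150, n_genes = 60,
                                      signature_size = 40,
                                      hazard_ratios = c(1, 1, 1, 1),
                                      mixing = rep(0.25, 4)), seed = 100 + s)
    logrank_test(cc$survival, cc$labels)$p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 4)  # ~ binomial(20, 0.05)
})

test_that("the censoring fraction matches its target in expectation", {
  cc <- generate_cohort(cohort_spec(n_samples = 5000, n_genes = 20,
                                    signature_size = 10,
                                    censoring_rate = 0.3), seed = 65)
  expect_lt(abs(mean(1 - cc$survival$event) - 0.3), 0.03)
  cc0 <- generate_cohort(cohort_spec(n_samples = 500, n_genes = 20,
                                     signature_size = 10,
                                     censoring_rate = 0), seed = 66)
  expect_true(all(cc0$survival$event == 1))
})

test_that("reference profiles produce the requested cluster gradient", {
  cc <- generate_cohort(cohort_spec(n_samples = 300, n_genes = 200,
                                    signature_size = 80,
                                    mixing = rep(0.25, 4)), seed = 67)
  m <- subset_to_signature(z_normalize(cc$expression), cc$signature)

  # weight 1 on cluster 3, zero noise: cluster-3 samples are the most similar
  ref3 <- generate_reference_profile(cc$centroids, c(0, 0, 1, 0))
  sim3 <- similarity_to_reference(m, ref3)
  mean_by_cluster <- tapply(sim3$scaled, cc$labels[sim3$sample_id], mean)
  expect_equal(unname(which.max(mean_by_cluster)), 3L)

  # strictly increasing weights: strictly increasing cluster means
  ref_grad <- generate_reference_profile(cc$centroids, c(1, 2, 3, 4))
  simg <- similarity_to_reference(m, ref_grad)
  mg <- tapply(simg$scaled, cc$labels[simg$sample_id], mean)
  expect_true(all(diff(mg) > 0))

  # equal weights: no meaningful trend across clusters
  ref_eq <- generate_reference_profile(cc$centroids, rep(1, 4),
                                       noise_sd = 1, seed = 68)
  sime <- similarity_to_reference(m, ref_eq)
  me <- tapply(sime$raw, cc$labels[sime$sample_id], mean)
  expect_lt(diff(range(me)), 0.2)

  expect_error(generate_reference_profile(cc$centroids, c(1, 2)), "per cluster")
})
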