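test_that("hypergeometric enrichment matches combinatorial enumeration", {
  cl <- rep(c("c1", "c2"), c(5, 15))
  ca <- c(rep("g", 4), "x", rep("g", 6), rep("x", 9))  # N=20, K=10, n=5, k=4
  enr <- hypergeometric_enrichment(cl, ca)
  expected <- (choose(10, 4) * choose(10, 1) + choose(10, 5)) / choose(20, 5)
  expect_equal(enr$p["c1", "g"], expected, tolerance = 1e-10)
  expect_equal(expected, 0.1517, tolerance = 1e-4)
  cnt <- enr$counts[enr$counts$cluster == "c1" & enr$counts$category == "g", ]
  expect_equal(unlist(cnt[, c("N", "K", "n", "k")], use.names = FALSE),
               c(20, 10, 5, 4))

  # k = 0 and K = N are certain events
  enr0 <- hypergeometric_enrichment(c("a", "a", "b"), c("x", "x", "y"))
  expect_equal(enr0$p["b", "x"], 1)  # k = 0
  enr1 <- hypergeometric_enrichment(c("a", "b"), c("x", "x"))
  expect_true(all(enr1$p[, "x"] == 1))  # category covers the universe

  # complement identity against the enumeration oracle across small cases
  set.seed(51)
  for (rep in 1:20) {
    N <- sample(5:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    upper <- hyper_upper_oracle(N, K, n, k)
    lo_support <- max(0, n - (N - K))
    lower <- if (k - 1 < lo_support) 0 else {
      js <- seq.int(lo_support, k - 1)
      sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
    }
    expect_equal(upper + lower, 1, tolerance = 1e-12)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE), upper,
                 tolerance = 1e-12)
  }

  # samples with missing annotation leave that column's universe
  enr_na <- hypergeometric_enrichment(c("a", "a", "b", "b"),
                                      c("x", NA, "y", "y"))
  expect_equal(unique(enr_na$counts$N), 3)
  expect_error(hypergeometric_enrichment("a", NA), "empty universe")
})

test_that("reference similarity is rank-based and min-max scaled", {
  set.seed(52)
  genes <- paste0("g", 1:20)
  ref <- setNames(rnorm(20), genes)
  m <- cbind(s1 = ref, s2 = -ref, s3 = rnorm(20))
  rownames(m) <- genes
  sim <- similarity_to_reference(m, ref)
  expect_equal(sim$raw[1], 1)
  expect_equal(sim$scaled[1], 1)     # the cohort max
  expect_equal(sim$scaled[2], 0)     # the cohort min (r = -1)
  # monotone transform of either profile leaves raw correlations unchanged
  sim2 <- similarity_to_reference(m, exp(ref) * 3)
  expect_equal(sim2$raw, sim$raw)
  # two-sample cohorts hit the min-max endpoints exactly
  sim3 <- similarity_to_reference(m[, 1:2], ref)
  expect_setequal(sim3$scaled, c(0, 1))
  # degenerate cohort: all correlations equal
  expect_warning(sim4 <- similarity_to_reference(m[, c(1, 1)], ref),
                 "equally similar")
  expect_true(all(sim4$scaled == 0.5))
  expect_error(similarity_to_reference(m[1:2, ], ref[1:2]), "fewer than 3")
})

test_that("marker profiles rank clusters and flag planted shifts", {
  set.seed(53)
  n <- 200
  labels <- rep(c("k1", "k2"), each = n / 2)
  m <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("VIM", "CDH1", "OTHER"), paste0("s", 1:n)))
  m["VIM", labels == "k2"] <- m["VIM", labels == "k2"] + 3  # +3 sd shift
  expect_warning(prof <- marker_profile(m, labels,
                                        markers = c("VIM", "CDH1", "ABSENT")),
                 "ABSENT")
  vim_k2 <- prof[prof$marker == "VIM" & prof$cluster == "k2", ]
  expect_equal(vim_k2$rank, 1)
  expect_lt(vim_k2$p, 1e-6)

  # two-cluster hand example: Welch t statistic from the textbook formula
  x1 <- c(1, 2, 3, 4); x0 <- c(2, 4, 6, 8)
  mm <- matrix(c(x1, x0), 1, 8,
               dimnames = list("CDH1", paste0("s", 1:8)))
  p <- marker_profile(mm, rep(c("a", "b"), each = 4), markers = "CDH1")
  tstat <- (mean(x1) - mean(x0)) /
    sqrt(var(x1) / 4 + var(x0) / 4)
  df <- (var(x1) / 4 + var(x0) / 4)^2 /
    ((var(x1) / 4)^2 / 3 + (var(x0) / 4)^2 / 3)
  expect_equal(p$p[p$cluster == "a"], 2 * pt(-abs(tstat), df),
               tolerance = 1e-12)
})

test_that("per-gene survival association finds planted prognostic genes", {
  set.seed(54)
  n <- 500
  z <- rnorm(n)
  ev_t <- rexp(n, 0.01 * exp(0.8 * z))
  cs_t <- rexp(n, 0.003)
  surv <- surv_fixture(pmin(ev_t, cs_t), as.integer(ev_t <= cs_t),
                       ids = paste0("s", 1:n))
  m <- rbind(HIT = z, matrix(rnorm(20 * n), 20, n))
  rownames(m) <- c("HIT", paste0("null", 1:20))
  colnames(m) <- surv$sample_id
  res <- per_gene_survival_association(m, surv)
  expect_equal(res$gene[1], "HIT")
  expect_lt(res$p[1], 0.01)
  expect_gte(attr(res, "n_significant"), 1)

  # permuted survival keeps the false-positive fraction near alpha
  surv_perm <- surv
  perm <- sample(n)
  surv_perm$time <- surv$time[perm]; surv_perm$event <- surv$event[perm]
  res0 <- per_gene_survival_association(m, surv_perm)
  expect_lte(attr(res0, "n_significant"), 3)

  mC <- rbind(m, CONST = rep(1, n))
  expect_warning(per_gene_survival_association(mC, surv), "constant")
})

test_that("TF differential expression recovers planted hits under Bonferroni", {
  set.seed(55)
  n <- 160
  labels <- rep(paste0("k", 1:4), each = n / 4)
  tfs <- c("TF_PLANT", paste0("TF", 1:30))
  m <- matrix(rnorm(length(tfs) * n), length(tfs), n,
              dimnames = list(tfs, paste0("s", 1:n)))
  m["TF_PLANT", labels == "k3"] <- m["TF_PLANT", labels == "k3"] + 2.5
  res <- tf_differential_expression(m, labels, gene_list = tfs)
  expect_equal(attr(res, "top")$top_over[attr(res, "top")$cluster == "k3"],
               "TF_PLANT")
  # Bonferroni definition over all tests performed
  expect_equal(res$p_adj, pmin(1, res$p * nrow(res)))
  # singleton clusters are skipped with a warning
  expect_warning(
    res1 <- tf_differential_expression(m[, 1:41],
                                       c(rep("a", 20), rep("b", 20), "c")),
    "size 1")
  expect_false("c" %in% res1$cluster)
})

test_that("Jaccard concordance matches set arithmetic and matching invariance", {
  ids <- paste0("s", 1:6)
  a <- setNames(c("x", "x", "x", "y", "y", "y"), ids)
  b <- setNames(c("p", "p", "q", "q", "q", "q"), ids)
  jc <- jaccard_concordance(a, b)
  # x = {1,2,3}; p = {1,2}: |int| = 2, |union| = 3
  expect_equal(jc$jaccard["x", "p"], 2 / 3)
  expect_equal(jc$jaccard["x", "q"], 1 / 6)
  expect_equal(jc$jaccard["y", "q"], 3 / 4)
  expect_equal(jc$matched_mean, mean(c(2 / 3, 3 / 4)))

  # identical labelings: matched diagonal all 1
  expect_equal(jaccard_concordance(a, a)$matched_mean, 1)
  # renaming clusters leaves the matched mean at 1
  a_renamed <- setNames(ifelse(a == "x", "beta", "alpha"), ids)
  expect_equal(jaccard_concordance(a, a_renamed)$matched_mean, 1)
  # matched mean 1 only for identical-up-to-renaming labelings
  expect_lt(jaccard_concordance(a, b)$matched_mean, 1)

  expect_error(jaccard_concordance(setNames("x", "s1"), setNames("y", "s2")),
               "share no samples")
})
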