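#' Specification of a synthetic breast-cancer-like cohort
#'
#' Defaults mirror the scale of a lymph-node-negative discovery cohort:
#' 562 samples, a 388-gene signature inside a larger gene panel, K = 4
#' latent expression clusters with mixing proportions (0.194, 0.457, 0.260,
#' 0.089), proportional-hazards survival with cluster-dependent hazard
#' ratios and independent exponential censoring.
#'
#' `separation` is the per-gene between-cluster shift in units of the
#' within-cluster noise sd: each cluster over-expresses its own block of
#' signature genes by `separation * noise_sd` (block design), so
#' `separation = 0` yields structureless data and `separation >= 6`
#' well-separated blobs.
#'
#' @param n_samples Cohort size.
#' @param n_genes Total gene panel size (signature genes plus background).
#' @param signature_size Number of signature genes with cluster structure.
#' @param K Number of latent clusters.
#' @param mixing Cluster mixing proportions (length K, summing to 1).
#' @param separation Per-gene between-cluster shift / noise sd.
#' @param noise_sd Within-cluster expression noise sd.
#' @param hazard_ratios Per-cluster hazard ratios (length K, > 0).
#' @param baseline_hazard Baseline exponential event rate per month.
#' @param censoring_rate Target fraction of censored samples, in `[0, 1)`.
#' @param covariate_effects Named log-hazard effects of the clinical
#'   covariates (`age` per decade, `size` and `grade` per ordinal step).
#' @param confounding Strength in `[0, 1]` with which categorical clinical
#'   labels (PAM50-like, receptor status, size, grade) are tied to the
#'   latent cluster; 0 = independent.
#' @return Validated list classed `"emat_cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 562, n_genes = 2000, signature_size = 388,
                        K = 4, mixing = c(0.194, 0.457, 0.260, 0.089),
                        separation = 6, noise_sd = 1,
                        hazard_ratios = c(1, 1.5, 2, 4),
                        baseline_hazard = 0.002, censoring_rate = 0.3,
                        covariate_effects = c(age = 0, size = 0, grade = 0),
                        confounding = 0.5) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               signature_size = as.integer(signature_size), K = as.integer(K),
               mixing = mixing, separation = separation, noise_sd = noise_sd,
               hazard_ratios = hazard_ratios,
               baseline_hazard = baseline_hazard,
               censoring_rate = censoring_rate,
               covariate_effects = covariate_effects,
               confounding = confounding)
  if (length(spec$mixing) != spec$K || abs(sum(spec$mixing) - 1) > 1e-8)
    stop2("mixing proportions must have length K and sum to 1")
  if (length(spec$hazard_ratios) != spec$K || any(spec$hazard_ratios <= 0))
    stop2("hazard_ratios must have length K and be positive")
  if (spec$censoring_rate < 0 || spec$censoring_rate >= 1)
    stop2("censoring_rate must be in [0, 1)")
  if (spec$K > spec$n_samples) stop2("K exceeds the number of samples")
  if (spec$signature_size > spec$n_genes)
    stop2("signature_size exceeds n_genes")
  class(spec) <- "emat_cohort_spec"
  spec
}

#' Simulate perturbation fold-change experiments with a planted signature
#'
#' Planted genes receive linear-scale ratios beyond the derivation
#' threshold (in a random direction) in at least `min_experiments`
#' randomly chosen experiments; all other cells are log-normally
#' concentrated near a ratio of 1.
#'
#' @param n_genes Gene panel size.
#' @param n_experiments Number of perturbation experiments, default 4.
#' @param planted Either a count or a character vector of planted gene ids.
#' @param fold_range Range of planted fold changes (both ends > 1; down
#'   calls use the reciprocal).
#' @param min_experiments Minimum experiments in which a planted gene is
#'   regulated, default 2.
#' @param noise_sd Background log2-ratio sd, default 0.2.
#' @param seed Optional RNG seed.
#' @return List: `folds` (a [fold_change_table()]), `truth` (planted gene
#'   ids), `directions` (planted per-gene direction).
#' @export
simulate_perturbation_experiments <- function(n_genes = 1000,
                                              n_experiments = 4,
                                              planted = 138,
                                              fold_range = c(2, 4),
                                              min_experiments = 2,
                                              noise_sd = 0.2,
                                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(fold_range <= 1))
    stop2("fold_range must lie strictly above 1 (reciprocals are used for down calls)")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (is.character(planted)) {
    if (!all(planted %in% genes)) stop2("planted genes must lie in the gene universe")
    truth <- planted
  } else {
    truth <- genes[seq_len(as.integer(planted))]
  }
  vals <- matrix(2^stats::rnorm(n_genes * n_experiments, 0, noise_sd),
                 n_genes, n_experiments,
                 dimnames = list(genes, sprintf("exp%d", seq_len(n_experiments))))
  directions <- stats::setNames(sample(c("up", "down"), length(truth),
                                       replace = TRUE), truth)
  for (g in truth) {
    n_active <- sample(seq.int(min_experiments, n_experiments), 1L)
    active <- sample.int(n_experiments, n_active)
    fc <- stats::runif(n_active, fold_range[1L], fold_range[2L])
    vals[g, active] <- if (directions[[g]] == "up") fc else 1 / fc
  }
  list(folds = fold_change_table(vals), truth = truth,
       directions = directions)
}

# exponential censoring rate achieving the target censoring fraction in
# expectation, given per-sample event rates: E[censored] = mean(mu/(rate+mu))
censoring_rate_for <- function(event_rates, target) {
  if (target == 0) return(0)
  f <- function(mu) mean(mu / (event_rates + mu)) - target
  stats::uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
}

#' Generate a full synthetic cohort
#'
#' Expression: each latent cluster over-expresses its own block of
#' signature genes by `separation * noise_sd`; background genes are pure
#' noise. Survival: exponential event times with per-sample rate
#' `baseline_hazard * HR(cluster) * exp(clinical effects)`, censored by an
#' independent exponential time whose rate is solved analytically for the
#' requested censoring fraction. Categorical clinical labels are tied to
#' the latent cluster with probability `confounding` (else drawn from the
#' marginal), emulating subtype enrichments.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional RNG seed; the output is fully determined by
#'   `(spec, seed)`.
#' @return List: `expression` (log2-scale [expression_matrix()]),
#'   `signature` (the planted [gene_signature()]), `clinical` (categorical
#'   data frame), `covariates` (encoded numeric [encode_covariates()]
#'   table), `survival` (a [survival_table()]), `labels` (true cluster
#'   index per sample), `centroids` (signature-gene centroids, genes x K).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "emat_cohort_spec")) stop2("spec must be a cohort_spec()")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_samples; K <- spec$K
  m_sig <- spec$signature_size
  genes <- c(sprintf("SIG%03d", seq_len(m_sig)),
             sprintf("BG%04d", seq_len(spec$n_genes - m_sig)))
  samples <- sprintf("S%04d", seq_len(n))
  labels <- sample.int(K, n, replace = TRUE, prob = spec$mixing)
  # block design: signature genes split into K contiguous blocks
  block <- cut(seq_len(m_sig), breaks = K, labels = FALSE)
  centroids <- matrix(0, m_sig, K,
                      dimnames = list(genes[seq_len(m_sig)], seq_len(K)))
  for (k in seq_len(K))
    centroids[block == k, k] <- spec$separation * spec$noise_sd
  vals <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd),
                 spec$n_genes, n, dimnames = list(genes, samples))
  vals[seq_len(m_sig), ] <- vals[seq_len(m_sig), ] + centroids[, labels]
  expr <- expression_matrix(vals, scale = "log2")
  # planted signature: EMT/MAT source split proportional to 253/138
  n_emt <- round(m_sig * 253 / 388)
  signature <- gene_signature(genes[seq_len(m_sig)],
                              direction = "unknown",
                              source = c(rep("EMT", n_emt),
                                         rep("MAT", m_sig - n_emt)),
                              name = "planted")
  # clinical labels, optionally confounded with the latent cluster
  draw_cat <- function(levels, preferred_by_cluster) {
    marginal <- sample(levels, n, replace = TRUE)
    tied <- preferred_by_cluster[labels]
    use_tie <- stats::runif(n) < spec$confounding
    ifelse(use_tie, tied, marginal)
  }
  pam_levels <- c("normal-like", "luminal A", "luminal B", "HER2", "basal")
  clinical <- data.frame(
    age = round(stats::rnorm(n, 61, 10)),
    size_class = draw_cat(c("<2", "2-5", ">5"),
                          c("<2", "2-5", "2-5", ">5")[seq_len(K)]),
    grade = draw_cat(c("low", "intermediate", "high"),
                     c("low", "intermediate", "intermediate", "high")[seq_len(K)]),
    er = draw_cat(c("positive", "negative"),
                  c("positive", "positive", "positive", "negative")[seq_len(K)]),
    her2 = draw_cat(c("positive", "negative"),
                    c("negative", "positive", "negative", "negative")[seq_len(K)]),
    pam50 = draw_cat(pam_levels, pam_levels[pmin(5L, seq_len(K))]),
    chemo = stats::runif(n) < 0.1,
    hormonal = stats::runif(n) < 0.45,
    radiation = stats::runif(n) < 0.5,
    row.names = samples, stringsAsFactors = FALSE)
  covariates <- encode_covariates(clinical)
  eff <- spec$covariate_effects
  lin <- eff[["age"]] * (covariates$age - 61) / 10 +
    eff[["size"]] * (covariates$size - 2) +
    eff[["grade"]] * (covariates$grade - 2)
  rates <- spec$baseline_hazard * spec$hazard_ratios[labels] * exp(lin)
  event_time <- stats::rexp(n, rates)
  mu <- censoring_rate_for(rates, spec$censoring_rate)
  cens_time <- if (mu == 0) rep(Inf, n) else stats::rexp(n, mu)
  surv <- survival_table(samples, pmin(event_time, cens_time),
                         as.integer(event_time <= cens_time),
                         endpoint = "synthetic")
  list(expression = expr, signature = signature, clinical = clinical,
       covariates = covariates, survival = surv,
       labels = stats::setNames(labels, samples), centroids = centroids)
}

#' Generate a reference profile with a chosen cluster gradient
#'
#' Builds a reference expression profile (a stand-in for an embryonic stem
#' cell line) as a weighted combination of cluster centroids plus noise, so
#' samples' expected similarity to the reference is monotone in the weight
#' of their cluster.
#'
#' @param centroids Genes x K centroid matrix (e.g. from
#'   [generate_cohort()]).
#' @param weights Length-K non-negative gradient weights.
#' @param noise_sd Additive Gaussian noise on the profile, default 0.
#' @param seed Optional RNG seed.
#' @return Named numeric vector over the centroid genes.
#' @export
generate_reference_profile <- function(centroids, weights, noise_sd = 0,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(weights) != ncol(centroids))
    stop2("weights must have one entry per cluster")
  profile <- as.numeric(centroids %*% (weights / max(sum(weights), 1e-12)))
  if (noise_sd > 0) profile <- profile + stats::rnorm(length(profile), 0, noise_sd)
  stats::setNames(profile, rownames(centroids))
}
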