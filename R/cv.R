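#' Define a feature set for the survival cross-validation benchmark
#'
#' @param name Display name, e.g. `"CP"` or `"CP+EMAT"`.
#' @param covariates Character vector of covariate-table column names.
#' @param includes_emat If `TRUE`, an ordinal EMAT cluster covariate is
#'   added, re-derived inside every split from the training half only
#'   (clustered, outcome-named, then transferred to the test half with the
#'   centroid classifier).
#' @return List classed `"emat_feature_set"`.
#' @export
feature_set <- function(name, covariates, includes_emat = FALSE) {
  structure(list(name = name, covariates = as.character(covariates),
                 includes_emat = isTRUE(includes_emat)),
            class = "emat_feature_set")
}

#' Percentage of improved folds (PIF)
#'
#' Percent of paired repeats in which the candidate's C-index strictly
#' exceeds the baseline's. Ties and losses both count against the
#' candidate.
#'
#' @param c_candidate,c_baseline Per-repeat C-index vectors, paired.
#' @return Percentage in `[0, 100]`.
#' @export
pif <- function(c_candidate, c_baseline) {
  if (length(c_candidate) != length(c_baseline))
    stop2("paired C-index vectors must have equal length")
  keep <- !is.na(c_candidate) & !is.na(c_baseline)
  if (!any(keep)) stop2("no complete pairs")
  100 * mean(c_candidate[keep] > c_baseline[keep])
}

#' One-sided Wilcoxon signed-rank test (candidate greater)
#'
#' Zero differences are dropped (Wilcoxon convention) and absolute
#' differences are ranked with average ranks for ties. For `n <= exact_limit`
#' non-zero differences, the p-value is exact over all `2^n` equiprobable
#' sign assignments (computed by convolution over the doubled ranks, so ties
#' are handled exactly); above that, a normal approximation with continuity
#' correction and the standard tie-adjusted variance is used.
#'
#' @param diffs Paired differences (candidate minus baseline).
#' @param exact_limit Largest `n` for the exact null distribution,
#'   default 20.
#' @return One-sided p-value for the alternative "candidate greater"; the
#'   signed-rank statistic W+ is attached as attribute `"statistic"`.
#' @export
wilcoxon_signed_rank_one_sided <- function(diffs, exact_limit = 20) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop2("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2*W+ over sign flips: product of (1 + x^{2 r_i}) / 2
    w2 <- round(2 * r)
    counts <- rep(0, sum(w2) + 1L)  # counts[s + 1] = #assignments with 2W = s
    counts[1L] <- 1
    for (wi in w2) {
      shifted <- c(rep(0, wi), counts[seq_len(length(counts) - wi)])
      counts <- counts + shifted
    }
    p <- sum(counts[seq.int(round(2 * W) + 1L, length(counts))]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  structure(min(max(p, 0), 1), statistic = W)
}

#' Repeated split-half cross-validation of prognostic feature sets
#'
#' Reproduces the benchmark design comparing classes of survival
#' predictors: in every repeat the cohort is split at random into halves
#' (the training half gets the extra sample when `n` is odd); the training
#' half is Ward-clustered into `K` EMAT groups on the signature matrix and
#' outcome-named; a centroid classifier transfers EMAT labels to the test
#' half; each feature set's Cox model is fitted on the training half and its
#' linear predictor is scored on the test half with Harrell's C-index.
#' After all repeats, the EMAT-containing set is compared against every
#' baseline with PIF and a one-sided Wilcoxon signed-rank test on the
#' paired C-index values.
#'
#' @param expr Expression matrix (genes x samples), already restricted to
#'   the signature and z-scored.
#' @param covariates Data frame of encoded numeric covariates, rows aligned
#'   with `surv`.
#' @param surv A [survival_table()] whose `sample_id`s match `colnames(expr)`.
#' @param feature_sets List of [feature_set()] objects; exactly one should
#'   have `includes_emat = TRUE` to serve as the candidate.
#' @param n_repeats Number of random partitions, default 200.
#' @param K Number of EMAT clusters per training half, default 4.
#' @param seed Optional RNG seed for reproducible splits.
#' @param horizon Months horizon used to outcome-name training clusters
#'   (capped at the training half's longest follow-up).
#' @return List classed `"emat_cv"`: `cindex` (repeat x feature-set data
#'   frame), `comparisons` (PIF and signed-rank p per baseline),
#'   `n_excluded` (repeats dropped for Cox failure), `n_redrawn`, `seed`.
#' @export
run_cv_comparison <- function(expr, covariates, surv, feature_sets,
                              n_repeats = 200, K = 4, seed = NULL,
                              horizon = 120) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(expr)
  if (!identical(colnames(expr), surv$sample_id))
    stop2("expression columns and survival rows must be aligned")
  if (nrow(covariates) != n)
    stop2("covariate rows must align with samples")
  if (n_repeats < 1L) stop2("n_repeats must be >= 1")
  set_names <- vapply(feature_sets, `[[`, "", "name")
  cmat <- matrix(NA_real_, n_repeats, length(feature_sets),
                 dimnames = list(NULL, set_names))
  excluded <- logical(n_repeats)
  n_redrawn <- 0L
  n_train <- ceiling(n / 2)
  for (rep_i in seq_len(n_repeats)) {
    repeat {
      train <- sort(sample.int(n, n_train))
      model <- ward_cluster(expr[, train, drop = FALSE], K)
      if (min(table(model$labels)) >= 2L) break
      n_redrawn <- n_redrawn + 1L  # degenerate training cluster: redraw split
    }
    test <- setdiff(seq_len(n), train)
    surv_train <- surv[train, , drop = FALSE]
    surv_test <- surv[test, , drop = FALSE]
    model <- assign_cluster_names(model, surv_train,
                                  horizon = min(horizon, max(surv_train$time)))
    emat_train <- match(cluster_names(model), paste0("EMAT", seq_len(K)))
    clf <- fit_centroids(expr[, train, drop = FALSE], model)
    pred <- predict(clf, expr[, test, drop = FALSE])
    emat_test <- match(pred, paste0("EMAT", seq_len(K)))
    ok <- TRUE
    for (f in seq_along(feature_sets)) {
      fs <- feature_sets[[f]]
      ctr <- covariates[train, fs$covariates, drop = FALSE]
      cte <- covariates[test, fs$covariates, drop = FALSE]
      if (fs$includes_emat) {
        ctr$emat <- emat_train
        cte$emat <- emat_test
      }
      res <- tryCatch({
        fit <- suppressWarnings(cox_fit(ctr, surv_train))
        beta <- stats::coef(fit$fit)
        beta[is.na(beta)] <- 0
        risk <- as.numeric(as.matrix(cte) %*% beta)
        as.numeric(concordance_index(risk, surv_test))
      }, error = function(e) NA_real_)
      if (is.na(res)) ok <- FALSE
      cmat[rep_i, f] <- res
    }
    if (!ok) excluded[rep_i] <- TRUE
  }
  cand <- which(vapply(feature_sets, `[[`, TRUE, "includes_emat"))
  comparisons <- NULL
  if (length(cand) == 1L && length(feature_sets) > 1L) {
    keep <- !excluded
    comparisons <- do.call(rbind, lapply(
      setdiff(seq_along(feature_sets), cand), function(f) {
        diffs <- cmat[keep, cand] - cmat[keep, f]
        data.frame(candidate = set_names[cand], baseline = set_names[f],
                   pif = pif(cmat[keep, cand], cmat[keep, f]),
                   p_signed_rank = as.numeric(
                     wilcoxon_signed_rank_one_sided(diffs)))
      }))
  }
  structure(list(cindex = as.data.frame(cmat), comparisons = comparisons,
                 n_excluded = sum(excluded), n_redrawn = n_redrawn,
                 seed = seed),
            class = "emat_cv")
}

#' @export
print.emat_cv <- function(x, ...) {
  cat(sprintf("Cross-validation benchmark: %d repeats (%d excluded)\n",
              nrow(x$cindex), x$n_excluded))
  cat("mean C-index per feature set:\n")
  print(round(colMeans(x$cindex, na.rm = TRUE), 4))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}
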