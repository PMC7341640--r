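#' Ward hierarchical clustering of samples over signature genes
#'
#' Samples (matrix columns) are clustered agglomeratively with Ward's
#' variance-minimization criterion on Euclidean distances of the (typically
#' z-scored) signature matrix, and the tree is cut to exactly `K` clusters.
#' `hclust(method = "ward.D2")` implements the same objective as SciPy's
#' Ward linkage, so partitions are comparable across toolkits. Cluster
#' indices follow `cutree`'s deterministic order of first appearance.
#'
#' @param m Expression matrix (genes x samples), usually restricted to the
#'   signature and z-scored.
#' @param K Number of clusters, `1 <= K <= n_samples`.
#' @return A list classed `"emat_clusters"` with elements `labels` (named
#'   integer vector 1..K), `K`, `hclust` (the merge record, sufficient to
#'   re-cut the tree), `centroids` (genes x K per-cluster means) and
#'   `name_map` (cluster index -> display name; identity names until
#'   [assign_cluster_names()] is applied).
#' @export
ward_cluster <- function(m, K) {
  n <- ncol(m)
  K <- as.integer(K)
  if (K < 1L) stop2("K must be at least 1")
  if (K > n) stop2("K (", K, ") exceeds the number of samples (", n, ")")
  hc <- stats::hclust(stats::dist(t(unclass(m))), method = "ward.D2")
  labels <- stats::cutree(hc, k = K)
  names(labels) <- colnames(m)
  centroids <- cluster_centroids(m, labels)
  structure(list(labels = labels, K = K, hclust = hc, centroids = centroids,
                 name_map = stats::setNames(paste0("cluster", seq_len(K)),
                                            seq_len(K))),
            class = "emat_clusters")
}

#' @export
print.emat_clusters <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d samples in %d clusters\n",
              length(x$labels), x$K))
  print(table(x$name_map[x$labels]))
  invisible(x)
}

# per-cluster per-gene mean expression
cluster_centroids <- function(m, labels) {
  ks <- sort(unique(labels))
  out <- vapply(ks, function(k) rowMeans(unclass(m)[, labels == k, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), as.character(ks))
  out
}

#' Display names of cluster assignments
#' @param model An `"emat_clusters"` object.
#' @return Named character vector of per-sample display names.
#' @export
cluster_names <- function(model) {
  stats::setNames(unname(model$name_map[as.character(model$labels)]),
                  names(model$labels))
}

# pairwise sample-sample distance matrix under the silhouette metrics
sample_distances <- function(m, metric = c("euclidean", "cosine", "correlation")) {
  metric <- match.arg(metric)
  x <- unclass(m)
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(t(x))),
    correlation = 1 - stats::cor(x),
    cosine = {
      nrm <- sqrt(colSums(x^2))
      if (any(nrm == 0)) stop2("cosine distance undefined for all-zero sample")
      1 - crossprod(x / rep(nrm, each = nrow(x)))
    })
  diag(D) <- 0
  D
}

#' Mean silhouette score of a clustering
#'
#' Per-sample silhouette \eqn{s = (b - a) / max(a, b)} with `a` the mean
#' distance to the sample's own cluster and `b` the smallest mean distance
#' to any other cluster; samples in singleton clusters contribute `s = 0`.
#' Cosine and correlation distances are `1 - similarity`.
#'
#' @param m Expression matrix (genes x samples).
#' @param labels Per-sample cluster labels (>= 2 distinct values).
#' @param metric Distance measure: `"euclidean"`, `"cosine"` or
#'   `"correlation"`.
#' @return Mean silhouette over samples, in `[-1, 1]`; per-sample widths in
#'   attribute `"widths"`.
#' @export
silhouette_score <- function(m, labels,
                             metric = c("euclidean", "cosine", "correlation")) {
  ks <- unique(labels)
  if (length(ks) < 2L) stop2("silhouette needs at least 2 clusters")
  if (length(labels) != ncol(m))
    stop2("labels must align with matrix columns")
  D <- sample_distances(m, metric)
  sizes <- table(labels)
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, labels == own]) / (sizes[[as.character(own)]] - 1L)
    b <- min(vapply(setdiff(ks, own),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  structure(mean(s), widths = s)
}

#' Select the number of clusters by average silhouette
#'
#' Cuts one Ward tree at each candidate `K` and scores the partition with
#' the average silhouette under three distance measures (cosine, Euclidean,
#' correlation). The chosen `K` maximizes the mean of the three averages;
#' ties go to the smaller `K`.
#'
#' @param m Expression matrix (genes x samples) over signature genes.
#' @param candidates Candidate cluster counts, all >= 2. Default `3:5`.
#' @return A list classed `"emat_silhouette"` with `scores` (long data frame
#'   K x metric x score), `summary` (per-K mean of the three metrics) and
#'   `chosen_K`.
#' @export
select_n_clusters <- function(m, candidates = 3:5) {
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 2L)) stop2("candidate cluster counts must be >= 2")
  if (max(candidates) > ncol(m))
    stop2("largest candidate K exceeds the number of samples")
  hc <- stats::hclust(stats::dist(t(unclass(m))), method = "ward.D2")
  metrics <- c("cosine", "euclidean", "correlation")
  Ds <- lapply(stats::setNames(metrics, metrics),
               function(met) sample_distances(m, met))
  rows <- list()
  for (K in candidates) {
    labels <- stats::cutree(hc, k = K)
    for (met in metrics) {
      sc <- mean_silhouette_from_dist(Ds[[met]], labels)
      rows[[length(rows) + 1L]] <-
        data.frame(K = K, metric = met, score = sc)
    }
  }
  scores <- do.call(rbind, rows)
  summary <- stats::aggregate(score ~ K, scores, mean)
  chosen <- summary$K[which.max(summary$score)]  # which.max: first (smallest K) on ties
  structure(list(scores = scores, summary = summary,
                 chosen_K = as.integer(chosen), hclust = hc),
            class = "emat_silhouette")
}

#' @export
print.emat_silhouette <- function(x, ...) {
  cat("Silhouette-based cluster-number selection\n")
  print(x$summary, row.names = FALSE)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

# silhouette mean from a precomputed distance matrix (internal fast path)
mean_silhouette_from_dist <- function(D, labels) {
  ks <- unique(labels)
  sizes <- table(labels)
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) next
    a <- sum(D[i, labels == own]) / (sizes[[as.character(own)]] - 1L)
    b <- min(vapply(setdiff(ks, own),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    if (max(a, b) > 0) s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Name clusters EMAT1..EMATK by outcome
#'
#' Renames clusters in decreasing order of Kaplan-Meier survival probability
#' at a fixed horizon, so EMAT1 is always the best-outcome cluster and EMATK
#' the worst. Ties in survival probability put the larger cluster first.
#'
#' @param model An `"emat_clusters"` object.
#' @param surv A [survival_table()] covering all clustered samples.
#' @param horizon Survival horizon in months (default 120, i.e. 10 years);
#'   must not exceed the longest follow-up in `surv`.
#' @param prefix Display-name prefix, default `"EMAT"`.
#' @return The model with an updated `name_map`; labels and centroids are
#'   untouched (renaming is a pure relabelling).
#' @export
assign_cluster_names <- function(model, surv, horizon = 120, prefix = "EMAT") {
  missing_ids <- setdiff(names(model$labels), surv$sample_id)
  if (length(missing_ids) > 0L)
    stop2("survival table is missing ", length(missing_ids),
          " clustered sample(s), e.g. ", missing_ids[1L])
  if (horizon > max(surv$time))
    stop2("horizon (", horizon, ") lies beyond all follow-up (max ",
          max(surv$time), ")")
  surv <- surv[match(names(model$labels), surv$sample_id), , drop = FALSE]
  ks <- sort(unique(model$labels))
  s_at <- vapply(ks, function(k) {
    sel <- model$labels == k
    fit <- survival::survfit(
      survival::Surv(surv$time[sel], surv$event[sel]) ~ 1)
    summary(fit, times = horizon, extend = TRUE)$surv
  }, numeric(1))
  sizes <- as.numeric(table(model$labels)[as.character(ks)])
  ord <- order(-s_at, -sizes, ks)
  model$name_map <- stats::setNames(
    paste0(prefix, seq_along(ks))[match(ks, ks[ord])], as.character(ks))
  model$survival_at_horizon <- stats::setNames(s_at, model$name_map[as.character(ks)])
  model
}
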