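#' Fit a nearest-centroid classifier from labelled expression
#'
#' For each class, the centroid is the vector of per-gene mean expression
#' over the samples carrying that label. Classification of new samples is by
#' highest Spearman rank correlation with a centroid, which makes the
#' classifier insensitive to monotone intensity distortions between
#' datasets.
#'
#' @param m Expression matrix (genes x samples).
#' @param labels Per-sample class labels aligned with the matrix columns, or
#'   an `"emat_clusters"` model (its display names are used).
#' @param min_coverage Minimum fraction of classifier genes a query profile
#'   must share, in (0, 1]. Default 0.5.
#' @return A list classed `"emat_centroid_classifier"` with `gene_ids`,
#'   `centroids` (genes x K), `class_names` and `min_coverage`.
#' @export
fit_centroids <- function(m, labels, min_coverage = 0.5) {
  if (inherits(labels, "emat_clusters")) labels <- cluster_names(labels)
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop2("labels must align with matrix columns")
  classes <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes == 0L)) stop2("every class needs at least one sample")
  cen <- vapply(classes,
                function(k) rowMeans(unclass(m)[, labels == k, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(cen) <- list(rownames(m), classes)
  structure(list(gene_ids = rownames(m), centroids = cen,
                 class_names = classes, min_coverage = min_coverage),
            class = "emat_centroid_classifier")
}

#' @export
print.emat_centroid_classifier <- function(x, ...) {
  cat(sprintf("Centroid classifier: %d genes, classes %s\n",
              length(x$gene_ids), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

# overlap guard shared by both classifiers
check_overlap <- function(profile, gene_ids, min_coverage) {
  if (is.null(names(profile))) stop2("query profile must be a named vector")
  overlap <- intersect(names(profile), gene_ids)
  coverage <- length(overlap) / length(gene_ids)
  if (length(overlap) < 3L || coverage < min_coverage)
    stop2(sprintf(
      "insufficient gene overlap: %d genes, %.1f%% of the classifier's %d (need >= %.1f%% and >= 3)",
      length(overlap), 100 * coverage, length(gene_ids), 100 * min_coverage))
  overlap
}

#' Classify one expression profile by rank-correlated centroid
#'
#' Spearman rank correlation is computed over the gene intersection between
#' the query and the classifier; the class whose centroid correlates highest
#' is assigned. Exact correlation ties go to the lowest class index with a
#' warning.
#'
#' @param profile Named numeric vector of one sample's expression. Any
#'   monotone transform of the training scale is acceptable (ranks only).
#' @param clf An [fit_centroids()] classifier.
#' @return List with `label` and the per-class `correlations`.
#' @export
classify_centroid <- function(profile, clf) {
  overlap <- check_overlap(profile, clf$gene_ids, clf$min_coverage)
  rho <- vapply(clf$class_names, function(k) {
    stats::cor(profile[overlap], clf$centroids[overlap, k],
               method = "spearman")
  }, numeric(1))
  top <- which(rho == max(rho))
  if (length(top) > 1L)
    warning("correlation tie between classes ",
            paste(clf$class_names[top], collapse = ", "),
            "; assigning the lowest index", call. = FALSE)
  list(label = clf$class_names[top[1L]],
       correlations = stats::setNames(rho, clf$class_names))
}

#' Classify every column of an expression matrix
#'
#' @param object An [fit_centroids()] classifier.
#' @param newdata Expression matrix (genes x samples).
#' @param ... Unused.
#' @return Named character vector of class labels; the per-class correlation
#'   matrix is attached as attribute `"correlations"`.
#' @export
predict.emat_centroid_classifier <- function(object, newdata, ...) {
  res <- lapply(seq_len(ncol(newdata)), function(j) {
    classify_centroid(stats::setNames(newdata[, j], rownames(newdata)), object)
  })
  labels <- vapply(res, `[[`, "", "label")
  names(labels) <- colnames(newdata)
  attr(labels, "correlations") <-
    t(vapply(res, `[[`, numeric(length(object$class_names)), "correlations"))
  labels
}

#' K-nearest-neighbour classification by Spearman correlation
#'
#' Assigns the majority label among the `k` training samples most
#' rank-correlated with the query. Vote ties are broken in favour of the
#' tied class with the larger summed correlation over its voting
#' neighbours.
#'
#' @param profile Named numeric vector of one sample's expression.
#' @param training Expression matrix of the training cohort.
#' @param labels Training labels aligned with `training` columns.
#' @param k Number of neighbours, default 5.
#' @param min_coverage Minimum gene-overlap fraction, default 0.5.
#' @return List with `label`, the `neighbors` used and their correlations.
#' @export
classify_knn <- function(profile, training, labels, k = 5, min_coverage = 0.5) {
  k <- as.integer(k)
  if (k <= 0L) stop2("k must be positive")
  if (k > ncol(training)) stop2("k exceeds the number of training samples")
  labels <- as.character(labels)
  if (length(labels) != ncol(training))
    stop2("labels must align with training columns")
  overlap <- check_overlap(profile, rownames(training), min_coverage)
  rho <- apply(unclass(training)[overlap, , drop = FALSE], 2L, function(col) {
    stats::cor(profile[overlap], col, method = "spearman")
  })
  nn <- order(rho, decreasing = TRUE)[seq_len(k)]
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(rho[nn][labels[nn] == cl]), numeric(1))
    top <- top[which.max(sums)]
  }
  list(label = top[1L],
       neighbors = stats::setNames(rho[nn], colnames(training)[nn]))
}
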