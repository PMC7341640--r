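#' Hypergeometric enrichment of clusters in categorical annotations
#'
#' For cluster `c` and category level `g`, with `N` annotated samples, `K`
#' of them in category `g`, `n` in cluster `c` and `k` in both, the
#' over-representation p-value is `P(X >= k)` for hypergeometric
#' `X ~ Hyper(N, K, n)`. Samples missing the annotation are excluded from
#' that annotation's universe. P-values are reported raw (no multiplicity
#' correction), matching how enrichment heatmaps are usually displayed.
#'
#' @param cluster_labels Per-sample cluster labels.
#' @param category_labels Per-sample category labels (may contain `NA`).
#' @return List classed `"emat_enrichment"`: `p` (clusters x categories
#'   matrix), `counts` (long data frame of N, K, n, k per cell).
#' @export
hypergeometric_enrichment <- function(cluster_labels, category_labels) {
  if (length(cluster_labels) != length(category_labels))
    stop2("cluster and category labels must be aligned")
  keep <- !is.na(category_labels)
  if (!any(keep)) stop2("empty universe: all category labels are missing")
  cl <- as.character(cluster_labels[keep])
  ca <- as.character(category_labels[keep])
  clusters <- sort(unique(cl))
  cats <- sort(unique(ca))
  N <- length(cl)
  p <- matrix(NA_real_, length(clusters), length(cats),
              dimnames = list(clusters, cats))
  counts <- list()
  for (ci in seq_along(clusters)) {
    n <- sum(cl == clusters[ci])
    for (gi in seq_along(cats)) {
      K <- sum(ca == cats[gi])
      k <- sum(cl == clusters[ci] & ca == cats[gi])
      p[ci, gi] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      counts[[length(counts) + 1L]] <-
        data.frame(cluster = clusters[ci], category = cats[gi],
                   N = N, K = K, n = n, k = k)
    }
  }
  structure(list(p = p, counts = do.call(rbind, counts)),
            class = "emat_enrichment")
}

#' @export
print.emat_enrichment <- function(x, ...) {
  cat("Hypergeometric over-representation p-values (clusters x categories):\n")
  print(signif(x$p, 3))
  invisible(x)
}

#' Minus-log10 transform of an enrichment matrix, heatmap-ready
#' @param enr An `"emat_enrichment"` object.
#' @return Matrix of `-log10(p)`.
#' @export
enrichment_neglog10 <- function(enr) -log10(enr$p)

#' Per-sample similarity to a reference expression profile
#'
#' Spearman rank correlation of every sample against a reference profile
#' (e.g. an embryonic stem cell line), then min-max scaled across the
#' cohort so 0 marks the least and 1 the most reference-like sample.
#'
#' @param m Expression matrix (genes x samples).
#' @param reference Named numeric vector of reference expression.
#' @param gene_scope Optional gene set (signature) to compute the
#'   correlation over; default uses all shared genes.
#' @return Data frame (`sample_id`, `raw`, `scaled`) classed
#'   `"emat_similarity"`.
#' @export
similarity_to_reference <- function(m, reference, gene_scope = NULL) {
  genes <- intersect(rownames(m), names(reference))
  if (!is.null(gene_scope)) {
    scope <- if (inherits(gene_scope, "emat_signature")) gene_scope$gene
             else as.character(gene_scope)
    genes <- intersect(genes, scope)
  }
  if (length(genes) < 3L)
    stop2("fewer than 3 genes shared with the reference profile")
  raw <- apply(unclass(m)[genes, , drop = FALSE], 2L, function(col)
    stats::cor(col, reference[genes], method = "spearman"))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all samples equally similar to the reference; scaled values set to 0.5",
            call. = FALSE)
    scaled <- rep(0.5, length(raw))
  } else {
    scaled <- (raw - rng[1L]) / diff(rng)
  }
  structure(data.frame(sample_id = colnames(m), raw = raw, scaled = scaled,
                       row.names = NULL),
            class = c("emat_similarity", "data.frame"))
}

#' Marker expression profile across clusters
#'
#' For each marker gene (defaults are the epithelial, mesenchymal, amoeboid
#' and collective-migration biomarkers CDH1, VIM, RHOA, JUP): per-cluster
#' mean expression, the cluster's rank among clusters (1 = highest mean),
#' and an unpaired two-tailed Welch t-test of the cluster against all other
#' samples.
#'
#' @param m Expression matrix (genes x samples).
#' @param labels Per-sample cluster labels.
#' @param markers Marker gene ids. Markers absent from the matrix are
#'   reported in attribute `"missing"` with a warning; the rest are
#'   computed.
#' @return Long data frame (`marker`, `cluster`, `mean`, `rank`, `p`).
#' @export
marker_profile <- function(m, labels, markers = c("CDH1", "VIM", "RHOA", "JUP")) {
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop2("labels must align with matrix columns")
  missing <- setdiff(markers, rownames(m))
  if (length(missing) > 0L)
    warning("marker(s) absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  markers <- intersect(markers, rownames(m))
  if (length(markers) == 0L) stop2("no marker genes present in the matrix")
  clusters <- sort(unique(labels))
  rows <- list()
  for (g in markers) {
    x <- unclass(m)[g, ]
    mu <- vapply(clusters, function(k) mean(x[labels == k]), numeric(1))
    rk <- rank(-mu, ties.method = "min")
    for (ki in seq_along(clusters)) {
      ink <- labels == clusters[ki]
      p <- tryCatch(stats::t.test(x[ink], x[!ink])$p.value,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(marker = g, cluster = clusters[ki], mean = mu[ki],
                   rank = rk[ki], p = p)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "missing") <- missing
  out
}

#' Univariable survival association of every signature gene
#'
#' Fits one univariable Cox model per gene on its z-scored expression and
#' reports the hazard ratio and Wald p, sorted by p. Constant genes carry
#' no information and are excluded with a warning.
#'
#' @param m Expression matrix restricted to the genes of interest.
#' @param surv A [survival_table()] aligned with the matrix columns.
#' @param alpha Significance threshold for the reported passing count,
#'   default 0.01.
#' @return Data frame (`gene`, `coef`, `hr`, `p`) sorted by `p`;
#'   attributes `"n_significant"` and `"alpha"`.
#' @export
per_gene_survival_association <- function(m, surv, alpha = 0.01) {
  if (ncol(m) != nrow(surv)) stop2("matrix columns must align with survival rows")
  sds <- row_pop_sd(unclass(m))
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " constant gene(s) excluded: ",
            paste(utils::head(rownames(m)[flat], 5L), collapse = ", "),
            call. = FALSE)
  genes <- rownames(m)[!flat]
  rows <- lapply(genes, function(g) {
    z <- (unclass(m)[g, ] - mean(unclass(m)[g, ])) / sds[match(g, rownames(m))]
    fit <- tryCatch(
      suppressWarnings(cox_fit(data.frame(expr = z), surv)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(gene = g, coef = fit$table$coef, hr = fit$table$hr,
               p = fit$table$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$p < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Differential expression of transcription factors across clusters
#'
#' Two-sided Welch t-test of every gene (typically a transcription-factor
#' panel) in each cluster versus all other samples, Bonferroni-corrected
#' over all tests actually performed. Per cluster, the most over- and most
#' under-expressed significant genes (largest absolute mean difference
#' among Bonferroni-significant tests) are summarized.
#'
#' @param m Expression matrix (genes x samples), restricted to the panel.
#' @param labels Per-sample cluster labels.
#' @param gene_list Optional gene ids to restrict the matrix to (e.g. a TF
#'   list, one symbol per line via [readLines()]).
#' @param alpha Adjusted-p significance threshold, default 0.01.
#' @return Data frame (`gene`, `cluster`, `mean_diff`, `p`, `p_adj`,
#'   `direction`, `significant`); per-cluster top hits in attribute
#'   `"top"`.
#' @export
tf_differential_expression <- function(m, labels, gene_list = NULL,
                                       alpha = 0.01) {
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop2("labels must align with matrix columns")
  if (!is.null(gene_list)) {
    genes <- intersect(as.character(gene_list), rownames(m))
    if (length(genes) == 0L) stop2("gene list does not intersect the matrix")
    m <- unclass(m)[genes, , drop = FALSE]
  }
  clusters <- sort(unique(labels))
  usable <- clusters[table(labels)[clusters] >= 2L]
  skipped <- setdiff(clusters, usable)
  if (length(skipped) > 0L)
    warning("cluster(s) of size 1 skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  rows <- list()
  for (k in usable) {
    in_k <- labels == k
    for (g in rownames(m)) {
      x1 <- unclass(m)[g, in_k]
      x0 <- unclass(m)[g, !in_k]
      tt <- tryCatch(stats::t.test(x1, x0), error = function(e) NULL)
      if (is.null(tt)) next
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, cluster = k, mean_diff = mean(x1) - mean(x0),
                   p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop2("no testable (gene, cluster) pairs")
  out$p_adj <- pmin(1, out$p * nrow(out))  # Bonferroni over all tests run
  out$direction <- ifelse(out$mean_diff > 0, "over", "under")
  out$significant <- out$p_adj < alpha
  top <- do.call(rbind, lapply(usable, function(k) {
    sig <- out[out$cluster == k & out$significant, , drop = FALSE]
    pick <- function(dirn) {
      sub <- sig[sig$direction == dirn, , drop = FALSE]
      if (nrow(sub) == 0L) return(NA_character_)
      sub$gene[which.max(abs(sub$mean_diff))]
    }
    data.frame(cluster = k, top_over = pick("over"), top_under = pick("under"))
  }))
  attr(out, "top") <- top
  attr(out, "alpha") <- alpha
  out
}

#' Jaccard concordance between two clusterings
#'
#' Treats each cluster as a set of sample ids and computes the pairwise
#' Jaccard matrix `|a_i & b_j| / |a_i | b_j|`, then finds the one-to-one
#' cluster matching that maximizes the summed Jaccard values (exhaustive
#' over permutations; supported up to 6 clusters).
#'
#' @param labels_a,labels_b Named label vectors over the same sample
#'   universe.
#' @return List classed `"emat_jaccard"`: `jaccard` (matrix), `matching`
#'   (data frame of matched cluster pairs), `matched_mean`.
#' @export
jaccard_concordance <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop2("label vectors must be named by sample id")
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0L) stop2("label vectors share no samples")
  a <- as.character(labels_a[common])
  b <- as.character(labels_b[common])
  ka <- sort(unique(a)); kb <- sort(unique(b))
  J <- matrix(0, length(ka), length(kb), dimnames = list(ka, kb))
  for (i in seq_along(ka)) {
    for (j in seq_along(kb)) {
      inter <- sum(a == ka[i] & b == kb[j])
      J[i, j] <- inter / (sum(a == ka[i]) + sum(b == kb[j]) - inter)
    }
  }
  n_small <- min(dim(J))
  n_big <- max(dim(J))
  if (n_big > 6L) stop2("exhaustive cluster matching supported up to 6 clusters")
  transposed <- nrow(J) > ncol(J)
  M <- if (transposed) t(J) else J  # rows <= cols
  best <- NULL; best_sum <- -Inf
  for (p in all_permutations(n_big)) {
    sel <- p[seq_len(n_small)]
    s <- sum(M[cbind(seq_len(n_small), sel)])
    if (s > best_sum) { best_sum <- s; best <- sel }
  }
  matching <- data.frame(
    cluster_a = if (transposed) colnames(J)[best] else rownames(J)[seq_len(n_small)],
    cluster_b = if (transposed) rownames(J)[seq_len(n_small)] else colnames(J)[best],
    jaccard = M[cbind(seq_len(n_small), best)])
  structure(list(jaccard = J, matching = matching,
                 matched_mean = mean(matching$jaccard)),
            class = "emat_jaccard")
}

#' @export
print.emat_jaccard <- function(x, ...) {
  cat("Jaccard concordance matrix:\n")
  print(round(x$jaccard, 3))
  cat(sprintf("matched mean Jaccard: %.3f\n", x$matched_mean))
  invisible(x)
}
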