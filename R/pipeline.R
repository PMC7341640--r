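#' Run the full subtyping and survival analysis pipeline
#'
#' Orchestrates the analysis end to end: preprocessing (log2 transform when
#' needed, per-gene z-normalization), restriction to the signature,
#' silhouette-based choice of the cluster number, Ward clustering,
#' outcome-based cluster naming, Kaplan-Meier / log-rank and Cox analyses,
#' hypergeometric enrichment against categorical clinical columns, marker
#' profiles, optional reference-similarity scoring and the optional
#' cross-validation benchmark. Stages whose inputs are absent are skipped
#' with a message rather than failing the run.
#'
#' @param expr An [expression_matrix()] (raw, log2 or zscore scale).
#' @param signature A [gene_signature()].
#' @param surv Optional [survival_table()] (required for cluster naming and
#'   all survival stages).
#' @param clinical Optional categorical clinical data frame (for
#'   enrichment; rownames = sample ids).
#' @param covariates Optional encoded covariate table for Cox models and
#'   the CV benchmark.
#' @param reference Optional named reference profile for similarity
#'   scoring.
#' @param candidates Candidate cluster numbers, default `3:5`.
#' @param markers Marker genes profiled across clusters.
#' @param min_coverage Signature-coverage threshold, default 0.5.
#' @param cv_repeats Number of CV repeats; 0 (default) skips the benchmark.
#' @param seed RNG seed recorded in the manifest and used for the CV
#'   benchmark.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV with a comment header carrying seed, config hash and
#'   package version.
#' @return List classed `"emat_pipeline"` with elements `silhouette`,
#'   `clusters`, `labels` (named display labels), `km` (per-cluster
#'   Kaplan-Meier), `logrank`, `cox_univariable`, `cox_multivariable`,
#'   `enrichment`, `markers`, `similarity`, `cv` and `manifest`.
#' @export
run_full_pipeline <- function(expr, signature, surv = NULL, clinical = NULL,
                              covariates = NULL, reference = NULL,
                              candidates = 3:5,
                              markers = c("CDH1", "VIM", "RHOA", "JUP"),
                              min_coverage = 0.5, cv_repeats = 0,
                              seed = NULL, out_dir = NULL) {
  manifest <- list(
    version = as.character(utils::packageVersion("emat")),
    seed = seed %||% NA,
    config = list(candidates = candidates, min_coverage = min_coverage,
                  cv_repeats = cv_repeats, markers = markers))
  manifest$hash <- config_hash(manifest$config)
  header <- c(sprintf("emat %s", manifest$version),
              sprintf("seed: %s", manifest$seed),
              sprintf("config hash: %s", manifest$hash))
  res <- list(manifest = manifest)

  # preprocessing chain up to z-scores, then signature restriction
  if (expr_scale(expr) == "raw") expr <- log2_transform(expr)
  if (expr_scale(expr) == "log2") expr <- z_normalize(expr)
  sig_expr <- subset_to_signature(expr, signature, min_coverage = min_coverage)
  message("signature coverage: ",
          sprintf("%.1f%%", 100 * attr(sig_expr, "coverage")))

  sil <- select_n_clusters(sig_expr, candidates = candidates)
  model <- ward_cluster(sig_expr, sil$chosen_K)
  res$silhouette <- sil
  res$clusters <- model

  have_surv <- !is.null(surv)
  if (have_surv) {
    surv <- surv[match(colnames(sig_expr), surv$sample_id), , drop = FALSE]
    model <- assign_cluster_names(model, surv,
                                  horizon = min(120, max(surv$time)))
    res$clusters <- model
  } else {
    message("no survival table supplied; skipping cluster naming and survival stages")
  }
  labels <- cluster_names(model)
  res$labels <- labels

  if (have_surv) {
    res$km <- lapply(split(seq_along(labels), labels), function(idx)
      kaplan_meier(surv[idx, , drop = FALSE]))
    res$logrank <- logrank_test(surv, labels, pairwise = TRUE)
    emat_ord <- data.frame(emat = match(labels, sort(unique(labels))),
                           row.names = names(labels))
    res$cox_univariable <- cox_fit(emat_ord, surv)
    if (!is.null(covariates)) {
      cov_all <- cbind(covariates[names(labels), , drop = FALSE], emat_ord)
      res$cox_multivariable <- cox_fit(cov_all, surv)
    }
  }

  if (!is.null(clinical)) {
    cat_cols <- names(clinical)[vapply(clinical, function(x)
      is.character(x) || is.factor(x), TRUE)]
    res$enrichment <- lapply(
      stats::setNames(cat_cols, cat_cols),
      function(cc) hypergeometric_enrichment(labels,
                                             clinical[names(labels), cc]))
  }

  present <- intersect(markers, rownames(expr))
  if (length(present) > 0L)
    res$markers <- marker_profile(expr, labels, markers = markers)

  if (!is.null(reference))
    res$similarity <- similarity_to_reference(sig_expr, reference)

  if (cv_repeats > 0 && have_surv && !is.null(covariates)) {
    cp <- setdiff(colnames(covariates), c("emat", "pam50", "ihc"))
    sets <- list(feature_set("CP", cp),
                 feature_set("CP+EMAT", cp, includes_emat = TRUE))
    if ("ihc" %in% colnames(covariates))
      sets <- c(sets, list(feature_set("CP+IHC", c(cp, "ihc"))))
    if ("pam50" %in% colnames(covariates))
      sets <- c(sets, list(feature_set("CP+PAM50", c(cp, "pam50"))))
    # candidate must be unique: reorder so CP+EMAT is flagged
    res$cv <- run_cv_comparison(sig_expr, covariates[names(labels), , drop = FALSE],
                                surv, sets, n_repeats = cv_repeats,
                                K = model$K, seed = seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_outputs(res, out_dir, header)
  }
  class(res) <- "emat_pipeline"
  res
}

# write every result table with the manifest header
write_pipeline_outputs <- function(res, out_dir, header) {
  out <- function(name) file.path(out_dir, name)
  write_tsv_report(data.frame(sample_id = names(res$labels),
                              emat = unname(res$labels)),
                   out("cluster_assignments.tsv"), header)
  write_tsv_report(res$silhouette$scores, out("silhouette.tsv"), header)
  if (!is.null(res$logrank)) {
    lr <- res$logrank
    write_tsv_report(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                     out("logrank.tsv"), header)
  }
  if (!is.null(res$cox_multivariable))
    write_tsv_report(res$cox_multivariable$table, out("cox_multivariable.tsv"),
                     header)
  if (!is.null(res$cox_univariable))
    write_tsv_report(res$cox_univariable$table, out("cox_univariable.tsv"),
                     header)
  if (!is.null(res$enrichment)) {
    enr <- do.call(rbind, lapply(names(res$enrichment), function(nm)
      cbind(annotation = nm, res$enrichment[[nm]]$counts,
            p = as.vector(t(res$enrichment[[nm]]$p)))))
    write_tsv_report(enr, out("enrichment.tsv"), header)
  }
  if (!is.null(res$markers))
    write_tsv_report(res$markers, out("markers.tsv"), header)
  if (!is.null(res$similarity))
    write_tsv_report(res$similarity, out("similarity.tsv"), header)
  if (!is.null(res$cv)) {
    write_tsv_report(cbind(repeat_idx = seq_len(nrow(res$cv$cindex)),
                           res$cv$cindex), out("cv_cindex.tsv"), header)
    write_tsv_report(res$cv$comparisons, out("cv_summary.tsv"), header)
  }
  writeLines(c(paste0("# ", header),
               paste0("stages: ", paste(setdiff(names(res), "manifest"),
                                        collapse = ", "))),
             out("manifest.txt"))
  invisible(out_dir)
}

#' @export
print.emat_pipeline <- function(x, ...) {
  cat("emat pipeline run\n")
  cat("  chosen K:", x$clusters$K, "\n")
  cat("  cluster sizes:\n")
  print(table(x$labels))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank p across clusters: %.3g\n", x$logrank$p))
  invisible(x)
}
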