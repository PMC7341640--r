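#' Construct an expression matrix with a scale tag
#'
#' Expression matrices are genes x samples numeric matrices with unique ids
#' on both axes and an explicit scale tag recording where the matrix sits in
#' the `raw -> log2 -> zscore` preprocessing chain.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param scale One of `"raw"`, `"log2"`, `"zscore"`.
#' @return The matrix classed `"emat_expr"` with attribute `scale_tag`.
#' @export
expression_matrix <- function(values, scale = c("raw", "log2", "zscore")) {
  scale <- match.arg(scale)
  check_named_matrix(values, "expression matrix")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop2("missing value for gene '", rownames(values)[bad[1L]],
          "', sample '", colnames(values)[bad[2L]], "'")
  }
  attr(values, "scale_tag") <- scale
  class(values) <- unique(c("emat_expr", class(values)))
  values
}

#' Scale tag of an expression matrix
#' @param m An expression matrix.
#' @return `"raw"`, `"log2"` or `"zscore"`; plain matrices are treated as raw.
#' @export
expr_scale <- function(m) attr(m, "scale_tag") %||% "raw"

# rebuild tag/class after subsetting operations that strip attributes
as_expr <- function(values, scale) {
  attr(values, "scale_tag") <- scale
  class(values) <- unique(c("emat_expr", class(values)))
  values
}

#' Log2-transform a raw expression matrix
#'
#' @param m Raw-scale expression matrix with strictly positive entries.
#' @return The elementwise base-2 logarithm, tagged `"log2"`.
#' @export
log2_transform <- function(m) {
  if (expr_scale(m) != "raw")
    stop2("log2_transform expects a raw-scale matrix; got scale '",
          expr_scale(m), "'")
  check_named_matrix(unclass(m), "expression matrix")
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop2("non-positive value for gene '", rownames(m)[bad[1L, 1L]],
          "', sample '", colnames(m)[bad[1L, 2L]], "'")
  as_expr(log2(unclass(m)), "log2")
}

#' Z-normalize each gene across samples
#'
#' Centers every gene row to mean 0 and scales it to population (divide-by-n)
#' standard deviation 1. Zero-variance rows carry no ranking information and
#' are dropped with a warning.
#'
#' @param m A log2-scale expression matrix with at least 2 samples.
#' @return The row-standardized matrix, tagged `"zscore"`.
#' @export
z_normalize <- function(m) {
  if (!expr_scale(m) %in% c("log2", "zscore"))
    stop2("z_normalize expects a log2-scale matrix; log2_transform raw data first")
  x <- unclass(m)
  check_named_matrix(x, "expression matrix")
  if (ncol(x) < 2L)
    stop2("z-normalization needs at least 2 samples")
  sds <- row_pop_sd(x)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene row(s) dropped: ",
            paste(utils::head(rownames(x)[flat], 5L), collapse = ", "),
            if (sum(flat) > 5L) ", ..." else "", call. = FALSE)
    x <- x[!flat, , drop = FALSE]
    sds <- sds[!flat]
    if (nrow(x) == 0L) stop2("all gene rows have zero variance")
  }
  as_expr((x - rowMeans(x)) / sds, "zscore")
}

#' Restrict an expression matrix to signature genes
#'
#' Rows are reordered to follow the signature's own gene order. The fraction
#' of signature genes found in the matrix is reported in attribute
#' `"coverage"`; when it falls below `min_coverage` the subset is refused,
#' which is the guard used before cross-platform classification.
#'
#' @param m An expression matrix.
#' @param sig A [gene_signature()] (or character vector of gene ids).
#' @param min_coverage Minimum acceptable fraction of signature genes present
#'   in the matrix, in (0, 1]. Default 0.5.
#' @return The row-subset matrix (same scale tag), with attribute
#'   `"coverage"`.
#' @export
subset_to_signature <- function(m, sig, min_coverage = 0.5) {
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1)
    stop2("min_coverage must be in (0, 1]")
  genes <- if (inherits(sig, "emat_signature")) sig$gene else as.character(sig)
  found <- genes[genes %in% rownames(m)]
  coverage <- length(found) / length(genes)
  if (coverage < min_coverage)
    stop2(sprintf(
      "only %.1f%% of signature genes found (%d of %d); need >= %.1f%%",
      100 * coverage, length(found), length(genes), 100 * min_coverage))
  out <- as_expr(unclass(m)[found, , drop = FALSE], expr_scale(m))
  attr(out, "coverage") <- coverage
  out
}

#' Collapse probe-level rows to genes by maximal variance
#'
#' When several probes map to the same gene symbol, the probe with the
#' largest variance across samples is kept as that gene's row.
#'
#' @param values Numeric matrix with probe ids as row names.
#' @param probe_to_gene Named character vector mapping probe id -> gene
#'   symbol; probes absent from the map are dropped.
#' @return Matrix with gene symbols as row names.
#' @export
collapse_probes <- function(values, probe_to_gene) {
  probes <- intersect(rownames(values), names(probe_to_gene))
  if (length(probes) == 0L) stop2("no probes map to genes")
  values <- values[probes, , drop = FALSE]
  genes <- probe_to_gene[probes]
  vars <- apply(values, 1L, stats::var)
  keep <- vapply(split(seq_along(genes), genes),
                 function(idx) idx[which.max(vars[idx])], integer(1))
  message(length(probes) - length(keep), " redundant probe(s) collapsed to ",
          length(keep), " genes by maximal variance")
  out <- values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}
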