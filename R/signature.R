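#' Construct a fold-change table from perturbation experiments
#'
#' A fold-change table holds treated-vs-control expression ratios (linear
#' scale) for a panel of genes across several independent perturbation
#' experiments. Rows are genes, columns are experiments; all ratios must be
#' strictly positive.
#'
#' @param values Numeric matrix of expression ratios with gene ids as row
#'   names and experiment ids as column names.
#' @return The validated matrix, classed `"emat_folds"`.
#' @export
fold_change_table <- function(values) {
  check_named_matrix(values, "fold-change table")
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop2("non-positive or missing ratio for gene '",
          rownames(values)[bad[1L, 1L]], "' in experiment '",
          colnames(values)[bad[1L, 2L]], "'")
  }
  class(values) <- c("emat_folds", class(values))
  values
}

#' Construct a gene signature
#'
#' A gene signature is a set of genes with the motility program each was
#' derived from (`"EMT"`, `"MAT"` or `"both"`) and the direction of regulation
#' observed in the deriving experiments.
#'
#' @param gene Character vector of unique gene symbols.
#' @param direction Per-gene regulation direction, one of `"up"`, `"down"`,
#'   `"mixed"`, `"unknown"`. Recycled if length 1.
#' @param source Per-gene source program (`"EMT"`, `"MAT"`, `"both"`).
#'   Recycled if length 1.
#' @param name Free-text signature name.
#' @return A data frame with columns `gene`, `source`, `direction`, classed
#'   `"emat_signature"`; the signature name is stored in attribute `"name"`.
#' @export
gene_signature <- function(gene, direction = "unknown", source = "both",
                           name = "signature") {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop2("duplicated gene ids in signature: ",
          paste(unique(gene[duplicated(gene)]), collapse = ", "))
  direction <- rep_len(as.character(direction), length(gene))
  source <- rep_len(as.character(source), length(gene))
  if (!all(direction %in% c("up", "down", "mixed", "unknown")))
    stop2("direction must be one of up, down, mixed, unknown")
  out <- data.frame(gene = gene, source = source, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("emat_signature", "data.frame")
  out
}

#' @export
print.emat_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s': %d genes (%s)\n",
              attr(x, "name"), nrow(x),
              paste(sprintf("%s %d", names(table(x$source)), table(x$source)),
                    collapse = ", ")))
  invisible(x)
}

#' Derive a gene signature from perturbation fold changes
#'
#' Implements the threshold-and-count derivation rule: a gene enters the
#' signature when it is up- or downregulated at least `fold_threshold`-fold
#' (ratio \eqn{\ge f} or \eqn{\le 1/f}, inclusive) in at least
#' `min_experiments` experiments relative to control. Up- and down-calls are
#' pooled when counting qualifying experiments.
#'
#' @param folds A [fold_change_table()] (genes x experiments, linear-scale
#'   ratios).
#' @param fold_threshold Fold-change threshold, a ratio >= 1. Default 1.5,
#'   the threshold used to derive the 138-gene MAT list.
#' @param min_experiments Minimum number of qualifying experiments. Default 2.
#' @param source Source tag recorded for every derived gene.
#' @param name Name of the resulting signature.
#' @return A [gene_signature()]. Direction is `"up"` if every qualifying call
#'   is an up-call, `"down"` if every one is a down-call, `"mixed"` otherwise.
#' @export
derive_signature <- function(folds, fold_threshold = 1.5, min_experiments = 2,
                             source = "MAT", name = "derived") {
  if (!inherits(folds, "emat_folds")) folds <- fold_change_table(folds)
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      fold_threshold < 1)
    stop2("fold_threshold must be a single ratio >= 1")
  min_experiments <- as.integer(min_experiments)
  if (min_experiments < 1L)
    stop2("min_experiments must be a positive count")
  if (min_experiments > ncol(folds))
    stop2("min_experiments (", min_experiments,
          ") exceeds the number of experiments (", ncol(folds), ")")
  up <- folds >= fold_threshold
  down <- folds <= 1 / fold_threshold
  n_calls <- rowSums(up | down)
  keep <- which(n_calls >= min_experiments)
  if (length(keep) == 0L)
    return(gene_signature(character(0), character(0), character(0), name))
  has_up <- rowSums(up[keep, , drop = FALSE]) > 0L
  has_down <- rowSums(down[keep, , drop = FALSE]) > 0L
  direction <- ifelse(has_up & has_down, "mixed",
                      ifelse(has_up, "up", "down"))
  gene_signature(rownames(folds)[keep], direction, source, name)
}

#' Combine two gene signatures into their union
#'
#' Genes present in both inputs are retained once with source `"both"`;
#' if the two inputs disagree on direction the combined direction is
#' `"mixed"`.
#'
#' @param a,b [gene_signature()] objects, both non-empty.
#' @param name Name for the combined signature.
#' @return A [gene_signature()] with `|A| + |B| - |A intersect B|` entries.
#' @export
combine_signatures <- function(a, b, name = "combined") {
  if (!inherits(a, "emat_signature") || !inherits(b, "emat_signature"))
    stop2("both inputs must be gene signatures")
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop2("both signatures must be non-empty")
  shared <- intersect(a$gene, b$gene)
  only_a <- a[!a$gene %in% shared, , drop = FALSE]
  only_b <- b[!b$gene %in% shared, , drop = FALSE]
  ia <- match(shared, a$gene)
  ib <- match(shared, b$gene)
  dir_shared <- ifelse(a$direction[ia] == b$direction[ib],
                       a$direction[ia], "mixed")
  gene_signature(
    gene = c(only_a$gene, only_b$gene, shared),
    direction = c(only_a$direction, only_b$direction, dir_shared),
    source = c(only_a$source, only_b$source, rep("both", length(shared))),
    name = name
  )
}

#' Compute fold-change ratios from treated and control replicate matrices
#'
#' Helper for callers holding raw group-level expression instead of
#' precomputed ratios: the ratio for each gene is the mean over treated
#' replicates divided by the mean over control replicates.
#'
#' @param treated,control Numeric matrices (genes x replicates) on a linear
#'   scale, with identical row names.
#' @return Named vector of per-gene ratios.
#' @export
fold_change_from_groups <- function(treated, control) {
  if (!identical(rownames(treated), rownames(control)))
    stop2("treated and control matrices must share the same gene rows")
  tm <- rowMeans(treated)
  cm <- rowMeans(control)
  if (any(cm <= 0) || any(tm <= 0))
    stop2("group means must be strictly positive; found non-positive mean for gene '",
          rownames(treated)[which(tm <= 0 | cm <= 0)[1L]], "'")
  tm / cm
}

#' Read a gene list from two-column tab-separated text
#'
#' Expected layout: `gene_id<TAB>direction` with an optional header line.
#' Direction values outside `up/down/mixed/unknown` (other than a header)
#' are rejected.
#'
#' @param path Path to the file.
#' @param source Source tag to attach to every gene.
#' @param name Signature name; defaults to the file name.
#' @return A [gene_signature()].
#' @export
read_gene_list <- function(path, source = "both",
                           name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop2("gene list file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 1L | ncols > 2L))
    stop2("gene list must have one or two tab-separated columns")
  gene <- vapply(parts, `[`, "", 1L)
  dir <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "unknown", "")
  # drop a header line if the second field is not a direction keyword
  if (!dir[1L] %in% c("up", "down", "mixed", "unknown") ||
      tolower(gene[1L]) %in% c("gene", "gene_id", "symbol")) {
    gene <- gene[-1L]
    dir <- dir[-1L]
  }
  gene_signature(gene, dir, source, name)
}

#' Write a gene list as two-column tab-separated text
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(sig, path) {
  writeLines(c("gene_id\tdirection",
               paste(sig$gene, sig$direction, sep = "\t")), path)
  invisible(path)
}

#' Overlap between two gene signatures
#'
#' Generic utility for comparing a derived signature against an external gene
#' list (e.g. checking how many genes it shares with a proliferation
#' signature).
#'
#' @param a,b [gene_signature()] objects or character vectors of gene ids.
#' @return List with the shared `genes`, counts `n_a`, `n_b`, `n_shared`, and
#'   the Jaccard index of the two gene sets.
#' @export
signature_overlap <- function(a, b) {
  ga <- if (inherits(a, "emat_signature")) a$gene else as.character(a)
  gb <- if (inherits(b, "emat_signature")) b$gene else as.character(b)
  shared <- intersect(ga, gb)
  list(genes = shared, n_a = length(ga), n_b = length(gb),
       n_shared = length(shared),
       jaccard = length(shared) / length(union(ga, gb)))
}
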