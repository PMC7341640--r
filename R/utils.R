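# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# validate a numeric matrix with unique, non-empty dimnames on both axes
check_named_matrix <- function(values, what = "matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop2(what, " must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop2(what, " is empty")
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || is.null(cn) || anyNA(rn) || anyNA(cn) ||
      any(rn == "") || any(cn == ""))
    stop2(what, " must have non-empty row and column names")
  if (anyDuplicated(rn))
    stop2(what, ": duplicated row ids: ",
          paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(cn))
    stop2(what, ": duplicated column ids: ",
          paste(unique(cn[duplicated(cn)]), collapse = ", "))
  invisible(values)
}

# population (divide-by-n) standard deviation, rowwise
row_pop_sd <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowMeans((x - mu)^2))
}

# all permutations of 1..n (n small; used for cluster matching)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# FNV-1a hash of an arbitrary R object, for run manifests
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L)[-(1:14)])
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
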