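#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header line `gene_id<TAB>sample1<TAB>...`, one gene per
#' row. Lines starting with `#` are treated as comments. Duplicate gene or
#' sample ids and non-numeric or missing cells are rejected with the
#' offending coordinates.
#'
#' @param path Path to the TSV file.
#' @param scale Scale tag to attach (`"raw"`, `"log2"`, `"zscore"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2L) stop2("expression TSV needs a gene column plus samples")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop2("duplicated gene id(s): ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad) > 0L)
      stop2("non-numeric or missing value at gene '", genes[bad[1L]],
            "', sample '", samples[j], "'")
    vals[, j] <- num
  }
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip reproduces the matrix exactly.
#'
#' @param m An expression matrix.
#' @param path Output path.
#' @param comments Optional character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, comments = NULL) {
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  lines <- c(if (length(comments)) paste0("# ", comments), header, body)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a survival table
#'
#' @param sample_id Unique sample identifiers.
#' @param time Follow-up time in months, non-negative.
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @param endpoint Endpoint tag: `"DSS"`, `"DMFS"` or `"synthetic"`.
#' @return Data frame with columns `sample_id`, `time`, `event`, classed
#'   `"emat_survival"`, endpoint stored as attribute.
#' @export
survival_table <- function(sample_id, time, event,
                           endpoint = c("synthetic", "DSS", "DMFS")) {
  endpoint <- match.arg(endpoint)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop2("duplicated sample ids in survival table")
  time <- as.numeric(time)
  event <- as.integer(event)
  if (anyNA(time) || any(time < 0)) stop2("survival times must be non-negative")
  if (anyNA(event) || !all(event %in% c(0L, 1L)))
    stop2("event indicator must be 0 or 1")
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop2("sample_id, time and event must have equal length")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("emat_survival", "data.frame")
  out
}

#' Read a survival table from CSV (sample_id, time_months, event)
#' @param path Path to the CSV file.
#' @param endpoint Endpoint tag attached to the table.
#' @return A [survival_table()].
#' @export
read_survival <- function(path, endpoint = "synthetic") {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% colnames(df)))
    stop2("survival CSV must have columns: ", paste(need, collapse = ", "))
  survival_table(df$sample_id, df$time_months, df$event, endpoint = endpoint)
}

#' Write a survival table as CSV
#' @param surv A [survival_table()].
#' @param path Output path.
#' @param comments Optional `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path, comments = NULL) {
  lines <- c(if (length(comments)) paste0("# ", comments),
             "sample_id,time_months,event",
             sprintf("%s,%.17g,%d", surv$sample_id, surv$time, surv$event))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as tab-separated text with comment header
#' @param df Data frame.
#' @param path Output path.
#' @param comments Optional `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
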