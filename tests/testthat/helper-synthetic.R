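# shared fixtures built in code

# well-separated Gaussian blobs: genes x samples matrix plus true labels
make_blobs <- function(n_per = 10, K = 2, n_genes = 20, sep = 10, sd = 1,
                       seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(K), each = n_per)
  centroids <- matrix(0, n_genes, K)
  block <- cut(seq_len(n_genes), K, labels = FALSE)
  for (k in seq_len(K)) centroids[block == k, k] <- sep
  vals <- centroids[, labels] + matrix(rnorm(n_genes * length(labels), 0, sd),
                                       n_genes)
  dimnames(vals) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_along(labels)))
  list(m = vals, labels = stats::setNames(labels, colnames(vals)))
}

# small survival table with explicit values
surv_fixture <- function(time, event, ids = sprintf("p%02d", seq_along(time))) {
  survival_table(ids, time, event)
}

# hypergeometric upper-tail probability from first principles (sum of
# combinatorial terms), independent of stats::phyper
hyper_upper_oracle <- function(N, K, n, k) {
  js <- seq.int(k, min(K, n))
  if (length(js) == 0 || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Harrell's C by exhaustive pair enumeration
cindex_oracle <- function(risk, time, event) {
  conc <- 0; adm <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == event[j]) next
        early <- if (event[i] == 1) i else j
        late <- if (event[i] == 1) j else i
      } else {
        early <- if (time[i] < time[j]) i else j
        late <- if (time[i] < time[j]) j else i
        if (event[early] == 0) next
      }
      adm <- adm + 1
      if (risk[early] > risk[late]) conc <- conc + 1
      else if (risk[early] == risk[late]) conc <- conc + 0.5
    }
  }
  conc / adm
}

# one-sided signed-rank p by enumeration of all 2^n sign assignments
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Ws <- as.matrix(signs) %*% r
  mean(Ws >= W)
}

# Cox partial log-likelihood for a single covariate, no tied event times
cox_pl_oracle <- function(beta, x, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    risk_set <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk_set])))
  }
  s
}
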