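#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` and returns the estimate as a tidy step
#' function: at each observed event time, S(t) is multiplied by
#' `1 - d_i / n_i` with `d_i` events among `n_i` at risk.
#'
#' @param surv A [survival_table()].
#' @return Data frame (`time`, `n_risk`, `n_event`, `n_censor`, `surv`)
#'   classed `"emat_km"` with the underlying `survfit` in attribute `"fit"`.
#' @export
kaplan_meier <- function(surv) {
  if (nrow(surv) < 1L) stop2("survival table is empty")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("emat_km", "data.frame")
  out
}

#' Survival probability at a given time from a Kaplan-Meier estimate
#' @param km An `"emat_km"` object (or [survival_table()], fitted first).
#' @param time Time point(s), months.
#' @return S(t), carried forward from the last event time before `t`.
#' @export
km_survival_at <- function(km, time) {
  if (inherits(km, "emat_survival")) km <- kaplan_meier(km)
  summary(attr(km, "fit"), times = time, extend = TRUE)$surv
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank test; the statistic is referred to a
#' chi-square distribution with `groups - 1` degrees of freedom. With
#' `pairwise = TRUE` every pair of groups is additionally tested on its own
#' risk table.
#'
#' @param surv A [survival_table()].
#' @param groups Per-sample group labels aligned with `surv` rows.
#' @param pairwise Also compute all pairwise two-group tests.
#' @return List classed `"emat_logrank"` with `chisq`, `df`, `p` and,
#'   when requested, a symmetric `pairwise_p` matrix.
#' @export
logrank_test <- function(surv, groups, pairwise = FALSE) {
  groups <- as.character(groups)
  if (length(groups) != nrow(surv))
    stop2("groups must align with survival rows")
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop2("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ factor(groups))
  df <- length(lev) - 1L
  out <- list(chisq = unname(sd$chisq), df = df,
              p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
              observed = sd$obs, expected = sd$exp, groups = lev)
  if (pairwise) {
    pm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_along(lev)[-length(lev)]) {
      for (j in (i + 1L):length(lev)) {
        sel <- groups %in% lev[c(i, j)]
        sub <- survival::survdiff(
          survival::Surv(surv$time[sel], surv$event[sel]) ~ factor(groups[sel]))
        pm[i, j] <- pm[j, i] <- stats::pchisq(sub$chisq, 1L, lower.tail = FALSE)
      }
    }
    out$pairwise_p <- pm
  }
  class(out) <- "emat_logrank"
  out
}

#' @export
print.emat_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Encode clinical covariates with the ordinal scheme used for Cox models
#'
#' Multi-level subtype variables are coded as single ordinal covariates
#' (one hazard ratio per variable): tumor size `<2 / 2-5 / >5` cm as 1/2/3,
#' grade low/intermediate/high as 1/2/3, joint ER-HER2 immunohistochemistry
#' status `ER+HER2- / ER+HER2+ / ER-HER2+ / ER-HER2-` as 1/2/3/4, PAM50
#' normal-like/LumA/LumB/HER2/basal as 0/1/2/3/4, and EMAT1..EMATK as 1..K.
#' Treatment columns become 0/1 flags. Unknown levels map to `NA` and are
#' excluded listwise at model time.
#'
#' @param clinical Data frame with any of the columns `age`, `size_class`
#'   (`"<2"`, `"2-5"`, `">5"`), `grade` (`"low"`, `"intermediate"`,
#'   `"high"`), `er`, `her2` (`"positive"`/`"negative"`), `pam50`
#'   (`"normal-like"`, `"luminal A"`, `"luminal B"`, `"HER2"`, `"basal"`),
#'   `emat` (`"EMAT1"`...), `chemo`, `hormonal`, `radiation` (logical/0-1).
#' @return Data frame of numeric covariates (same rownames), classed
#'   `"emat_covariates"`.
#' @export
encode_covariates <- function(clinical) {
  out <- data.frame(row.names = rownames(clinical))
  code <- function(x, map) unname(map[as.character(x)])
  if (!is.null(clinical$age)) out$age <- as.numeric(clinical$age)
  if (!is.null(clinical$size_class))
    out$size <- code(clinical$size_class, c("<2" = 1, "2-5" = 2, ">5" = 3))
  if (!is.null(clinical$grade))
    out$grade <- code(clinical$grade,
                      c(low = 1, intermediate = 2, high = 3))
  if (!is.null(clinical$er) && !is.null(clinical$her2)) {
    key <- paste(clinical$er, clinical$her2, sep = "/")
    out$ihc <- code(key, c("positive/negative" = 1, "positive/positive" = 2,
                           "negative/positive" = 3, "negative/negative" = 4))
  }
  if (!is.null(clinical$pam50))
    out$pam50 <- code(clinical$pam50,
                      c("normal-like" = 0, "luminal A" = 1, "luminal B" = 2,
                        "HER2" = 3, "basal" = 4))
  if (!is.null(clinical$emat)) {
    k <- suppressWarnings(as.integer(sub("^EMAT", "", clinical$emat)))
    out$emat <- k
  }
  for (flag in c("chemo", "hormonal", "radiation")) {
    if (!is.null(clinical[[flag]]))
      out[[flag]] <- as.integer(as.logical(clinical[[flag]]))
  }
  class(out) <- c("emat_covariates", "data.frame")
  out
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by partial-likelihood maximization with Efron tie
#' handling (`survival::coxph`). Rows with any missing covariate are
#' excluded listwise; a warning is raised when fewer than 10 complete rows
#' per covariate remain.
#'
#' @param covariates Data frame of numeric covariates; rows aligned with
#'   `surv` (matched by rownames when present, else by position).
#' @param surv A [survival_table()].
#' @param truncate_months Optional administrative censoring horizon (e.g.
#'   120 for 10-year analyses): follow-up beyond it is censored at the
#'   horizon.
#' @return List classed `"emat_cox"`: `table` (per-covariate `coef`, `hr`,
#'   `hr_lo`, `hr_hi`, `p`), `lrt_p` (model likelihood-ratio p), `n`,
#'   `n_events` and the underlying `fit`.
#' @export
cox_fit <- function(covariates, surv, truncate_months = NULL) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1L) stop2("at least one covariate is required")
  if (nrow(covariates) != nrow(surv))
    stop2("covariates and survival table must have the same rows")
  time <- surv$time
  event <- surv$event
  if (!is.null(truncate_months)) {
    event[time > truncate_months] <- 0L
    time <- pmin(time, truncate_months)
  }
  complete <- stats::complete.cases(covariates)
  n <- sum(complete)
  if (n < 10L * ncol(covariates))
    warning("only ", n, " complete rows for ", ncol(covariates),
            " covariate(s); estimates may be unstable", call. = FALSE)
  if (sum(event[complete]) < 1L) stop2("no events among complete rows")
  dat <- cbind(covariates[complete, , drop = FALSE],
               .time = time[complete], .event = event[complete])
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = dat, ties = "efron"),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Ran out of iterations", msg))
        stop2("Cox fit did not converge: ", msg)
      if (grepl("infinite|Loglik converged before", msg)) {
        separation <<- TRUE
        warning("possible complete separation: ", msg, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    hr_lo = s$conf.int[, "lower .95"],
                    hr_hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab,
                 lrt_p = unname(stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]),
                                              df = length(stats::coef(fit)),
                                              lower.tail = FALSE)),
                 n = n, n_events = sum(event[complete]),
                 separation = separation, fit = fit),
            class = "emat_cox")
}

#' @export
print.emat_cox <- function(x, ...) {
  cat(sprintf("Cox model: n = %d, events = %d, LRT p = %.3g\n",
              x$n, x$n_events, x$lrt_p))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Univariable Cox fits, one covariate at a time
#'
#' @param covariates Data frame of numeric covariates.
#' @param surv A [survival_table()].
#' @param truncate_months Optional follow-up truncation (see [cox_fit()]).
#' @return Data frame with one row per covariate (`term`, `coef`, `hr`,
#'   `hr_lo`, `hr_hi`, `p`, `n`).
#' @export
cox_univariable <- function(covariates, surv, truncate_months = NULL) {
  rows <- lapply(colnames(covariates), function(v) {
    f <- cox_fit(covariates[, v, drop = FALSE], surv, truncate_months)
    cbind(f$table, n = f$n)
  })
  do.call(rbind, rows)
}

#' Harrell's concordance index
#'
#' Fraction of admissible sample pairs whose predicted risk ordering agrees
#' with the observed survival ordering. A pair is admissible when the
#' earlier of the two times is an event (so the ordering is determinable
#' under right censoring); equal times are admissible only when exactly one
#' of the two is an event. Higher risk predicting the earlier event counts
#' as concordant; tied risk scores contribute 0.5.
#'
#' @param risk_scores Numeric risk scores aligned with `surv` rows (larger =
#'   predicted earlier event; e.g. a Cox linear predictor).
#' @param surv A [survival_table()].
#' @return C in `[0, 1]`; the number of admissible pairs is attached as
#'   attribute `"n_pairs"`.
#' @export
concordance_index <- function(risk_scores, surv) {
  r <- as.numeric(risk_scores)
  if (length(r) != nrow(surv))
    stop2("risk scores must align with survival rows")
  t <- surv$time; e <- surv$event
  conc <- 0; adm <- 0
  for (i in which(e == 1L)) {
    # subjects known to outlive i: later times, or same time but censored
    later <- (t > t[i]) | (t == t[i] & e == 0L)
    adm <- adm + sum(later)
    conc <- conc + sum(r[i] > r[later]) + 0.5 * sum(r[i] == r[later])
  }
  if (adm == 0) stop2("no admissible pairs under the censoring pattern")
  structure(conc / adm, n_pairs = adm)
}
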