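#' Univariate Cox proportional hazards fit for one parameter
#'
#' Partial-likelihood fit (Efron ties) with Wald confidence interval and
#' p-value.
#'
#' @param x Numeric covariate values.
#' @param time Follow-up times (> 0, years).
#' @param event Event indicator (logical or 0/1).
#' @param name Parameter name carried into the result.
#' @return One-row data.frame: `parameter`, `coef`, `hr`, `lo`, `hi`, `p`.
#' @export
cox_univariate <- function(x, time, event, name = "x") {
  event <- as.integer(event)
  if (sum(event) < 1) stop("no events: Cox model cannot be fit")
  if (any(time <= 0)) stop("follow-up times must be positive")
  d <- data.frame(x = x, time = time, event = event)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  sm <- summary(fit)
  data.frame(parameter = name,
             coef = unname(stats::coef(fit)),
             hr = unname(exp(stats::coef(fit))),
             lo = sm$conf.int[1, "lower .95"],
             hi = sm$conf.int[1, "upper .95"],
             p = sm$coefficients[1, "Pr(>|z|)"],
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen across parameters with FDR adjustment
#'
#' @param cohort Analysis table.
#' @param parameters Parameter column names (defaults to the 19 statistical
#'   metrics plus PC1--PC4 when present).
#' @param time_col,event_col Names of the time and event columns.
#' @return Data frame of [cox_univariate] rows plus `p_adj` (BH).
#' @export
cox_univariate_screen <- function(cohort, parameters = NULL,
                                  time_col = "os_time",
                                  event_col = "os_event") {
  if (is.null(parameters)) {
    parameters <- intersect(c(metric_names(statistical = TRUE),
                              paste0("PC", 1:4)), names(cohort))
  }
  keep <- !is.na(cohort[[time_col]]) & !is.na(cohort[[event_col]])
  cohort <- cohort[keep, , drop = FALSE]
  res <- do.call(rbind, lapply(parameters, function(pn) {
    cox_univariate(cohort[[pn]], cohort[[time_col]], cohort[[event_col]],
                   name = pn)
  }))
  res$p_adj <- fdr_adjust(res$p)
  rownames(res) <- NULL
  res
}

cox_bic <- function(fit, n) {
  p <- length(stats::coef(fit))
  ll <- fit$loglik[length(fit$loglik)]
  -2 * ll + p * log(n)
}

#' Backward stepwise Cox elimination by BIC
#'
#' Starting from the full candidate model, repeatedly drops the covariate
#' whose removal most decreases the BIC, until no removal decreases it.
#'
#' @param cohort Analysis table containing the candidates.
#' @param candidates Character vector of covariate names (e.g. PC3, sex,
#'   V1.2/Peak2).
#' @param time_col,event_col Names of the time and event columns.
#' @return List with `retained` (names, possibly empty), `fit` (coxph or
#'   NULL for the empty model), `summary` ([cox_univariate]-style rows for
#'   retained covariates), `bic_trace`.
#' @export
cox_backward_bic <- function(cohort, candidates, time_col = "os_time",
                             event_col = "os_event") {
  keep <- !is.na(cohort[[time_col]]) & !is.na(cohort[[event_col]])
  d <- cohort[keep, , drop = FALSE]
  d$.time <- d[[time_col]]
  d$.event <- as.integer(d[[event_col]])
  if (sum(d$.event) < 1) stop("no events: Cox model cannot be fit")
  n <- nrow(d)
  fit_set <- function(vars) {
    if (!length(vars)) return(NULL)
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(sprintf("`%s`", vars), collapse = " + ")))
    survival::coxph(fml, data = d, ties = "efron")
  }
  bic_of <- function(vars) {
    if (!length(vars)) {
      null_fit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = d)
      return(-2 * null_fit$loglik[1])
    }
    cox_bic(fit_set(vars), n)
  }
  vars <- candidates
  trace <- data.frame(model = paste(vars, collapse = "+"), bic = bic_of(vars))
  repeat {
    if (!length(vars)) break
    current <- bic_of(vars)
    drops <- vapply(seq_along(vars), function(i) bic_of(vars[-i]), numeric(1))
    if (min(drops) < current) {
      i <- which.min(drops)
      vars <- vars[-i]
      trace <- rbind(trace, data.frame(model = paste(vars, collapse = "+"),
                                       bic = min(drops)))
    } else break
  }
  fit <- fit_set(vars)
  summary_rows <- if (!is.null(fit)) {
    sm <- summary(fit)
    data.frame(parameter = vars,
               coef = unname(stats::coef(fit)),
               hr = unname(exp(stats::coef(fit))),
               lo = sm$conf.int[, "lower .95"],
               hi = sm$conf.int[, "upper .95"],
               p = sm$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(parameter = character(0), coef = numeric(0), hr = numeric(0),
               lo = numeric(0), hi = numeric(0), p = numeric(0))
  }
  list(retained = vars, fit = fit, summary = summary_rows, bic_trace = trace)
}

#' Format a Cox result row for reporting
#'
#' Prints the hazard ratio to two decimals with its 95% interval in the
#' conventional `HR (lo-hi)` layout.
#'
#' @param row One-row data.frame with `hr`, `lo`, `hi` (e.g. from
#'   [cox_univariate]).
#' @return Character scalar, e.g. `"1.74 (1.17-2.58)"`.
#' @export
format_cox_result <- function(row) {
  sprintf("%.2f (%.2f-%.2f)", row$hr, row$lo, row$hi)
}

#' Kaplan-Meier comparison after a median split
#'
#' Dichotomizes the cohort at the median of a parameter (values at the
#' median go to the lower arm), estimates product-limit curves per arm and
#' compares them with the Mantel-Cox (log-rank) test.
#'
#' @param x Numeric parameter values.
#' @param time,event Follow-up times and event indicators.
#' @return List with `group` (factor `<=median` / `>median`), `fit`
#'   (survfit), `chisq`, `p`, `median_value`.
#' @export
km_median_split <- function(x, time, event) {
  med <- stats::median(x)
  group <- factor(ifelse(x > med, ">median", "<=median"),
                  levels = c("<=median", ">median"))
  if (any(table(group) < 2)) {
    stop("cannot split at the median: fewer than 2 samples on one side")
  }
  d <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  list(group = group, fit = fit, chisq = unname(lr$chisq), p = p,
       median_value = med)
}

#' Restricted mean survival time for one group
#'
#' Area under the Kaplan-Meier curve up to the truncation time `tau`, with
#' the Greenwood plug-in estimator for the asymptotic variance.
#'
#' @param time,event Follow-up times and event indicators.
#' @param tau Truncation time (years). Clipped with a warning when it
#'   exceeds the last observed time.
#' @return Named numeric: `rmst`, `se`, `lo`, `hi`, `tau`.
#' @export
rmst_one <- function(time, event, tau = 8) {
  event <- as.integer(event)
  if (tau > max(time)) {
    warning(sprintf("tau = %g beyond last observed time %g; clipping",
                    tau, max(time)))
    tau <- max(time)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- fit$time; ss <- fit$surv; nn <- fit$n.risk; dd <- fit$n.event
  keep <- tt <= tau + 1e-12
  tt <- tt[keep]; ss <- ss[keep]; nn <- nn[keep]; dd <- dd[keep]
  # step-function area: S jumps at event times, S = 1 before the first
  t_grid <- c(0, tt, tau)
  s_grid <- c(1, ss)
  rmst <- sum(s_grid * diff(t_grid))
  # Greenwood plug-in: var = sum over event times of A_i^2 d_i / (n_i (n_i - d_i))
  ev <- which(dd > 0)
  v <- 0
  for (i in ev) {
    # area under the curve from t_i to tau
    gi <- t_grid >= tt[i] - 1e-12
    a_i <- sum((s_grid * diff(t_grid))[gi[-length(gi)]])
    denom <- nn[i] * (nn[i] - dd[i])
    if (denom > 0) v <- v + a_i^2 * dd[i] / denom
  }
  se <- sqrt(v)
  c(rmst = rmst, se = se, lo = rmst - 1.96 * se, hi = rmst + 1.96 * se,
    tau = tau)
}

#' Compare restricted mean survival between two groups
#'
#' @param group Two-level factor (or coercible).
#' @param time,event Follow-up times and event indicators.
#' @param tau Truncation time (default 8 years).
#' @return An `rmst_result` list: `tau`, `by_group` (per-group rmst/CI),
#'   `difference`, `lo`, `hi`, `p` (normal-theory two-sided).
#' @export
rmst_compare <- function(group, time, event, tau = 8) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("rmst_compare needs exactly two groups")
  parts <- lapply(levels(group), function(g) {
    sel <- group == g
    rmst_one(time[sel], event[sel], tau = tau)
  })
  names(parts) <- levels(group)
  by_group <- do.call(rbind, parts)
  diff <- parts[[1]]["rmst"] - parts[[2]]["rmst"]
  se <- sqrt(parts[[1]]["se"]^2 + parts[[2]]["se"]^2)
  z <- diff / se
  structure(list(
    tau = tau,
    by_group = data.frame(group = levels(group), by_group, row.names = NULL),
    difference = unname(diff),
    lo = unname(diff - 1.96 * se),
    hi = unname(diff + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(z)))
  ), class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("<rmst_result: tau = %g y; difference %.2f y (%.2f-%.2f), p = %.3g>\n",
              x$tau, x$difference, x$lo, x$hi, x$p))
  invisible(x)
}

#' Progression-free survival screen for the NED group
#'
#' Applies the univariate Cox screen (with FDR adjustment) to NED patients
#' with PFS data; the time origin is sample collection.
#'
#' @param cohort Analysis table with `status`, `pfs_time`, `pfs_event`.
#' @param parameters Parameter columns, as in [cox_univariate_screen].
#' @return Data frame of univariate Cox rows with `p_adj`.
#' @export
pfs_analysis <- function(cohort, parameters = NULL) {
  ned <- cohort[cohort$status == "NED" & !is.na(cohort$pfs_time) &
                  !is.na(cohort$pfs_event), , drop = FALSE]
  if (sum(ned$pfs_event) < 1) stop("no PFS events among NED patients")
  cox_univariate_screen(ned, parameters, time_col = "pfs_time",
                        event_col = "pfs_event")
}
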