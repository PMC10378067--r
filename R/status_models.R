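#' Partial-F model reduction for one parameter
#'
#' Starts from the status x sex interaction model and reduces by partial
#' F-tests: the interaction is retained iff its partial-F p-value is below
#' `alpha` against the main-effects model; otherwise sex is retained iff its
#' partial-F p-value is below `alpha` against the status-only model.
#' When any status x sex cell has fewer than two observations the
#' interaction step is skipped with a warning.
#'
#' @param data Data frame with columns `response`, `status`, `sex`.
#' @param alpha Partial-F threshold (default 0.05).
#' @return One of `"interaction"`, `"main-effects"`, `"status-only"`.
#' @export
partial_f_reduce <- function(data, alpha = 0.05) {
  data <- droplevels(data)
  fit_main <- stats::lm(response ~ status + sex, data = data)
  cells <- table(data$status, data$sex)
  if (all(cells >= 2)) {
    fit_int <- stats::lm(response ~ status * sex, data = data)
    p_int <- stats::anova(fit_main, fit_int)[2, "Pr(>F)"]
    if (!is.na(p_int) && p_int < alpha) return("interaction")
  } else {
    warning("status x sex cell with < 2 observations; interaction model skipped")
  }
  fit_status <- stats::lm(response ~ status, data = data)
  p_sex <- stats::anova(fit_status, fit_main)[2, "Pr(>F)"]
  if (!is.na(p_sex) && p_sex < alpha) "main-effects" else "status-only"
}

status_formula <- function(form) {
  switch(form,
         "interaction" = response ~ status * sex,
         "main-effects" = response ~ status + sex,
         "status-only" = response ~ status,
         stop("unknown model form: ", form))
}

#' Automated residual diagnostics
#'
#' Programmatic proxies for visual Q-Q and residual-vs-fitted inspection: a
#' Shapiro-Wilk test on the residuals and a Breusch-Pagan test for
#' heteroscedasticity. The fit passes when both p-values are at least
#' `alpha`. An exact (zero-residual) fit is degenerate and is flagged as a
#' pass with a note. Diagnostic plots can be written with
#' [plot_status_diagnostics].
#'
#' @param fit A fitted `lm`.
#' @param alpha Diagnostic significance level (default 0.05).
#' @return List with `normality_p`, `heteroscedasticity_p`, `pass`, `note`.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  r <- stats::residuals(fit)
  if (stats::sd(r) < 1e-12) {
    return(list(normality_p = NA_real_, heteroscedasticity_p = NA_real_,
                pass = TRUE, note = "degenerate: exact fit (zero residuals)"))
  }
  norm_p <- tryCatch(stats::shapiro.test(r)$p.value, error = function(e) NA_real_)
  het_p <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
  pass <- isTRUE(norm_p >= alpha) && isTRUE(het_p >= alpha)
  list(normality_p = unname(norm_p), heteroscedasticity_p = unname(het_p),
       pass = pass, note = NA_character_)
}

#' Write Q-Q and residual-vs-fitted plots for a fit
#'
#' @param fit A fitted `lm` or `rq`.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_status_diagnostics <- function(fit, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  r <- stats::residuals(fit)
  stats::qqnorm(r); stats::qqline(r)
  graphics::plot(stats::fitted(fit), r, xlab = "fitted", ylab = "residual",
                 main = "Residuals vs fitted")
  graphics::abline(h = 0, lty = 2)
  invisible(path)
}

rq_overall_p <- function(fit, data) {
  # Wald chi-square that all non-intercept coefficients are zero, using the
  # asymptotic (non-iid, "nid") covariance -- equivalent to comparison
  # against the intercept-only median fit in the Wald metric.
  b <- stats::coef(fit)
  keep <- setdiff(names(b), "(Intercept)")
  if (!length(keep)) return(1)
  sm <- tryCatch(suppressWarnings(summary(fit, se = "nid", covariance = TRUE)),
                 error = function(e) NULL)
  if (is.null(sm) || is.null(sm$cov)) return(NA_real_)
  V <- sm$cov
  rownames(V) <- colnames(V) <- names(b)
  bb <- b[keep]
  stat <- tryCatch(drop(t(bb) %*% solve(V[keep, keep, drop = FALSE], bb)),
                   error = function(e) NA_real_)
  if (!is.finite(stat)) return(NA_real_)
  stats::pchisq(stat, df = length(keep), lower.tail = FALSE)
}

#' Fit the status model for one parameter
#'
#' Chooses the model form by [partial_f_reduce], fits it by least squares,
#' and tests overall significance against the intercept-only model. When the
#' residual diagnostics fail, the same form is refit as a median (tau = 0.5)
#' quantile regression via [quantreg::rq] with Wald inference from
#' asymptotic standard errors.
#'
#' @param data Data frame with `response`, `status`, `sex`.
#' @param parameter Name attached to errors and results.
#' @param alpha Partial-F / diagnostic threshold.
#' @return A `status_model_result` list: `parameter`, `form`, `engine`,
#'   `fit`, `overall_p`, `diagnostics`, `data`.
#' @export
fit_status_model <- function(data, parameter = "parameter", alpha = 0.05) {
  if (stats::sd(data$response) < 1e-12) {
    # constant response: no model-vs-intercept evidence by definition
    fit <- stats::lm(response ~ 1, data = data)
    return(structure(list(parameter = parameter, form = "status-only",
                          engine = "least-squares", fit = fit, overall_p = 1,
                          diagnostics = residual_diagnostics(fit), data = data),
                     class = "status_model_result"))
  }
  form <- partial_f_reduce(data, alpha = alpha)
  fml <- status_formula(form)
  fit <- tryCatch(stats::lm(fml, data = data), error = function(e) {
    stop("parameter ", parameter, ": ", conditionMessage(e))
  })
  if (any(is.na(stats::coef(fit)))) {
    stop("parameter ", parameter, ": singular design for form '", form, "'")
  }
  diag <- residual_diagnostics(fit, alpha = alpha)
  engine <- "least-squares"
  if (!diag$pass) {
    engine <- "median-regression"
    fit <- suppressWarnings(quantreg::rq(fml, tau = 0.5, data = data))
    overall_p <- rq_overall_p(fit, data)
  } else {
    fs <- summary(fit)$fstatistic
    overall_p <- if (is.null(fs) || !is.finite(fs[1])) 1 else
      unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(list(parameter = parameter, form = form, engine = engine,
                 fit = fit, overall_p = overall_p, diagnostics = diag,
                 data = data),
            class = "status_model_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")` with input
#' validation; shared by the status stage and the univariate Cox screen.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values (monotone step-up, capped at 1).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tukey-adjusted pairwise status contrasts
#'
#' Estimated marginal means per status group (equal weighting over sex for
#' main-effects models; within sex when the interaction is retained), with
#' all three pairwise differences and the studentized-range (Tukey)
#' adjustment.
#'
#' @param result A `status_model_result`.
#' @return Data frame: `contrast`, optionally `sex`, `estimate`, `SE`,
#'   `p_tukey`.
#' @export
pairwise_emmeans <- function(result) {
  by_sex <- identical(result$form, "interaction")
  spec <- if (by_sex) ~ status | sex else ~ status
  em <- emmeans::emmeans(result$fit, spec, data = result$data)
  prs <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  out <- as.data.frame(prs)
  keep <- intersect(c("contrast", "sex", "estimate", "SE", "p.value"), names(out))
  out <- out[keep]
  names(out)[names(out) == "p.value"] <- "p_tukey"
  out
}

#' Run the status linear-model stage across all parameters
#'
#' Fits each parameter's status model, FDR-adjusts the overall p-values
#' across parameters, and computes Tukey-adjusted pairwise contrasts for
#' parameters whose adjusted p-value is below `fdr_alpha`.
#'
#' @param cohort Analysis table with `status`, `sex` and one column per
#'   parameter.
#' @param parameters Character vector of parameter column names (defaults to
#'   the 19 statistical metrics plus PC1--PC4 when present).
#' @param alpha Partial-F / diagnostic threshold.
#' @param fdr_alpha Adjusted-p threshold for reporting contrasts.
#' @return List with `summary` (one row per parameter: form, engine,
#'   diagnostics, overall and adjusted p), `contrasts` (per-contrast rows)
#'   and `models` (the fitted `status_model_result`s).
#' @export
fit_all_status_models <- function(cohort, parameters = NULL, alpha = 0.05,
                                  fdr_alpha = 0.05) {
  if (is.null(parameters)) {
    parameters <- intersect(c(metric_names(statistical = TRUE),
                              paste0("PC", 1:4)), names(cohort))
  }
  models <- lapply(parameters, function(pn) {
    d <- data.frame(response = cohort[[pn]], status = cohort$status,
                    sex = cohort$sex)
    fit_status_model(d, parameter = pn, alpha = alpha)
  })
  names(models) <- parameters
  summary_df <- do.call(rbind, lapply(models, function(m) {
    data.frame(parameter = m$parameter, form = m$form, engine = m$engine,
               normality_p = m$diagnostics$normality_p,
               heteroscedasticity_p = m$diagnostics$heteroscedasticity_p,
               overall_p = m$overall_p, stringsAsFactors = FALSE)
  }))
  summary_df$overall_p_adj <- fdr_adjust(summary_df$overall_p)
  rownames(summary_df) <- NULL
  contrasts <- list()
  for (i in seq_along(models)) {
    if (isTRUE(summary_df$overall_p_adj[i] < fdr_alpha)) {
      cc <- tryCatch(pairwise_emmeans(models[[i]]), error = function(e) NULL)
      if (!is.null(cc)) {
        cc <- cbind(parameter = summary_df$parameter[i], cc)
        contrasts[[length(contrasts) + 1]] <- cc
      }
    }
  }
  contrasts <- if (length(contrasts)) {
    base <- Reduce(function(a, b) {
      for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
      for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
      rbind(a, b[names(a)])
    }, contrasts)
    base
  } else {
    data.frame(parameter = character(0), contrast = character(0),
               estimate = numeric(0), SE = numeric(0), p_tukey = numeric(0))
  }
  list(summary = summary_df, contrasts = contrasts, models = models)
}
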