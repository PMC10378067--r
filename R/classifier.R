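#' Variance-inflation-factor predictor reduction
#'
#' Iteratively drops the predictor with the highest VIF (1 / (1 - R^2) of
#' that predictor regressed on the others) until every VIF is at most
#' `threshold`. Deterministic: ties and perfect collinearity drop the later
#' column.
#'
#' @param design Data frame or matrix of numeric candidate predictors
#'   (>= 2 columns, no constant columns).
#' @param threshold Maximum admissible VIF (default 5, i.e. at most 80%
#'   multicollinearity).
#' @return Character vector of retained predictor names.
#' @export
vif_reduce <- function(design, threshold = 5) {
  X <- as.data.frame(design)
  if (ncol(X) < 2) stop("VIF reduction needs at least two predictors")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant predictor column(s): ",
                          paste(names(X)[sds == 0], collapse = ", "))
  vif_one <- function(j, d) {
    # lm warns about "essentially perfect fit" on duplicated columns; the
    # collinearity warning below is the informative one
    r2 <- suppressWarnings(summary(stats::lm(d[[j]] ~ ., data = d[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) {
      warning("predictor '", names(d)[j], "' is perfectly collinear")
      return(Inf)
    }
    1 / (1 - r2)
  }
  repeat {
    if (ncol(X) < 2) break
    v <- vapply(seq_along(X), vif_one, numeric(1), d = X)
    if (all(v <= threshold)) break
    # ties / Inf: drop the LATER column among maxima
    worst <- max(which(v == max(v)))
    X <- X[-worst]
  }
  names(X)
}

#' Stepwise logistic model selection
#'
#' Greedy forward or backward stepwise selection of a binomial GLM by AIC
#' or BIC: a step is accepted only when the criterion strictly decreases
#' (ties keep the smaller model). If the selected model shows complete
#' separation (diverging coefficients), it is refit with a small ridge
#' penalty and a warning.
#'
#' @param data Data frame containing the response and candidates.
#' @param response Name of the binary (0/1 or two-level factor) response.
#' @param candidates Character vector of candidate predictor names,
#'   typically demographics plus the [vif_reduce]d thermogram parameters.
#' @param direction `"forward"` or `"backward"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return A `logistic_model` list: `fit` (glm), `predictors`,
#'   `coefficients`, `se`, `criterion`, `direction`.
#' @export
stepwise_select <- function(data, response, candidates,
                            direction = c("forward", "backward"),
                            criterion = c("AIC", "BIC")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  y <- data[[response]]
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  if (length(unique(y)) != 2) stop("response must be binary")
  d <- data[candidates]
  d$.y <- y
  k <- if (criterion == "AIC") 2 else log(nrow(d))
  upper <- stats::as.formula(paste(".y ~", paste(candidates, collapse = " + ")))
  start <- if (direction == "forward") {
    stats::glm(.y ~ 1, family = stats::binomial(), data = d)
  } else {
    stats::glm(upper, family = stats::binomial(), data = d)
  }
  fit <- suppressWarnings(
    stats::step(start, scope = list(lower = ~1, upper = upper),
                direction = direction, k = k, trace = 0)
  )
  if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
      !fit$converged) {
    warning("possible separation in selected logistic model; ",
            "refitting with a small ridge penalty")
    fit <- ridge_logistic_refit(fit, d)
  }
  as_logistic_model(fit, criterion, direction)
}

ridge_logistic_refit <- function(fit, d, lambda = 1e-2) {
  X <- stats::model.matrix(fit)
  y <- fit$y
  p <- ncol(X)
  # one Newton solve of the ridge-penalized logistic score (penalty spares
  # the intercept); adequate as a stabilizing fallback
  b <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (i in 1:50) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  fit$coefficients[] <- b
  fit$ridge <- lambda
  fit
}

as_logistic_model <- function(fit, criterion = NA, direction = NA) {
  sm <- summary(fit)$coefficients
  structure(list(
    fit = fit,
    predictors = setdiff(names(stats::coef(fit)), "(Intercept)"),
    coefficients = stats::coef(fit),
    se = sm[, "Std. Error"],
    criterion = criterion,
    direction = direction
  ), class = "logistic_model")
}

#' The four candidate classifier specifications
#'
#' Candidate models for NED vs active classification: (1) age; (2) age +
#' TPeak2; (3) TPeak2 only; (4) age + Width + TPeak1 + TPeak2 + Peak2.3 +
#' PC4.
#'
#' @return Named list of right-hand-side character vectors.
#' @export
classifier_model_specs <- function() {
  list(
    model1 = "age",
    model2 = c("age", "TPeak2"),
    model3 = "TPeak2",
    model4 = c("age", "Width", "TPeak1", "TPeak2", "Peak2.3", "PC4")
  )
}

#' Stratified fold assignment
#'
#' Class-stratified k-fold partition via [caret::createFolds], so each fold
#' carries both classes in near-original proportion.
#'
#' @param y Binary factor/vector of class labels.
#' @param k Number of folds.
#' @return List of test-index vectors, one per fold.
#' @export
make_stratified_folds <- function(y, k = 5) {
  caret::createFolds(factor(y), k = k, list = TRUE, returnTrain = FALSE)
}

#' Repeated stratified cross-validated classifier performance
#'
#' For each of `repeats` repetitions a fresh stratified `folds`-fold
#' partition is drawn (seed schedule: `seed + repeat index`, recorded in
#' the report); the logistic model is refit on each training split and
#' scored on the held-out fold by ROC-AUC. Confusion metrics use a 0.5
#' probability threshold on the pooled held-out predictions of each
#' repetition. If a training fold degenerates to one class the repetition
#' is re-randomized with a shifted seed and the event is logged.
#'
#' @param data Data frame with the response and predictors.
#' @param response Name of the binary response column (second factor level
#'   or value 1 = positive class).
#' @param predictors Character vector of predictor names.
#' @param repeats,folds Cross-validation schedule (defaults 25 x 5).
#' @param seed Base integer seed.
#' @return A `cv_report` list: `auc` (repeats x folds matrix), `mean_auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `roc_band` (mean and 2.5/97.5 percentile sensitivity on a specificity
#'   grid), `seeds`, `relabelled_repeats`.
#' @export
cross_validate <- function(data, response, predictors, repeats = 25,
                           folds = 5, seed = 1) {
  y <- data[[response]]
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  if (length(unique(y)) != 2) stop("both classes must be present")
  d <- data[predictors]
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  auc_mat <- matrix(NA_real_, repeats, folds)
  acc <- sens <- spec <- numeric(repeats)
  spec_grid <- seq(0, 1, by = 0.02)
  sens_curves <- matrix(NA_real_, repeats, length(spec_grid))
  seeds <- seed + seq_len(repeats)
  redraws <- integer(0)
  for (r in seq_len(repeats)) {
    attempt <- 0
    repeat {
      fold_sets <- withr::with_seed(seeds[r] + 1000L * attempt,
                                    make_stratified_folds(y, k = folds))
      ok <- all(vapply(fold_sets, function(idx) {
        length(unique(y[-idx])) == 2 && length(unique(y[idx])) == 2
      }, logical(1)))
      if (ok) break
      attempt <- attempt + 1
      if (attempt == 1) redraws <- c(redraws, r)
      if (attempt > 25) stop("could not build stratified folds with both classes")
    }
    prob <- rep(NA_real_, nrow(d))
    for (f in seq_along(fold_sets)) {
      idx <- fold_sets[[f]]
      fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                         data = d[-idx, , drop = FALSE]))
      prob[idx] <- stats::predict(fit, newdata = d[idx, , drop = FALSE],
                                  type = "response")
      auc_mat[r, f] <- as.numeric(pROC::auc(
        pROC::roc(y[idx], prob[idx], levels = c(0, 1),
                  direction = "<", quiet = TRUE)))
    }
    pred <- as.integer(prob >= 0.5)
    acc[r] <- mean(pred == y)
    sens[r] <- mean(pred[y == 1] == 1)
    spec[r] <- mean(pred[y == 0] == 0)
    roc_all <- pROC::roc(y, prob, levels = c(0, 1), direction = "<",
                         quiet = TRUE)
    sens_curves[r, ] <- pROC::coords(roc_all, x = spec_grid,
                                     input = "specificity",
                                     ret = "sensitivity",
                                     transpose = FALSE)[, 1]
  }
  structure(list(
    auc = auc_mat,
    mean_auc = mean(auc_mat),
    accuracy = mean(acc),
    sensitivity = mean(sens),
    specificity = mean(spec),
    balanced_accuracy = (mean(sens) + mean(spec)) / 2,
    roc_band = data.frame(
      specificity = spec_grid,
      sensitivity_mean = colMeans(sens_curves),
      sensitivity_lo = apply(sens_curves, 2, stats::quantile, 0.025),
      sensitivity_hi = apply(sens_curves, 2, stats::quantile, 0.975)
    ),
    seeds = seeds,
    relabelled_repeats = redraws
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report: mean AUC %.4f over %d x %d folds; ",
                     "bal. accuracy %.3f at threshold 0.5>\n"),
              x$mean_auc, nrow(x$auc), ncol(x$auc), x$balanced_accuracy))
  invisible(x)
}

#' Build a logistic model from fixed coefficients
#'
#' Used for worked examples with externally stated coefficients: the intercept can
#' be recovered with [calibrate_intercept] when only the slope coefficients
#' and one predicted probability are reported.
#'
#' @param coefficients Named numeric vector of slope coefficients
#'   (log-odds per unit).
#' @param intercept Intercept on the log-odds scale.
#' @param se Optional named standard errors.
#' @param vcov Optional covariance matrix (intercept first) for delta-method
#'   confidence intervals.
#' @return A `logistic_model`.
#' @export
logistic_model <- function(coefficients, intercept = 0, se = NULL,
                           vcov = NULL) {
  stopifnot(all(is.finite(coefficients)), is.finite(intercept))
  structure(list(
    fit = NULL,
    predictors = names(coefficients),
    coefficients = c("(Intercept)" = unname(intercept), coefficients),
    se = se,
    vcov = vcov,
    criterion = NA, direction = NA
  ), class = "logistic_model")
}

#' Calibrate an intercept from a stated prediction
#'
#' Solves for the intercept that makes the model reproduce a stated
#' probability at stated covariate values:
#' `qlogis(p) - sum(coef * x)`.
#'
#' @param coefficients Named slope coefficients.
#' @param at Named covariate values.
#' @param probability The probability the model should produce at `at`.
#' @return The intercept (log-odds scale).
#' @export
calibrate_intercept <- function(coefficients, at, probability) {
  stopifnot(probability > 0, probability < 1)
  missing <- setdiff(names(coefficients), names(at))
  if (length(missing)) stop("missing covariate value(s): ",
                            paste(missing, collapse = ", "))
  stats::qlogis(probability) -
    sum(coefficients * unlist(at)[names(coefficients)])
}

#' Predicted probability with delta-method interval
#'
#' Inverse-logit of the linear predictor; the 95% interval is computed on
#' the log-odds scale by the delta method (when a covariance matrix is
#' available) and then transformed.
#'
#' @param model A `logistic_model` (fitted or constructed).
#' @param covariates Named list/vector of covariate values.
#' @return Named numeric: `probability`, `lo`, `hi` (NA when no covariance
#'   is available).
#' @export
predict_probability <- function(model, covariates) {
  cf <- model$coefficients
  slopes <- cf[setdiff(names(cf), "(Intercept)")]
  missing <- setdiff(names(slopes), names(covariates))
  if (length(missing)) stop("missing covariate(s): ",
                            paste(missing, collapse = ", "))
  x <- unlist(covariates)[names(slopes)]
  eta <- unname(cf["(Intercept)"] + sum(slopes * x))
  V <- model$vcov
  if (is.null(V) && !is.null(model$fit)) V <- stats::vcov(model$fit)
  if (!is.null(V)) {
    g <- c(1, x)
    se_eta <- sqrt(drop(t(g) %*% V %*% g))
    lo <- stats::plogis(eta - 1.96 * se_eta)
    hi <- stats::plogis(eta + 1.96 * se_eta)
  } else {
    lo <- hi <- NA_real_
  }
  c(probability = stats::plogis(eta), lo = lo, hi = hi)
}

#' Percent change in odds per unit of a predictor
#'
#' `100 * (exp(coefficient) - 1)`, reported to one decimal place.
#'
#' @param coefficient Log-odds coefficient.
#' @return Percent change in odds (one decimal).
#' @export
odds_interpretation <- function(coefficient) {
  stopifnot(is.finite(coefficient))
  round(100 * (exp(coefficient) - 1), 1)
}
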