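test_that("VIF reduction keeps orthogonal predictors and drops collinear ones", {
  set.seed(21)
  # exactly orthogonal columns via QR
  Q <- qr.Q(qr(matrix(rnorm(200 * 3), 200, 3)))
  d <- as.data.frame(Q); names(d) <- c("a", "b", "c")
  expect_equal(vif_reduce(d), c("a", "b", "c"))

  # pairwise correlation exactly rho: VIF = 1/(1-rho^2)
  make_pair <- function(rho) {
    x1 <- Q[, 1]; e <- Q[, 2]
    data.frame(x1 = x1, x2 = rho * x1 + sqrt(1 - rho^2) * e)
  }
  # rho = 0.8944 sits just below the VIF 5 boundary: both retained
  expect_equal(vif_reduce(make_pair(0.8944)), c("x1", "x2"))
  # rho = 0.9 exceeds it: the later column is dropped
  expect_equal(vif_reduce(make_pair(0.90)), "x1")

  # near-perfect collinearity: later column dropped with a warning
  d2 <- data.frame(x = rnorm(100))
  d2$y <- 2 * d2$x + rnorm(100, 0, 1e-9)
  expect_warning(out <- vif_reduce(d2), "collinear")
  expect_equal(out, "x")
  expect_error(vif_reduce(data.frame(a = rnorm(5), b = rep(1, 5))), "constant")
})

test_that("stepwise selection finds a strong predictor and rejects pure noise", {
  set.seed(31)
  hit <- 0
  for (r in 1:100) {
    n <- 300
    X <- as.data.frame(matrix(rnorm(n * 11), n, 11))
    names(X) <- c("signal", paste0("noise", 1:10))
    eta <- -0.5 + 2 * X$signal
    X$y <- rbinom(n, 1, plogis(eta))
    m <- stepwise_select(X, "y", setdiff(names(X), "y"),
                         direction = "forward", criterion = "BIC")
    hit <- hit + ("signal" %in% m$predictors)
  }
  expect_gte(hit / 100, 0.9)

  none <- 0
  for (r in 1:60) {
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("noise", 1:6)
    X$y <- rbinom(n, 1, 0.5)
    m <- stepwise_select(X, "y", setdiff(names(X), "y"),
                         direction = "forward", criterion = "BIC")
    none <- none + (length(m$predictors) == 0)
  }
  expect_gt(none / 60, 0.5)  # intercept-only is the most frequent outcome
})

test_that("forward AIC on the synthetic cohort picks up the TPeak2 effect", {
  set.seed(41)
  co <- generate_cohort(cohort_config(seed = 41))
  m <- compute_metric_table(co$thermograms)
  tab <- build_cohort_table(m, fit_thermogram_pca(co$thermograms, 4), co$clinical)
  pts <- tab[tab$status != "control", ]
  pts$y <- as.integer(pts$status == "active")
  sel <- stepwise_select(pts, "y", c("age", "TPeak2", "Width", "Area"),
                         direction = "forward", criterion = "AIC")
  expect_true("TPeak2" %in% sel$predictors)
})

test_that("stratified folds carry 14-15 active and 6-7 NED with the printed class sizes", {
  y <- rep(c(1, 0), c(74, 33))
  for (s in 1:25) {
    folds <- withr::with_seed(s, make_stratified_folds(y, k = 5))
    expect_length(folds, 5)
    expect_equal(sort(unname(unlist(folds))), 1:107)
    for (f in folds) {
      expect_true(sum(y[f] == 1) %in% 14:15)
      expect_true(sum(y[f] == 0) %in% 6:7)
    }
  }
})

test_that("cross-validation is perfect on separable data and null on independent labels", {
  set.seed(51)
  d <- data.frame(x = c(rnorm(40, 0, 0.5), rnorm(40, 10, 0.5)),
                  y = factor(rep(0:1, each = 40)))
  cv <- cross_validate(d, "y", "x", repeats = 5, folds = 5, seed = 3)
  expect_equal(cv$mean_auc, 1)
  expect_equal(cv$balanced_accuracy, (cv$sensitivity + cv$specificity) / 2)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))

  dn <- data.frame(x = rnorm(200), z = rnorm(200), y = rbinom(200, 1, 0.5))
  cvn <- cross_validate(dn, "y", c("x", "z"), repeats = 10, folds = 5, seed = 3)
  expect_gt(cvn$mean_auc, 0.45); expect_lt(cvn$mean_auc, 0.55)
})

test_that("mean CV AUC is invariant to sample order under the same seed schedule", {
  set.seed(61)
  n <- 120
  d <- data.frame(x = rnorm(n), y = rbinom(n, 1, 0.5))
  d$x <- d$x + 0.8 * d$y
  cv1 <- cross_validate(d, "y", "x", repeats = 5, folds = 5, seed = 9)
  perm <- sample(n)
  cv2 <- cross_validate(d[perm, ], "y", "x", repeats = 5, folds = 5, seed = 9)
  expect_equal(cv1$mean_auc, cv2$mean_auc, tolerance = 0.02)
})

test_that("coefficient recovery: fitted log-odds within 3 SE of truth at n = 2000", {
  set.seed(71)
  ok <- 0
  for (r in 1:40) {
    n <- 2000
    age <- rnorm(n, 57, 14)
    tp2 <- rnorm(n, 70, 1)
    eta <- -40 + 0.0427 * age + 0.5010 * tp2
    y <- rbinom(n, 1, plogis(eta))
    fit <- glm(y ~ age + tp2, family = binomial())
    sm <- summary(fit)$coefficients
    ok <- ok + (abs(sm["age", 1] - 0.0427) <= 3 * sm["age", 2] &&
                  abs(sm["tp2", 1] - 0.5010) <= 3 * sm["tp2", 2])
  }
  expect_gte(ok / 40, 0.9)
})

test_that("worked-example predictions reproduce the published percentages", {
  coefs <- c(age = 0.0427, TPeak2 = 0.5010)
  b0 <- calibrate_intercept(coefs, c(age = 57, TPeak2 = 70), 0.741)
  m <- logistic_model(coefs, intercept = b0)
  p_med <- predict_probability(m, c(age = 57, TPeak2 = 70))
  expect_equal(unname(p_med["probability"]), 0.741, tolerance = 1e-12)
  expect_equal(round(100 * unname(predict_probability(m, c(age = 43, TPeak2 = 70))["probability"]), 1),
               61.1)
  expect_equal(round(100 * unname(predict_probability(m, c(age = 57, TPeak2 = 69))["probability"]), 1),
               63.4)
  # one-SD drops in age and TPeak2 have nearly equivalent impact
  drop_age <- 0.741 - predict_probability(m, c(age = 43, TPeak2 = 70))["probability"]
  drop_tp2 <- 0.741 - predict_probability(m, c(age = 57, TPeak2 = 69))["probability"]
  expect_lt(abs(drop_age - drop_tp2), 0.025)

  expect_error(predict_probability(m, c(age = 57)), "TPeak2")
  # zero model predicts 0.5 everywhere
  m0 <- logistic_model(c(a = 0, b = 0), intercept = 0)
  expect_equal(unname(predict_probability(m0, c(a = 5, b = -2))["probability"]), 0.5)
})

test_that("odds interpretation matches 100(exp(b)-1) to one decimal", {
  expect_equal(odds_interpretation(0.0427), 4.4)
  expect_equal(odds_interpretation(0.5010), 65.0)
  expect_equal(odds_interpretation(0), 0.0)
  expect_equal(odds_interpretation(-0.105), round(100 * (exp(-0.105) - 1), 1))
})

test_that("delta-method interval behaves for a fitted model", {
  set.seed(81)
  n <- 400
  x <- rnorm(n); y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  fit <- glm(y ~ x, family = binomial())
  m <- thermoparam:::as_logistic_model(fit)
  pr <- predict_probability(m, c(x = 0.5))
  expect_true(pr["lo"] < pr["probability"] && pr["probability"] < pr["hi"])
  ref <- predict(fit, newdata = data.frame(x = 0.5), type = "link", se.fit = TRUE)
  expect_equal(unname(pr["lo"]), unname(plogis(ref$fit - 1.96 * ref$se.fit)),
               tolerance = 1e-9)
})
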