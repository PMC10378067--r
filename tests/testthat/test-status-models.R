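make_status_data <- function(n_per_cell, means, sd = 1) {
  # means: 3x2 matrix (status x sex)
  grid <- expand.grid(status = c("control", "NED", "active"),
                      sex = c("female", "male"))
  d <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(status = grid$status[i], sex = grid$sex[i],
               response = rnorm(n_per_cell, means[grid$status[i], grid$sex[i]], sd))
  }))
  d$status <- factor(d$status, levels = c("control", "NED", "active"))
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d
}

test_that("partial-F reduction detects a true interaction and stays null-calibrated", {
  set.seed(101)
  means_int <- matrix(c(0, 0, 0, 0, 0, 3), 3, 2,
                      dimnames = list(c("control", "NED", "active"),
                                      c("female", "male")))
  hits <- 0
  for (r in 1:200) {
    d <- make_status_data(40, means_int)
    hits <- hits + (partial_f_reduce(d) == "interaction")
  }
  expect_gte(hits / 200, 0.95)

  # identical means: status-only dominates, overall p roughly uniform
  means0 <- matrix(0, 3, 2, dimnames = dimnames(means_int))
  forms <- character(100); ps <- numeric(100)
  for (r in 1:100) {
    d <- make_status_data(20, means0)
    forms[r] <- partial_f_reduce(d)
    ps[r] <- fit_status_model(d)$overall_p
  }
  expect_gt(mean(forms == "status-only"), 0.8)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("nested models with identical fit give partial F = 0 and p = 1", {
  # responses mirrored exactly across sex within each status: the sex
  # coefficient is exactly zero, so both fits have identical RSS
  cell <- c(-1, 0, 1)
  d <- do.call(rbind, lapply(c("control", "NED", "active"), function(s) {
    do.call(rbind, lapply(c("female", "male"), function(x) {
      data.frame(status = s, sex = x,
                 response = cell + match(s, c("control", "NED", "active")))
    }))
  }))
  d$status <- factor(d$status, levels = c("control", "NED", "active"))
  d$sex <- factor(d$sex)
  a <- anova(lm(response ~ status, data = d), lm(response ~ status + sex, data = d))
  expect_equal(a[2, "F"], 0, tolerance = 1e-9)
  expect_equal(a[2, "Pr(>F)"], 1, tolerance = 1e-9)
})

test_that("residual diagnostics pass Gaussian errors and fail heavy tails", {
  set.seed(202)
  pass_g <- 0; fail_t <- 0
  for (r in 1:200) {
    x <- rnorm(150); y <- 1 + 0.5 * x + rnorm(150)
    pass_g <- pass_g + residual_diagnostics(lm(y ~ x))$pass
  }
  # independent alpha=0.05 tests: pass rate near (1-alpha)^2 = 0.9025
  expect_gt(pass_g / 200, 0.9025 - 3 * sqrt(0.9025 * 0.0975 / 200))
  expect_lt(pass_g / 200, 1)
  for (r in 1:100) {
    x <- rnorm(150); y <- 1 + 0.5 * x + rt(150, df = 2)
    fail_t <- fail_t + !residual_diagnostics(lm(y ~ x))$pass
  }
  expect_gte(fail_t / 100, 0.8)

  # exact fit flagged as degenerate pass
  x <- 1:10; y <- 2 * x
  dg <- residual_diagnostics(lm(y ~ x))
  expect_true(dg$pass)
  expect_match(dg$note, "degenerate")
})

test_that("heavy-tailed responses fall back to median regression and recover the shift", {
  set.seed(303)
  ok <- 0
  for (r in 1:20) {
    d <- make_status_data(100, matrix(0, 3, 2,
      dimnames = list(c("control", "NED", "active"), c("female", "male"))))
    shift <- 2
    d$response <- rt(nrow(d), df = 3)
    d$response[d$status == "active"] <- d$response[d$status == "active"] + shift
    m <- fit_status_model(d)
    if (m$engine == "median-regression") {
      est <- coef(m$fit)[["statusactive"]]
      ok <- ok + (abs(est - shift) / shift < 0.2)
    }
  }
  expect_gte(ok / 20, 0.7)

  # constant response is reported non-significant
  d0 <- make_status_data(10, matrix(0, 3, 2,
    dimnames = list(c("control", "NED", "active"), c("female", "male"))))
  d0$response <- 1.5
  expect_equal(fit_status_model(d0)$overall_p, 1)
})

test_that("cohort-level status stage flags a generated Area shift", {
  set.seed(404)
  hits <- 0
  for (r in 1:25) {
    co <- generate_cohort(cohort_config(seed = 5000 + r))
    m <- compute_metric_table(co$thermograms)
    # impose a clean control-vs-melanoma shift in Area on top of the
    # generated curves (the default generator has no Area effect)
    tab <- build_cohort_table(m, fit_thermogram_pca(co$thermograms, 4), co$clinical)
    shift <- 2 * sd(tab$Area)
    tab$Area <- tab$Area + ifelse(tab$status == "control", 0, shift)
    res <- fit_status_model(data.frame(response = tab$Area, status = tab$status,
                                       sex = tab$sex), "Area")
    hits <- hits + (res$overall_p < 0.05)
  }
  expect_gte(hits / 25, 0.9)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(fdr_adjust(0.03), 0.03)
  # hand computation: p_(i) * m / i with cumulative minimum from the top
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.011, 0.9)
  expect_equal(fdr_adjust(p), c(0.004, 0.2666667, 0.022, 0.9), tolerance = 1e-6)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  pr <- runif(23)
  expect_true(all(fdr_adjust(pr) >= pr & fdr_adjust(pr) <= 1))
})

test_that("Tukey-adjusted contrasts: nulls give p near 1, shifted control separates", {
  set.seed(505)
  means0 <- matrix(0, 3, 2, dimnames = list(c("control", "NED", "active"),
                                            c("female", "male")))
  # exactly equal group means: the same within-cell values in every cell
  cell <- rnorm(10)
  d0 <- expand.grid(status = factor(c("control", "NED", "active"),
                                    levels = c("control", "NED", "active")),
                    sex = factor(c("female", "male")), i = 1:10)
  d0$response <- cell[d0$i]
  fit0 <- lm(response ~ status, data = d0)
  cc <- pairwise_emmeans(structure(list(form = "status-only", fit = fit0,
                                        data = d0),
                                   class = "status_model_result"))
  expect_equal(nrow(cc), 3)
  expect_lt(max(abs(cc$estimate)), 1e-12)
  expect_true(all(cc$p_tukey > 0.999))

  hits <- 0
  for (r in 1:50) {
    means <- means0; means["control", ] <- 2
    d <- make_status_data(30, means)
    fit <- lm(response ~ status, data = d)
    res <- structure(list(form = "status-only", fit = fit, data = d),
                     class = "status_model_result")
    cc <- pairwise_emmeans(res)
    ctl <- grepl("control", cc$contrast)
    hits <- hits + (all(cc$p_tukey[ctl] < 0.05) && cc$p_tukey[!ctl] > 0.05)
  }
  expect_gte(hits / 50, 0.9)

  # Tukey p >= unadjusted p, always
  for (r in 1:20) {
    d <- make_status_data(15, means0)
    fit <- lm(response ~ status, data = d)
    res <- structure(list(form = "status-only", fit = fit, data = d),
                     class = "status_model_result")
    em <- emmeans::emmeans(fit, ~status, data = d)
    unadj <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))$p.value
    adj <- pairwise_emmeans(res)$p_tukey
    expect_true(all(adj >= unadj - 1e-12))
  }
})

test_that("marginal means average sex cells with equal weight under imbalance", {
  # 6-cell fixture with unbalanced sexes, additive model
  set.seed(606)
  d <- rbind(make_status_data(4, matrix(c(0, 1, 2, 3, 4, 5), 3, 2,
    dimnames = list(c("control", "NED", "active"), c("female", "male")))),
    make_status_data(16, matrix(c(0, 1, 2, 3, 4, 5), 3, 2,
      dimnames = list(c("control", "NED", "active"), c("female", "male"))))[1:20, ])
  fit <- lm(response ~ status + sex, data = d)
  em <- summary(emmeans::emmeans(fit, ~status, data = d))
  # hand computation from the fitted coefficients: intercept + status effect
  # + half the sex effect (equal weighting over the two sexes)
  b <- coef(fit)
  hand <- c(b[1] + b["sexmale"] / 2,
            b[1] + b["statusNED"] + b["sexmale"] / 2,
            b[1] + b["statusactive"] + b["sexmale"] / 2)
  expect_equal(em$emmean, unname(hand), tolerance = 1e-10)
})

test_that("stage-level run adjusts across parameters and reports contrasts only under FDR", {
  co <- generate_cohort(cohort_config(seed = 99))
  m <- compute_metric_table(co$thermograms)
  tab <- build_cohort_table(m, fit_thermogram_pca(co$thermograms, 4), co$clinical)
  res <- fit_all_status_models(tab)
  expect_equal(nrow(res$summary), 23)
  expect_true(all(res$summary$overall_p_adj >= res$summary$overall_p - 1e-12))
  sig <- res$summary$parameter[res$summary$overall_p_adj < 0.05]
  expect_setequal(unique(res$contrasts$parameter), sig)
  # the same machinery supports alternative grouping labels unchanged
  tab2 <- tab[tab$status == "active", ]
  tab2$status <- factor(sample(c("localized", "distant"), nrow(tab2), TRUE))
  d <- data.frame(response = tab2$Area, status = tab2$status, sex = tab2$sex)
  expect_s3_class(fit_status_model(d, "Area"), "status_model_result")
})
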