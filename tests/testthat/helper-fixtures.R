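# Fixture builders and independent brute-force oracles. The oracles use
# plain loops and closed forms only, never the package's own extraction
# path, so they can serve as an independent second route.

gaussian_curve <- function(mu, sigma, A = 1, tt = canonical_mesh()) {
  rowSums(vapply(seq_along(mu), function(k) {
    A[k] * exp(-(tt - mu[k])^2 / (2 * sigma[k]^2))
  }, numeric(length(tt))))
}

make_set <- function(cp, ids = NULL) {
  thermogram_set(canonical_mesh(), cp, ids)
}

# a random, well-separated three-transition fixture: centers at least
# ~4.5 degC apart with widths small enough that each transition keeps a
# distinct local maximum
random_three_gaussian <- function() {
  mu <- c(runif(1, 62, 64.5), runif(1, 69, 71), runif(1, 74.5, 76.5))
  sigma <- c(runif(1, 1.2, 1.8), runif(1, 1.2, 1.8), runif(1, 1.6, 2.2))
  A <- c(runif(1, 0.18, 0.32), runif(1, 0.22, 0.38), runif(1, 0.1, 0.18))
  list(mu = mu, sigma = sigma, A = A,
       set = make_set(gaussian_curve(mu, sigma, A)))
}

# ---- brute-force metric oracle ----------------------------------------

oracle_window_peak <- function(tt, y, w) {
  best_i <- NA
  for (i in seq_along(tt)) {
    if (tt[i] >= w[1] - 1e-9 && tt[i] <= w[2] + 1e-9) {
      if (is.na(best_i) || y[i] > y[best_i]) best_i <- i
    }
  }
  c(temperature = tt[best_i], height = y[best_i])
}

oracle_valley <- function(tt, y, t1, t2) {
  best_i <- NA
  for (i in seq_along(tt)) {
    if (tt[i] > t1 + 1e-9 && tt[i] < t2 - 1e-9) {
      if (is.na(best_i) || y[i] < y[best_i]) best_i <- i
    }
  }
  c(temperature = tt[best_i], height = y[best_i])
}

oracle_monotonic_peaks <- function(tt, y, min_up = 3, min_down = 3) {
  res <- NULL
  n <- length(y)
  for (i in seq_len(n)) {
    up <- 0
    j <- i
    while (j > 1 && y[j - 1] < y[j]) { up <- up + 1; j <- j - 1 }
    down <- 0
    j <- i
    while (j < n && y[j + 1] < y[j]) { down <- down + 1; j <- j + 1 }
    if (up >= min_up && down >= min_down) {
      res <- rbind(res, c(tt[i], y[i]))
    }
  }
  if (is.null(res)) {
    data.frame(temperature = numeric(0), height = numeric(0))
  } else {
    data.frame(temperature = res[, 1], height = res[, 2])
  }
}

oracle_width <- function(tt, y) {
  half <- max(y) / 2
  t_first <- NA
  for (i in seq_len(length(y) - 1)) {
    if ((y[i] < half) != (y[i + 1] < half)) {
      t_first <- tt[i] + (half - y[i]) * (tt[i + 1] - tt[i]) / (y[i + 1] - y[i])
      break
    }
  }
  t_last <- NA
  for (i in rev(seq_len(length(y) - 1))) {
    if ((y[i] < half) != (y[i + 1] < half)) {
      t_last <- tt[i] + (half - y[i]) * (tt[i + 1] - tt[i]) / (y[i + 1] - y[i])
      break
    }
  }
  t_last - t_first
}

oracle_trapz <- function(tt, y) {
  s <- 0
  for (i in seq_len(length(tt) - 1)) {
    s <- s + (tt[i + 1] - tt[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

oracle_median <- function(y) {
  ys <- sort(y)
  n <- length(ys)
  if (n %% 2 == 1) ys[(n + 1) / 2] else (ys[n / 2] + ys[n / 2 + 1]) / 2
}

oracle_tfm <- function(tt, y) {
  num <- 0; den <- 0
  for (i in seq_along(y)) { num <- num + tt[i] * y[i]; den <- den + y[i] }
  num / den
}

oracle_metric_set <- function(tt, y) {
  w <- list(peak1 = c(60, 66.9), peak2 = c(67, 72.9), peak3 = c(73, 78))
  p1 <- oracle_window_peak(tt, y, w$peak1)
  p2 <- oracle_window_peak(tt, y, w$peak2)
  p3 <- oracle_window_peak(tt, y, w$peak3)
  v <- oracle_valley(tt, y, p1["temperature"], p2["temperature"])
  gmax_i <- 1
  for (i in seq_along(y)) if (y[i] > y[gmax_i]) gmax_i <- i
  c(Width = oracle_width(tt, y),
    Area = oracle_trapz(tt, y),
    Max = y[gmax_i],
    Median = oracle_median(y),
    TMax = tt[gmax_i],
    Peak1 = unname(p1["height"]), Peak2 = unname(p2["height"]),
    Peak3 = unname(p3["height"]), `V1.2` = unname(v["height"]),
    TPeak1 = unname(p1["temperature"]), TPeak2 = unname(p2["temperature"]),
    TPeak3 = unname(p3["temperature"]), `TV1.2` = unname(v["temperature"]),
    `Peak1.2` = unname(p1["height"] / p2["height"]),
    `Peak1.3` = unname(p1["height"] / p3["height"]),
    `Peak2.3` = unname(p2["height"] / p3["height"]),
    `V1.2.Peak1` = unname(v["height"] / p1["height"]),
    `V1.2.Peak2` = unname(v["height"] / p2["height"]),
    `V1.2.Peak3` = unname(v["height"] / p3["height"]),
    TFM = oracle_tfm(tt, y))
}
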