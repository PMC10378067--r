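#' Principal components of a thermogram set
#'
#' Column-mean-centered, unscaled PCA of the samples x temperatures matrix
#' via [stats::prcomp]. The decomposition keeps every explained-variance
#' fraction but truncates loadings and scores to `k` components. Loading
#' signs follow a deterministic convention: the element of largest magnitude
#' in each loading is positive, so downstream hazard-ratio directions are
#' reproducible across runs.
#'
#' @param ts A [thermogram_set] on the canonical mesh with n >= 2 samples.
#' @param k Number of components to retain (default 5, the scree report
#'   depth; statistical stages consume PC1--PC4).
#' @param center,scale. Passed to [stats::prcomp]; the defaults (center,
#'   no scaling) match standard practice for curves on a common scale.
#' @return An object of class `thermogram_pca`: `temperature`, `mean_curve`,
#'   `loadings` (temperatures x k), `scores` (samples x k),
#'   `explained_fraction` (all components), `sdev` (all components).
#' @export
fit_thermogram_pca <- function(ts, k = 5, center = TRUE, scale. = FALSE) {
  assert_canonical(ts)
  n <- n_samples(ts)
  if (n < 2) stop("PCA requires at least two samples")
  k <- min(k, n - 1, length(ts$temperature))
  X <- t(ts$cp)                       # samples x temperatures
  pc <- stats::prcomp(X, center = center, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(
    temperature = ts$temperature,
    mean_curve = if (isTRUE(center)) pc$center else rep(0, length(ts$temperature)),
    loadings = rotation[, seq_len(k), drop = FALSE],
    scores = scores[, seq_len(k), drop = FALSE],
    explained_fraction = ev / sum(ev),
    sdev = pc$sdev,
    k = k
  ), class = "thermogram_pca")
}

#' @export
print.thermogram_pca <- function(x, ...) {
  cat(sprintf("<thermogram_pca: %d component(s) kept, first %d explain %.1f%% of variance>\n",
              x$k, x$k, 100 * sum(x$explained_fraction[seq_len(x$k)])))
  invisible(x)
}

#' Project curves onto a fitted PCA basis
#'
#' Computes `(curve - mean_curve) %*% loadings` for each sample.
#'
#' @param ts A [thermogram_set] on the decomposition's mesh.
#' @param pca A `thermogram_pca` from [fit_thermogram_pca].
#' @return Matrix of scores, samples x k.
#' @export
project_thermograms <- function(ts, pca) {
  if (length(ts$temperature) != length(pca$temperature) ||
      any(abs(ts$temperature - pca$temperature) > 1e-6)) {
    stop("curves are not on the decomposition mesh")
  }
  centered <- sweep(t(ts$cp), 2, pca$mean_curve, "-")
  centered %*% pca$loadings
}

#' Persist a PCA decomposition
#'
#' Writes `<stem>_loadings.csv` (temperature + one column per PC),
#' `<stem>_scores.csv` (sample_id + one column per PC) and `<stem>.json`
#' (explained fractions, mesh spec, sign convention).
#'
#' @param pca A `thermogram_pca`.
#' @param stem Path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_pca <- function(pca, stem) {
  ld <- data.frame(Temperature = pca$temperature, pca$loadings, check.names = FALSE)
  utils::write.csv(ld, paste0(stem, "_loadings.csv"), row.names = FALSE)
  sc <- data.frame(sample_id = rownames(pca$scores), pca$scores, check.names = FALSE)
  utils::write.csv(sc, paste0(stem, "_scores.csv"), row.names = FALSE)
  meta <- list(
    explained_fraction = pca$explained_fraction,
    mesh = list(start = min(pca$temperature), stop = max(pca$temperature),
                step = diff(pca$temperature[1:2]), n = length(pca$temperature)),
    sign_convention = "largest-magnitude loading element positive",
    k = pca$k,
    mean_curve = pca$mean_curve
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Reload a persisted PCA decomposition
#' @param stem Path stem used in [write_pca].
#' @return A `thermogram_pca`.
#' @export
read_pca <- function(stem) {
  ld <- utils::read.csv(paste0(stem, "_loadings.csv"), check.names = FALSE)
  sc <- utils::read.csv(paste0(stem, "_scores.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  scores <- as.matrix(sc[-1])
  rownames(scores) <- sc$sample_id
  structure(list(
    temperature = ld$Temperature,
    mean_curve = meta$mean_curve,
    loadings = as.matrix(ld[-1]),
    scores = scores,
    explained_fraction = meta$explained_fraction,
    sdev = sqrt(meta$explained_fraction), # relative scale only
    k = meta$k
  ), class = "thermogram_pca")
}
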