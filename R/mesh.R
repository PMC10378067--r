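#' Canonical analysis temperature mesh
#'
#' The canonical mesh covers 45.0--90.0 degrees Celsius at 0.1 degree steps,
#' giving exactly 451 points. All summary metrics, PCA features and
#' statistical stages operate on curves interpolated to this mesh.
#'
#' @param start,stop,step Mesh limits and spacing in degrees Celsius.
#' @return Numeric vector of temperatures, strictly increasing with uniform
#'   spacing.
#' @export
#' @examples
#' length(canonical_mesh()) # 451
canonical_mesh <- function(start = 45, stop = 90, step = 0.1) {
  stopifnot(step > 0, stop > start)
  # integer arithmetic avoids cumulative floating-point drift in seq()
  n <- round((stop - start) / step)
  start + (0:n) * step
}

#' Test whether temperatures lie on the canonical mesh
#'
#' @param temperature Numeric vector of temperatures.
#' @param tol Matching tolerance in degrees Celsius.
#' @return Logical scalar.
#' @export
is_canonical_mesh <- function(temperature, tol = 1e-6) {
  ref <- canonical_mesh()
  length(temperature) == length(ref) && all(abs(temperature - ref) < tol)
}

assert_uniform_mesh <- function(temperature, tol = 1e-9) {
  if (length(temperature) < 2 || any(!is.finite(temperature))) {
    stop("temperature mesh must be finite with at least two points")
  }
  d <- diff(temperature)
  if (any(d <= 0)) stop("temperature mesh must be strictly increasing")
  if (max(d) - min(d) > tol * max(1, abs(mean(d)))) {
    stop("temperature mesh spacing is not uniform")
  }
  invisible(temperature)
}

#' Construct a set of thermogram curves on a shared mesh
#'
#' A `thermogram_set` is the package's container for one or more excess
#' specific heat capacity curves (cal/degC/g) sampled on a common
#' temperature mesh: a numeric temperature vector plus a temperatures x
#' samples matrix with sample ids as column names.
#'
#' @param temperature Numeric mesh (strictly increasing, uniform spacing).
#' @param cp Numeric matrix (length(temperature) rows) or a vector for a
#'   single sample.
#' @param sample_id Character vector of sample ids; defaults to existing
#'   column names.
#' @return An object of class `thermogram_set`.
#' @export
thermogram_set <- function(temperature, cp, sample_id = NULL) {
  temperature <- as.numeric(temperature)
  assert_uniform_mesh(temperature, tol = 1e-7)
  if (is.vector(cp)) cp <- matrix(as.numeric(cp), ncol = 1)
  cp <- as.matrix(cp)
  if (nrow(cp) != length(temperature)) {
    stop("cp must have one row per mesh temperature (",
         length(temperature), "), got ", nrow(cp))
  }
  if (!all(is.finite(cp))) {
    bad <- which(!is.finite(cp), arr.ind = TRUE)[1, ]
    stop("non-finite heat capacity at temperature ",
         temperature[bad[1]], " in sample ", colnames(cp)[bad[2]] %||% bad[2])
  }
  if (is.null(sample_id)) sample_id <- colnames(cp)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(ncol(cp)))
  if (length(sample_id) != ncol(cp)) stop("one sample_id per column required")
  colnames(cp) <- as.character(sample_id)
  structure(list(temperature = temperature, cp = cp),
            class = "thermogram_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thermogram_set <- function(x, ...) {
  cat(sprintf("<thermogram_set: %d sample(s), mesh %.1f-%.1f degC x %d points%s>\n",
              ncol(x$cp), min(x$temperature), max(x$temperature),
              length(x$temperature),
              if (is_canonical_mesh(x$temperature)) " (canonical)" else ""))
  invisible(x)
}

#' Number of samples in a thermogram set
#' @param ts A `thermogram_set`.
#' @return Integer.
#' @export
n_samples <- function(ts) ncol(ts$cp)

#' Extract one curve from a thermogram set
#' @param ts A `thermogram_set`.
#' @param i Column index or sample id.
#' @return A single-sample `thermogram_set`.
#' @export
get_curve <- function(ts, i) {
  thermogram_set(ts$temperature, ts$cp[, i, drop = FALSE])
}

assert_same_mesh <- function(a, b, tol = 1e-6) {
  if (length(a$temperature) != length(b$temperature) ||
      any(abs(a$temperature - b$temperature) > tol)) {
    stop("thermogram meshes do not match")
  }
  invisible(TRUE)
}

assert_canonical <- function(ts) {
  if (!is_canonical_mesh(ts$temperature)) {
    stop("curves must be on the canonical 45-90 degC / 0.1 degC mesh ",
         "(451 points); use interpolate_to_mesh() first")
  }
  invisible(ts)
}
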