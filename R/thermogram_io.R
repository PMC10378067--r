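#' Read a wide thermogram matrix CSV
#'
#' Expected layout: a header row, first column `Temperature`, one column of
#' excess specific heat capacity per sample. Comma separated, `.` decimal.
#'
#' @param path Path to the CSV file.
#' @return A [thermogram_set] with sample ids in column order.
#' @export
read_thermogram_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("thermogram matrix needs a temperature column plus at least one sample")
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v))) {
      row <- which(is.na(v))[1]
      stop(sprintf("non-numeric or missing value in column '%s' (data row %d) of %s",
                   names(raw)[j], row, path))
    }
    raw[[j]] <- v
  }
  thermogram_set(raw[[1]], as.matrix(raw[-1]))
}

#' Write a thermogram set as a wide CSV
#'
#' @param ts A [thermogram_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram_matrix <- function(ts, path) {
  out <- data.frame(Temperature = ts$temperature, check.names = FALSE)
  out <- cbind(out, as.data.frame(ts$cp, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Columns: `sample_id, status, sex, age, stage, n_affected, location,
#' os_time, os_event, pfs_time, pfs_event` (optional fields may be blank).
#' `status` must be one of control/NED/active; `os_time` must be positive
#' when present.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with typed columns.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "status", "sex", "age")
  missing <- setdiff(required, names(cl))
  if (length(missing)) stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(cl$status), c("control", "NED", "active"))
  if (length(bad)) stop("unknown status label(s): ", paste(bad, collapse = ", "))
  if ("os_time" %in% names(cl) && any(!is.na(cl$os_time) & cl$os_time <= 0)) {
    stop("os_time must be positive where present")
  }
  cl$status <- factor(cl$status, levels = c("control", "NED", "active"))
  if ("sex" %in% names(cl)) cl$sex <- factor(cl$sex, levels = c("female", "male"))
  for (col in c("os_event", "pfs_event")) {
    if (col %in% names(cl)) cl[[col]] <- as.logical(cl[[col]])
  }
  cl
}

#' Write a clinical table CSV
#' @param clinical Data frame as returned by [read_clinical_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Linearly interpolate curves onto a target mesh
#'
#' Straight-line interpolation between bracketing source points; values are
#' exact where source and target temperatures coincide. The source mesh must
#' span the target range (no extrapolation).
#'
#' @param ts A [thermogram_set].
#' @param target Numeric target mesh; defaults to the canonical mesh.
#' @return A [thermogram_set] on `target`.
#' @export
interpolate_to_mesh <- function(ts, target = canonical_mesh()) {
  assert_uniform_mesh(target, tol = 1e-7)
  eps <- 1e-9
  if (min(target) < min(ts$temperature) - eps ||
      max(target) > max(ts$temperature) + eps) {
    stop(sprintf("target mesh [%.3f, %.3f] extends beyond source support [%.3f, %.3f]",
                 min(target), max(target), min(ts$temperature), max(ts$temperature)))
  }
  cp <- apply(ts$cp, 2, function(y) {
    stats::approx(ts$temperature, y, xout = target, rule = 1)$y
  })
  cp <- matrix(cp, nrow = length(target), dimnames = list(NULL, colnames(ts$cp)))
  thermogram_set(target, cp)
}

#' Subtract a reference scan from each sample
#'
#' Pointwise subtraction of a buffer reference curve, the first step of
#' thermogram post-processing.
#'
#' @param ts A [thermogram_set] of sample scans.
#' @param reference A single-sample [thermogram_set] (or numeric vector on
#'   the same mesh).
#' @return A [thermogram_set].
#' @export
subtract_reference <- function(ts, reference) {
  ref <- reference_vector(ts, reference)
  thermogram_set(ts$temperature, ts$cp - ref, colnames(ts$cp))
}

reference_vector <- function(ts, reference) {
  if (inherits(reference, "thermogram_set")) {
    assert_same_mesh(ts, reference)
    if (ncol(reference$cp) != 1) stop("reference must be a single curve")
    reference$cp[, 1]
  } else {
    if (length(reference) != length(ts$temperature)) stop("thermogram meshes do not match")
    as.numeric(reference)
  }
}

#' Normalize curves by total protein mass
#'
#' Divides heat capacity by protein mass (concentration x cell volume) to
#' express curves per gram of total protein.
#'
#' @param ts A [thermogram_set].
#' @param protein_conc Protein concentration, g/L (> 0); scalar or one per sample.
#' @param cell_volume Calorimeter cell volume, L (> 0).
#' @return A [thermogram_set] in cal/degC/g.
#' @export
normalize_by_concentration <- function(ts, protein_conc, cell_volume) {
  if (any(protein_conc <= 0)) stop("protein concentration must be positive")
  if (any(cell_volume <= 0)) stop("cell volume must be positive")
  mass <- protein_conc * cell_volume
  cp <- sweep(ts$cp, 2, mass, "/")
  thermogram_set(ts$temperature, cp, colnames(ts$cp))
}

#' Linear baseline correction
#'
#' Fits a least-squares straight line to the points inside two flat anchor
#' windows (pre- and post-transition) and subtracts it from the whole curve.
#' Defaults anchor on 45--50 and 85--90 degC, the flat tails outside the
#' protein denaturation transitions.
#'
#' @param ts A [thermogram_set].
#' @param pre_window,post_window Length-2 numeric windows (degC) inside the
#'   mesh; must not overlap.
#' @return A baseline-corrected [thermogram_set].
#' @export
linear_baseline_correct <- function(ts, pre_window = c(45, 50),
                                    post_window = c(85, 90)) {
  tt <- ts$temperature
  if (pre_window[2] >= post_window[1]) stop("baseline windows must not overlap")
  sel <- (tt >= pre_window[1] & tt <= pre_window[2]) |
         (tt >= post_window[1] & tt <= post_window[2])
  if (sum(tt >= pre_window[1] & tt <= pre_window[2]) == 0 ||
      sum(tt >= post_window[1] & tt <= post_window[2]) == 0) {
    stop("empty baseline window")
  }
  X <- cbind(1, tt[sel])
  beta <- qr.solve(X, ts$cp[sel, , drop = FALSE])   # 2 x nsamples
  baseline <- cbind(1, tt) %*% beta
  thermogram_set(tt, ts$cp - baseline, colnames(ts$cp))
}

#' Average replicate scans
#'
#' Pointwise mean over the samples of a set (n >= 1), e.g. duplicate DSC
#' scans of the same specimen.
#'
#' @param ts A [thermogram_set] whose columns are replicates of one specimen.
#' @param sample_id Id for the averaged curve.
#' @return A single-sample [thermogram_set].
#' @export
average_replicates <- function(ts, sample_id = colnames(ts$cp)[1]) {
  if (n_samples(ts) < 1) stop("no replicate curves supplied")
  thermogram_set(ts$temperature, rowMeans(ts$cp), sample_id)
}
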