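#' Peak search windows
#'
#' Fixed temperature windows for the three plasma thermogram transitions:
#' Peak 1 at 60--66.9 degC, Peak 2 at 67--72.9 degC, Peak 3 at 73--78 degC
#' (closed intervals). Peaks 1 and 2 loosely track albumin and globulin
#' denaturation.
#'
#' @param peak1,peak2,peak3 Length-2 numeric windows (degC).
#' @return A named list of windows, class `peak_windows`.
#' @export
peak_windows <- function(peak1 = c(60, 66.9), peak2 = c(67, 72.9),
                         peak3 = c(73, 78)) {
  w <- list(peak1 = peak1, peak2 = peak2, peak3 = peak3)
  edges <- unlist(w)
  if (any(diff(edges) < 0)) stop("peak windows must be ordered and non-overlapping")
  structure(w, class = "peak_windows")
}

curve_vectors <- function(ts) {
  if (inherits(ts, "thermogram_set")) {
    if (ncol(ts$cp) != 1) stop("a single curve is required")
    list(temperature = ts$temperature, cp = ts$cp[, 1])
  } else {
    ts
  }
}

#' Monotonic-run peak identification
#'
#' A mesh point is a peak when it terminates a run of at least `min_up`
#' strictly increasing steps and is followed by at least `min_down` strictly
#' decreasing steps. Plateaus break a run.
#'
#' @param ts A single-sample [thermogram_set].
#' @param min_up,min_down Minimum run lengths (mesh steps).
#' @return A data.frame with columns `temperature`, `height`, sorted by
#'   temperature; zero rows when no peak qualifies.
#' @export
find_peaks_monotonic <- function(ts, min_up = 3, min_down = 3) {
  cv <- curve_vectors(ts)
  y <- cv$cp
  s <- sign(diff(y))           # +1 strict rise, -1 strict fall, 0 plateau
  r <- rle(s)
  ends <- cumsum(r$lengths)
  out <- data.frame(temperature = numeric(0), height = numeric(0))
  if (length(r$values) < 2) return(out)
  for (k in seq_len(length(r$values) - 1)) {
    if (r$values[k] == 1 && r$lengths[k] >= min_up &&
        r$values[k + 1] == -1 && r$lengths[k + 1] >= min_down) {
      i <- ends[k] + 1             # index of the local maximum
      out <- rbind(out, data.frame(temperature = cv$temperature[i], height = y[i]))
    }
  }
  out[order(out$temperature), , drop = FALSE]
}

#' Windowed peak identification
#'
#' For each predefined window, returns the mesh point of maximal heat
#' capacity inside the closed interval; ties go to the lowest temperature.
#'
#' @param ts A single-sample [thermogram_set].
#' @param windows A [peak_windows] object.
#' @return A data.frame with rows peak1/peak2/peak3 and columns
#'   `temperature`, `height`.
#' @export
find_peaks_windowed <- function(ts, windows = peak_windows()) {
  cv <- curve_vectors(ts)
  res <- lapply(windows, function(w) {
    sel <- which(cv$temperature >= w[1] - 1e-9 & cv$temperature <= w[2] + 1e-9)
    i <- sel[which.max(cv$cp[sel])]
    c(temperature = cv$temperature[i], height = cv$cp[i])
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- names(windows)
  out
}

#' Valley between two temperatures
#'
#' Mesh point of minimal heat capacity strictly between `t_left` and
#' `t_right`; ties go to the lowest temperature.
#'
#' @param ts A single-sample [thermogram_set].
#' @param t_left,t_right Bracketing temperatures (degC), `t_left < t_right`.
#' @return Named numeric: `temperature`, `height`.
#' @export
find_valley <- function(ts, t_left, t_right) {
  cv <- curve_vectors(ts)
  if (t_left >= t_right) stop("t_left must be below t_right")
  sel <- which(cv$temperature > t_left + 1e-9 & cv$temperature < t_right - 1e-9)
  if (length(sel) < 1) stop("no interior mesh point between the two peaks")
  i <- sel[which.min(cv$cp[sel])]
  c(temperature = cv$temperature[i], height = cv$cp[i])
}

#' Thermogram width at half height
#'
#' Distance between the outermost crossings of half the global maximum,
#' located by linear interpolation between bracketing mesh points. The
#' half level refers to the global envelope over the whole mesh, not to a
#' single transition.
#'
#' @param ts A single-sample [thermogram_set].
#' @return Width in degC.
#' @export
width_at_half_height <- function(ts) {
  cv <- curve_vectors(ts)
  y <- cv$cp; tt <- cv$temperature
  half <- max(y) / 2
  if (max(y) <= 0) stop("width undefined: curve maximum is not positive")
  above <- y >= half
  cross <- which(diff(above) != 0)
  if (!length(cross)) stop("width undefined: curve never crosses half height twice")
  interp_at <- function(i) {
    tt[i] + (half - y[i]) * (tt[i + 1] - tt[i]) / (y[i + 1] - y[i])
  }
  t_first <- if (above[1]) tt[1] else interp_at(cross[1])
  last <- cross[length(cross)]
  t_last <- if (above[length(above)]) tt[length(tt)] else interp_at(last)
  if (t_last <= t_first) stop("width undefined: degenerate half-height crossings")
  t_last - t_first
}

#' Total area under the thermogram
#'
#' Trapezoid integral of heat capacity over the mesh (cal/g).
#'
#' @param ts A single-sample [thermogram_set].
#' @return Area in cal/g.
#' @export
total_area <- function(ts) {
  cv <- curve_vectors(ts)
  pracma::trapz(cv$temperature, cv$cp)
}

#' Global maximum and its temperature
#'
#' @param ts A single-sample [thermogram_set].
#' @return Named numeric: `Max`, `TMax` (ties to lowest temperature).
#' @export
max_and_tmax <- function(ts) {
  cv <- curve_vectors(ts)
  i <- which.max(cv$cp)
  c(Max = cv$cp[i], TMax = cv$temperature[i])
}

#' Median heat capacity
#' @param ts A single-sample [thermogram_set].
#' @return Median of the mesh cp values (cal/degC/g).
#' @export
median_cp <- function(ts) {
  cv <- curve_vectors(ts)
  stats::median(cv$cp)
}

#' First moment temperature (TFM)
#'
#' Heat-capacity-weighted mean temperature,
#' \eqn{\sum T_i c_{p,i} / \sum c_{p,i}}.
#'
#' @param ts A single-sample [thermogram_set].
#' @return TFM in degC.
#' @export
first_moment_temperature <- function(ts) {
  cv <- curve_vectors(ts)
  s <- sum(cv$cp)
  if (s <= 0) stop("first moment undefined: total heat capacity is not positive")
  sum(cv$temperature * cv$cp) / s
}

#' Metric column names
#'
#' The 20 computed summary metrics. `TPeak3` is computed and reported but is
#' excluded from the 23-parameter statistical set because the two
#' peak-finding methods can disagree on shoulder-like third transitions.
#'
#' @param statistical If `TRUE`, return the 19 metrics used in the
#'   statistical stages (i.e. without `TPeak3`).
#' @return Character vector of column names.
#' @export
metric_names <- function(statistical = FALSE) {
  nm <- c("Width", "Area", "Max", "Median", "TMax",
          "Peak1", "Peak2", "Peak3", "V1.2",
          "TPeak1", "TPeak2", "TPeak3", "TV1.2",
          "Peak1.2", "Peak1.3", "Peak2.3",
          "V1.2.Peak1", "V1.2.Peak2", "V1.2.Peak3", "TFM")
  if (statistical) setdiff(nm, "TPeak3") else nm
}

#' Compute the full metric set for one curve
#'
#' Assembles the 20 summary metrics. Peaks come from the windowed method;
#' the valley V1.2 is the minimum between the Peak 1 and Peak 2 positions;
#' ratio metrics are quotients of the named heights. An agreement flag per
#' peak records whether the monotonic-run method found the same mesh point
#' inside that window.
#'
#' @param ts A single-sample [thermogram_set] on the canonical mesh.
#' @param windows A [peak_windows] object.
#' @return A one-row data.frame: 20 metric columns plus logical
#'   `agree_peak1`, `agree_peak2`, `agree_peak3`.
#' @export
compute_metric_set <- function(ts, windows = peak_windows()) {
  assert_canonical(ts)
  cv <- curve_vectors(ts)
  pk <- find_peaks_windowed(ts, windows)
  vl <- tryCatch(find_valley(ts, pk["peak1", "temperature"], pk["peak2", "temperature"]),
                 error = function(e) stop("V1.2: ", conditionMessage(e)))
  mm <- max_and_tmax(ts)
  ratio <- function(a, b, nm) {
    if (b == 0) stop(nm, ": zero denominator height")
    a / b
  }
  mono <- find_peaks_monotonic(ts)
  agree <- vapply(rownames(pk), function(p) {
    any(abs(mono$temperature - pk[p, "temperature"]) < 1e-9 &
        abs(mono$height - pk[p, "height"]) < 1e-12)
  }, logical(1))
  out <- data.frame(
    Width = tryCatch(width_at_half_height(ts), error = function(e) stop("Width: ", conditionMessage(e))),
    Area = total_area(ts),
    Max = unname(mm["Max"]),
    Median = median_cp(ts),
    TMax = unname(mm["TMax"]),
    Peak1 = pk["peak1", "height"],
    Peak2 = pk["peak2", "height"],
    Peak3 = pk["peak3", "height"],
    `V1.2` = unname(vl["height"]),
    TPeak1 = pk["peak1", "temperature"],
    TPeak2 = pk["peak2", "temperature"],
    TPeak3 = pk["peak3", "temperature"],
    `TV1.2` = unname(vl["temperature"]),
    `Peak1.2` = ratio(pk["peak1", "height"], pk["peak2", "height"], "Peak1.2"),
    `Peak1.3` = ratio(pk["peak1", "height"], pk["peak3", "height"], "Peak1.3"),
    `Peak2.3` = ratio(pk["peak2", "height"], pk["peak3", "height"], "Peak2.3"),
    `V1.2.Peak1` = ratio(unname(vl["height"]), pk["peak1", "height"], "V1.2.Peak1"),
    `V1.2.Peak2` = ratio(unname(vl["height"]), pk["peak2", "height"], "V1.2.Peak2"),
    `V1.2.Peak3` = ratio(unname(vl["height"]), pk["peak3", "height"], "V1.2.Peak3"),
    TFM = tryCatch(first_moment_temperature(ts), error = function(e) stop("TFM: ", conditionMessage(e))),
    check.names = FALSE
  )
  out$agree_peak1 <- unname(agree["peak1"])
  out$agree_peak2 <- unname(agree["peak2"])
  out$agree_peak3 <- unname(agree["peak3"])
  out
}

#' Compute the metric table for a whole set
#'
#' @param ts A [thermogram_set] on the canonical mesh.
#' @param windows A [peak_windows] object.
#' @return Data frame with `sample_id`, the 20 metric columns and the
#'   per-peak agreement flags, one row per sample.
#' @export
compute_metric_table <- function(ts, windows = peak_windows()) {
  assert_canonical(ts)
  rows <- lapply(seq_len(n_samples(ts)), function(i) {
    res <- tryCatch(compute_metric_set(get_curve(ts, i), windows),
                    error = function(e) {
                      stop("sample ", colnames(ts$cp)[i], ": ", conditionMessage(e))
                    })
    cbind(data.frame(sample_id = colnames(ts$cp)[i]), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a metric table CSV
#' @param metrics Output of [compute_metric_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
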