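#' Synthetic cohort generator configuration
#'
#' Defaults emulate the structure of a three-group melanoma DSC cohort:
#' 49 controls, 74 active, 33 NED; three-transition curves with peaks near
#' 63/70/75 degC; an active-group +0.4 degC shift of the second transition;
#' a latent per-subject factor `z` that simultaneously widens the Peak-3
#' tail and deepens the Peak1/Peak2 valley and drives overall survival with
#' log-hazard coefficient `cox_beta` = 0.553; group-specific age and sex
#' distributions; and uniform administrative censoring.
#'
#' Amplitudes, transition widths and jitter scales are stated conventions
#' chosen so that measured TPeak2 values span roughly 67.3--71.2 degC;
#' they are not measured quantities.
#'
#' @param n_control,n_active,n_ned Group sizes.
#' @param peak_centers,peak_sigmas,amplitudes Gaussian transition shape
#'   (degC, degC, cal/degC/g). `peak_centers[2]` is the NED/control mean of
#'   the second transition.
#' @param tpeak2_shift_active Mean shift (degC) of the second transition in
#'   the active group.
#' @param tpeak2_jitter_sd Between-subject SD of the second transition
#'   position (degC).
#' @param peak13_jitter_sd Between-subject SD of transitions 1 and 3 (degC).
#' @param amp_jitter_sd Multiplicative (log scale) SD of amplitudes.
#' @param peak3_tail_amp,valley_depth_amp Loadings of the latent factor `z`
#'   on the Peak-3 tail bump and the valley deepening (cal/degC/g per SD).
#' @param peak3_shoulder If `TRUE`, shrink the third transition to a
#'   shoulder so the two peak-finding methods disagree on Peak 3.
#' @param noise_sd Additive mesh-point noise SD (cal/degC/g).
#' @param cox_beta Log-hazard per unit of `z` (default 0.553).
#' @param os_shape,os_median_baseline Weibull shape and baseline (z = 0)
#'   median OS in years.
#' @param followup_range Administrative censoring window (years, uniform).
#' @param age_centers,age_ranges Per-group age medians and (lo, hi) bounds.
#' @param age_sd Age SD (years) before truncation to the group range.
#' @param sex_prob_female Per-group probability of female sex.
#' @param pfs_event_rate Target recurrence fraction among NED.
#' @param null_effects If `TRUE`, remove every group difference and set
#'   `cox_beta = 0` (shared age/sex distributions) for null calibration.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 49, n_active = 74, n_ned = 33,
                          peak_centers = c(63, 69.9, 75),
                          peak_sigmas = c(1.8, 1.6, 1.6),
                          amplitudes = c(0.26, 0.30, 0.10),
                          tpeak2_shift_active = 0.4,
                          tpeak2_jitter_sd = 0.7,
                          peak13_jitter_sd = 0.25,
                          amp_jitter_sd = 0.05,
                          peak3_tail_amp = 0.012,
                          valley_depth_amp = 0.008,
                          peak3_shoulder = FALSE,
                          noise_sd = 0.004,
                          cox_beta = 0.553,
                          os_shape = 1.2,
                          os_median_baseline = 5,
                          followup_range = c(1, 10),
                          age_centers = c(control = 59, active = 62, NED = 53),
                          age_ranges = list(control = c(25, 93),
                                            active = c(26, 93),
                                            NED = c(23, 79)),
                          age_sd = 15,
                          sex_prob_female = c(control = 0.653,
                                              active = 0.365, NED = 0.394),
                          pfs_event_rate = 7 / 32,
                          null_effects = FALSE,
                          seed = 1L) {
  stopifnot(all(amplitudes > 0), all(peak_sigmas > 0), noise_sd >= 0)
  cfg <- as.list(environment())
  if (null_effects) {
    cfg$tpeak2_shift_active <- 0
    cfg$cox_beta <- 0
    cfg$age_centers[] <- 57
    cfg$age_ranges <- list(control = c(23, 93), active = c(23, 93),
                           NED = c(23, 93))
    cfg$sex_prob_female[] <- 0.45
  }
  if (cfg$peak3_shoulder) cfg$amplitudes[3] <- 0.02
  structure(cfg, class = "cohort_config")
}

#' Generating-parameter truth record
#'
#' Emits the effects implied by a configuration, for parameter-recovery
#' tests. With class-conditional Gaussian TPeak2 (means Delta apart, common
#' SD sigma) and Gaussian age, the generating conditional log-odds of
#' active vs NED are `Delta/sigma^2` per degC of TPeak2 and
#' `Delta_age/age_sd^2` per year of age.
#'
#' @param config A [cohort_config].
#' @return List: `cox_beta`, `tpeak2_shift_active`, `logodds_tpeak2`,
#'   `logodds_age`, `seed`.
#' @export
ground_truth <- function(config) {
  list(
    cox_beta = config$cox_beta,
    tpeak2_shift_active = config$tpeak2_shift_active,
    logodds_tpeak2 = config$tpeak2_shift_active / config$tpeak2_jitter_sd^2,
    logodds_age = (config$age_centers[["active"]] -
                     config$age_centers[["NED"]]) / config$age_sd^2,
    seed = config$seed
  )
}

# Low-frequency measurement noise: white noise convolved with a Gaussian
# kernel (bandwidth 0.5 degC) and rescaled to the requested pointwise SD.
# Real thermograms are smooth at the 0.1 degC step (instrument response and
# duplicate averaging), so mesh-point-independent noise would be an
# unrealistically rough emulation.
smooth_noise <- function(n, sd, bw_steps = 5) {
  if (sd <= 0) return(numeric(n))
  kern <- stats::dnorm(seq(-3 * bw_steps, 3 * bw_steps), sd = bw_steps)
  kern <- kern / sqrt(sum(kern^2))     # preserves pointwise variance
  raw <- stats::rnorm(n)
  as.numeric(stats::filter(raw, kern, sides = 2, circular = TRUE)) * sd
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate one synthetic thermogram
#'
#' Sum of three Gaussian transitions with subject-level jitter, plus the
#' latent-factor tail/valley deformation and mesh-point noise:
#' `cp(T) = sum_k A_k exp(-(T - mu_k)^2 / (2 sigma_k^2)) + z * shape(T) + noise`.
#'
#' @param config A [cohort_config].
#' @param group One of `"control"`, `"NED"`, `"active"`.
#' @param z Latent tail/valley factor (standard normal scale).
#' @param sample_id Sample id for the curve.
#' @return A single-sample [thermogram_set] on the canonical mesh. The
#'   subject's realized second-transition center is attached as attribute
#'   `mu2`.
#' @export
generate_thermogram <- function(config, group, z = 0, sample_id = "S1") {
  tt <- canonical_mesh()
  mu <- config$peak_centers
  mu[1] <- mu[1] + stats::rnorm(1, 0, config$peak13_jitter_sd)
  mu[3] <- mu[3] + stats::rnorm(1, 0, config$peak13_jitter_sd)
  shift <- if (group == "active") config$tpeak2_shift_active else 0
  # jitter truncated at +/- 2.5 SD: clinical TPeak2 spans a bounded range,
  # and an unbounded draw can degenerate the Peak1/Peak2 valley
  jit2 <- if (config$tpeak2_jitter_sd > 0) {
    rtrunc_norm(1, 0, config$tpeak2_jitter_sd,
                -2.5 * config$tpeak2_jitter_sd, 2.5 * config$tpeak2_jitter_sd)
  } else 0
  mu[2] <- mu[2] + shift + jit2
  A <- config$amplitudes * exp(stats::rnorm(3, 0, config$amp_jitter_sd))
  cp <- rowSums(vapply(1:3, function(k) {
    A[k] * exp(-(tt - mu[k])^2 / (2 * config$peak_sigmas[k]^2))
  }, numeric(length(tt))))
  # latent factor: wider Peak-3 tail, deeper Peak1/Peak2 valley
  tail_bump <- exp(-(tt - 75.5)^2 / (2 * 2.5^2))
  valley_dip <- exp(-(tt - 66.5)^2 / (2 * 1.2^2))
  cp <- cp + z * (config$peak3_tail_amp * tail_bump -
                    config$valley_depth_amp * valley_dip)
  cp <- cp + smooth_noise(length(tt), config$noise_sd)
  out <- thermogram_set(tt, cp, sample_id)
  attr(out, "mu2") <- mu[2]
  out
}

#' Generate a full synthetic cohort
#'
#' Draws thermograms, demographics and outcomes for all three groups.
#' Overall survival is Weibull with log-hazard `cox_beta * z` and uniform
#' administrative censoring; NED patients additionally receive PFS times
#' (one NED record has PFS missing, exercising the incomplete-data path).
#' The generator is a pure function of the config (including its seed).
#'
#' @param config A [cohort_config].
#' @return List: `thermograms` ([thermogram_set]), `clinical` (data.frame in
#'   the clinical-table layout), `latent` (per-sample `z` and realized
#'   transition-2 center), `truth` ([ground_truth] record).
#' @export
generate_cohort <- function(config = cohort_config()) {
  withr::with_seed(config$seed, {
    groups <- c(rep("control", config$n_control),
                rep("active", config$n_active),
                rep("NED", config$n_ned))
    n <- length(groups)
    ids <- sprintf("S%03d", seq_len(n))
    z <- stats::rnorm(n)
    cp <- matrix(NA_real_, length(canonical_mesh()), n)
    mu2 <- numeric(n)
    for (i in seq_len(n)) {
      cur <- generate_thermogram(config, groups[i], z[i], ids[i])
      cp[, i] <- cur$cp[, 1]
      mu2[i] <- attr(cur, "mu2")
    }
    ts <- thermogram_set(canonical_mesh(), cp, ids)

    age <- numeric(n); sex <- character(n)
    for (g in unique(groups)) {
      sel <- groups == g
      rng <- config$age_ranges[[g]]
      age[sel] <- round(rtrunc_norm(sum(sel), config$age_centers[[g]],
                                    config$age_sd, rng[1], rng[2]))
      sex[sel] <- ifelse(stats::runif(sum(sel)) < config$sex_prob_female[[g]],
                         "female", "male")
    }
    stage <- rep(NA_integer_, n)
    stage[groups == "active"] <- sample(c(2L, 3L, 4L), config$n_active,
                                        replace = TRUE,
                                        prob = c(0.014, 0.243, 0.743))
    stage[groups == "NED"] <- sample(c(2L, 3L), config$n_ned, replace = TRUE,
                                     prob = c(0.364, 0.636))
    n_affected <- rep(NA_character_, n)
    location <- rep(NA_character_, n)
    act <- groups == "active"
    n_affected[act] <- sample(c("1", "2", ">=3"), config$n_active,
                              replace = TRUE, prob = c(0.446, 0.257, 0.297))
    location[act] <- ifelse(n_affected[act] == "1" &
                              stats::runif(config$n_active) < 0.99,
                            "localized", "distant")

    # OS: Weibull hazard h0(t) * exp(beta z); S(t) = exp(-(t/lambda)^k e^{bz})
    k <- config$os_shape
    lambda <- config$os_median_baseline / log(2)^(1 / k)
    u <- stats::runif(n)
    t_event <- lambda * (-log(u) * exp(-config$cox_beta * z))^(1 / k)
    censor <- stats::runif(n, config$followup_range[1], config$followup_range[2])
    os_time <- pmin(t_event, censor)
    os_event <- t_event <= censor

    pfs_time <- rep(NA_real_, n)
    pfs_event <- rep(NA, n)
    ned <- which(groups == "NED")
    if (length(ned)) {
      # exponential recurrence rate targeting the configured event fraction
      # within the follow-up window
      mean_fu <- mean(config$followup_range)
      rate <- -log(1 - min(config$pfs_event_rate, 0.95)) / mean_fu
      rec <- stats::rexp(length(ned), rate)
      fu <- stats::runif(length(ned), config$followup_range[1],
                         config$followup_range[2])
      pfs_time[ned] <- pmin(rec, fu)
      pfs_event[ned] <- rec <= fu
      pfs_time[ned[1]] <- NA; pfs_event[ned[1]] <- NA  # one NED lacks PFS data
    }

    clinical <- data.frame(
      sample_id = ids,
      status = factor(groups, levels = c("control", "NED", "active")),
      sex = factor(sex, levels = c("female", "male")),
      age = age, stage = stage, n_affected = n_affected,
      location = location,
      os_time = round(os_time, 4), os_event = os_event,
      pfs_time = round(pfs_time, 4), pfs_event = pfs_event,
      stringsAsFactors = FALSE
    )
    list(thermograms = ts, clinical = clinical,
         latent = data.frame(sample_id = ids, z = z, mu2 = mu2),
         truth = ground_truth(config))
  })
}

#' Write a generated cohort to disk
#'
#' Produces `thermograms.csv`, `clinical.csv`, `latent.csv` and
#' `truth.json` under `dir`, in the formats the I/O module reads back.
#'
#' @param cohort Output of [generate_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_thermogram_matrix(cohort$thermograms, file.path(dir, "thermograms.csv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.csv(cohort$latent, file.path(dir, "latent.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
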