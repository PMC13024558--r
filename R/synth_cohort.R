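# Synthetic VGRF gait cohort generator.
#
# Emulates the statistical structure the two-stage analysis assumes:
# periodic per-sensor stride waveforms (1-2 raised-Gaussian bumps within
# stance), cycle-to-cycle amplitude variability that is *reduced* in the
# PD group in proportion to Hoehn & Yahr stage, and severity-dependent
# stride-period lengthening. Ground-truth per-subject parameters are
# returned for recovery tests. All randomness flows from one seed;
# per-subject substreams are derived by stable hashing of the subject id,
# so generation is reproducible independent of order.

default_sensor_templates <- function() {
  # One row per plantar sensor (heel -> toe). Phase values are fractions of
  # the gait cycle; stance occupies roughly the first 62%. Amplitudes are
  # per-sensor peak forces in Newtons, sized so that window-level standard
  # deviations land in the tens-to-hundred Newton range typical of
  # per-sensor VGRF summaries.
  data.frame(
    sensor = 1:8,
    center1 = c(0.07, 0.10, 0.14, 0.22, 0.32, 0.42, 0.48, 0.52),
    width1 = c(0.055, 0.060, 0.075, 0.090, 0.095, 0.080, 0.070, 0.060),
    amp1 = c(380, 330, 240, 190, 200, 260, 330, 390),
    center2 = c(NA, 0.30, NA, NA, NA, NA, NA, 0.40),
    width2 = c(NA, 0.10, NA, NA, NA, NA, NA, 0.08),
    amp2 = c(0, 60, 0, 0, 0, 0, 0, 90)
  )
}

#' Configuration for a synthetic gait cohort
#'
#' Defaults mirror the reference cohort: 93 PD and 73 control subjects,
#' PD Hoehn & Yahr stages drawn from \{1, 1.5, 2, 2.5, 3\} with mean about
#' 2.3 and SD about 0.6, VGRF sampled at 100 Hz.
#'
#' @param n_control,n_pd Group sizes.
#' @param hy_distribution Data frame with columns `stage`, `prob` over the
#'   PD Hoehn & Yahr stages; probabilities must sum to 1.
#' @param record_seconds Duration of each walking record.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param stride_period_s Population mean stride period in controls (s).
#' @param stride_period_sd Between-subject SD of the stride period (s).
#' @param cycle_jitter_cv Within-subject cycle-to-cycle period jitter (CV).
#' @param sensor_templates Per-sensor waveform shape table; see
#'   `default_sensor_templates` in the package source.
#' @param subject_amp_sd Between-subject SD of the log force scale
#'   (body-weight-like multiplicative variation shared by all channels).
#' @param amp_cv_control Cycle-to-cycle amplitude coefficient of variation
#'   in controls.
#' @param variability_suppression Per-unit-H&Y multiplicative reduction of
#'   the amplitude CV (`beta` in [0,1)): PD CV = control CV * (1 - beta*h).
#' @param speed_slowing Per-unit-H&Y stride-period lengthening
#'   (`gamma` >= 0): PD period = control period * (1 + gamma*h).
#' @param noise_sd Additive Gaussian sensor noise (N).
#' @param seed Master seed for the cohort.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_control = 73L, n_pd = 93L,
                          hy_distribution = data.frame(
                            stage = c(1, 1.5, 2, 2.5, 3),
                            prob = c(0.05, 0.10, 0.25, 0.30, 0.30)),
                          record_seconds = 60,
                          sampling_rate_hz = 100,
                          stride_period_s = 1.10,
                          stride_period_sd = 0.06,
                          cycle_jitter_cv = 0.02,
                          subject_amp_sd = 0.10,
                          sensor_templates = default_sensor_templates(),
                          amp_cv_control = 0.12,
                          variability_suppression = 0.3,
                          speed_slowing = 0.1,
                          noise_sd = 3,
                          seed = 1L) {
  cfg <- list(n_control = as.integer(n_control), n_pd = as.integer(n_pd),
              hy_distribution = hy_distribution,
              record_seconds = record_seconds, sampling_rate_hz = sampling_rate_hz,
              stride_period_s = stride_period_s, stride_period_sd = stride_period_sd,
              cycle_jitter_cv = cycle_jitter_cv, subject_amp_sd = subject_amp_sd,
              sensor_templates = sensor_templates,
              amp_cv_control = amp_cv_control,
              variability_suppression = variability_suppression,
              speed_slowing = speed_slowing, noise_sd = noise_sd,
              seed = as.integer(seed))
  assert_that(abs(sum(cfg$hy_distribution$prob) - 1) < 1e-8,
              "cohort_config: hy_distribution probabilities must sum to 1",
              class = "gaitxai_config_error")
  assert_that(cfg$n_control >= 0 && cfg$n_pd >= 0,
              "cohort_config: group sizes must be non-negative", class = "gaitxai_config_error")
  assert_that(cfg$record_seconds > 0 && cfg$sampling_rate_hz > 0 && cfg$stride_period_s > 0,
              "cohort_config: durations and rates must be positive", class = "gaitxai_config_error")
  assert_that(cfg$variability_suppression >= 0 && cfg$variability_suppression < 1,
              "cohort_config: variability_suppression must be in [0,1)", class = "gaitxai_config_error")
  assert_that(cfg$speed_slowing >= 0,
              "cohort_config: speed_slowing must be >= 0", class = "gaitxai_config_error")
  h_max <- max(cfg$hy_distribution$stage)
  assert_that(cfg$amp_cv_control >= 0 && 1 - cfg$variability_suppression * h_max > 0,
              "cohort_config: amplitude CV would be non-positive at the highest H&Y stage",
              class = "gaitxai_config_error")
  structure(cfg, class = "cohort_config")
}

# Render one foot's sensor channels for a list of cycles; returns T x 8.
render_foot <- function(time_s, starts, periods, amps, templates) {
  T <- length(time_s)
  out <- matrix(0, T, 8L)
  for (k in seq_along(starts)) {
    lo <- starts[k]; per <- periods[k]
    idx <- which(time_s >= lo & time_s < lo + per)
    if (length(idx) == 0) next
    phi <- (time_s[idx] - lo) / per
    for (c in 1:8) {
      v <- templates$amp1[c] * exp(-0.5 * ((phi - templates$center1[c]) / templates$width1[c])^2)
      if (!is.na(templates$center2[c])) {
        v <- v + templates$amp2[c] * exp(-0.5 * ((phi - templates$center2[c]) / templates$width2[c])^2)
      }
      out[idx, c] <- out[idx, c] + amps[k] * v
    }
  }
  out
}

#' Generate one subject's VGRF record from ground truth
#'
#' Strides are concatenated cycles: per-sensor raised-Gaussian bumps scaled
#' by `1 + eps_cycle` with `eps_cycle ~ N(0, CV)`, cycle period jittered,
#' left and right feet anti-phased by half a period. Total-force channels
#' are the sums of the corresponding 8 sensors before noise injection;
#' Gaussian sensor noise is then added to all 18 channels.
#'
#' @param truth One row of the cohort truth table (`subject_id`, `hy_stage`,
#'   `stride_period_s`, `amp_cv`).
#' @param config A [cohort_config()].
#' @return A [gait_signal()].
#' @export
generate_subject_signal <- function(truth, config) {
  fs <- config$sampling_rate_hz
  T <- round(config$record_seconds * fs)
  time_s <- (seq_len(T) - 1) / fs
  tmpl <- config$sensor_templates
  with_seed(derive_seed(config$seed, paste0("signal_", truth$subject_id)), {
    feet <- lapply(c(0, truth$stride_period_s / 2), function(offset) {
      starts <- c(); periods <- c(); amps <- c()
      s <- offset - truth$stride_period_s  # start one cycle early so t=0 is mid-gait
      while (s < config$record_seconds) {
        per <- truth$stride_period_s * (1 + stats::rnorm(1, 0, config$cycle_jitter_cv))
        starts <- c(starts, s); periods <- c(periods, per)
        amps <- c(amps, 1 + stats::rnorm(1, 0, truth$amp_cv))
        s <- s + per
      }
      render_foot(time_s, starts, periods, amps, tmpl)
    })
    left <- feet[[1]]; right <- feet[[2]]
    # Variability suppression: beyond damping the cycle-to-cycle amplitude
    # CV (in truth$amp_cv), severity flattens the within-cycle dynamic
    # range of each sensor toward its mean force level by the same factor
    # (1 - beta*h) — a mean-preserving contraction that reproduces the
    # rigid, low-variability PD force profile (std down, mean unchanged).
    lambda <- 1 - config$variability_suppression * truth$hy_stage
    flatten <- function(m) sweep(sweep(m, 2L, colMeans(m), "-") * lambda, 2L, colMeans(m), "+")
    left <- flatten(left) * truth$amp_scale
    right <- flatten(right) * truth$amp_scale
    channels <- cbind(left, right, rowSums(left), rowSums(right))
    channels <- channels + matrix(stats::rnorm(T * 18L, 0, config$noise_sd), T, 18L)
    gait_signal(truth$subject_id, time_s, channels, fs)
  })
}

#' Generate a synthetic gait cohort
#'
#' @param config A [cohort_config()].
#' @return A list with `signals` (list of [gait_signal()]), `table`
#'   (a [subject_table()] with clinical covariates) and `truth`
#'   (per-subject ground-truth parameters for recovery tests).
#' @export
generate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"), "generate_cohort: need a cohort_config",
              class = "gaitxai_config_error")
  ids <- c(sprintf("CO%03d", seq_len(config$n_control)),
           sprintf("PD%03d", seq_len(config$n_pd)))
  group <- rep(c("CO", "PD"), c(config$n_control, config$n_pd))
  hy <- with_seed(derive_seed(config$seed, "hy_stages"), {
    ifelse(group == "PD",
           sample(config$hy_distribution$stage, length(ids), replace = TRUE,
                  prob = config$hy_distribution$prob),
           0)
  })
  truth <- do.call(rbind, lapply(seq_along(ids), function(i) {
    with_seed(derive_seed(config$seed, paste0("subject_", ids[i])), {
      base_period <- stats::rnorm(1, config$stride_period_s, config$stride_period_sd)
      amp_scale <- exp(stats::rnorm(1, 0, config$subject_amp_sd))
      data.frame(
        subject_id = ids[i], group = group[i], hy_stage = hy[i],
        stride_period_s = base_period * (1 + config$speed_slowing * hy[i]),
        amp_cv = config$amp_cv_control * (1 - config$variability_suppression * hy[i]),
        variability_factor = 1 - config$variability_suppression * hy[i],
        amp_scale = amp_scale,
        stringsAsFactors = FALSE)
    })
  }))
  # clinical covariates: noisy correlates of stage (not used by the pipeline)
  covar <- with_seed(derive_seed(config$seed, "covariates"), {
    data.frame(
      updrs = ifelse(group == "PD", pmax(0, round(10 * hy + stats::rnorm(length(ids), 0, 4))), 0),
      tug_s = round(8 + 2.2 * hy + stats::rnorm(length(ids), 0, 1.2), 1),
      speed_m_s = round(pmax(0.3, 1.3 - 0.18 * hy + stats::rnorm(length(ids), 0, 0.08)), 2))
  })
  table <- subject_table(cbind(truth[, c("subject_id", "group", "hy_stage")], covar))
  signals <- lapply(seq_len(nrow(truth)), function(i) {
    generate_subject_signal(truth[i, ], config)
  })
  names(signals) <- ids
  list(signals = signals, table = table, truth = truth)
}

#' Write a generated cohort to disk in GaitPDB layout
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sig in cohort$signals) {
    write_vgrf_file(sig, file.path(dir, paste0(sig$subject_id, ".txt")))
  }
  write_demographics(cohort$table, file.path(dir, "demographics.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
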