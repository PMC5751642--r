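# Synthetic drinking-study generator: cohorts, hourly EMA drink reports with
# missingness, and tandem-gait inertial recordings whose sway and step-timing
# variability degrade monotonically with eBAC. Emulates a 10-subject,
# 8-evening weekend EMA protocol (hourly 8 p.m. to midnight, ~32% completion,
# episode drink totals near mean 3.6, SD 2.2, range 1-10).

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator. Defaults
#' reproduce the emulated protocol: 10 subjects observed over 8 weekend
#' evenings with five hourly EMA slots (8 p.m. to midnight), 32% EMA
#' completion, roughly half of evenings involving drinking, and episode
#' drink totals with mean 3.6 and SD 2.2 truncated to 1-10 drinks.
#'
#' @param n_subjects Number of subjects.
#' @param n_evenings Evenings per subject.
#' @param hours_per_evening Hourly EMA slots per evening.
#' @param ema_completion_rate Probability each slot is observed, in (0, 1].
#' @param drinking_evening_fraction Fraction of evenings with any drinking.
#' @param drinks_mean,drinks_sd Episode-level drink-total parameters.
#' @param drinks_min,drinks_max Truncation bounds on the episode total.
#' @param prop_female Cohort fraction of female subjects.
#' @param weight_mean,weight_sd,weight_min Body-weight distribution (pounds),
#'   truncated below at `weight_min`.
#' @param impairment_gain Fractional increase in sway amplitude and
#'   step-interval jitter per g/dL of eBAC (unitless per g/dL).
#' @param noise_sd Additive white sensor-noise SD (g for acceleration,
#'   rad for attitude).
#' @param sway_sd Baseline (sober) lateral-sway acceleration SD in g.
#' @param step_hz Gait fundamental frequency in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 10L,
                              n_evenings = 8L,
                              hours_per_evening = 5L,
                              ema_completion_rate = 0.32,
                              drinking_evening_fraction = 0.5,
                              drinks_mean = 3.6,
                              drinks_sd = 2.2,
                              drinks_min = 1L,
                              drinks_max = 10L,
                              prop_female = 0.7,
                              weight_mean = 179,
                              weight_sd = 35,
                              weight_min = 80,
                              impairment_gain = 10,
                              noise_sd = 0.02,
                              sway_sd = 0.05,
                              step_hz = 1.8,
                              sample_rate = 100L,
                              duration_s = 30,
                              seed = 1L) {
  if (ema_completion_rate <= 0 || ema_completion_rate > 1) {
    stop("'ema_completion_rate' must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(n_subjects >= 1, n_evenings >= 1, hours_per_evening >= 1,
            drinks_sd >= 0, impairment_gain >= 0, noise_sd >= 0,
            sway_sd >= 0, step_hz > 0, sample_rate > 0, duration_s > 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_evenings = as.integer(n_evenings),
         hours_per_evening = as.integer(hours_per_evening),
         ema_completion_rate = ema_completion_rate,
         drinking_evening_fraction = drinking_evening_fraction,
         drinks_mean = drinks_mean, drinks_sd = drinks_sd,
         drinks_min = as.integer(drinks_min),
         drinks_max = as.integer(drinks_max),
         prop_female = prop_female,
         weight_mean = weight_mean, weight_sd = weight_sd,
         weight_min = weight_min,
         impairment_gain = impairment_gain, noise_sd = noise_sd,
         sway_sd = sway_sd, step_hz = step_hz,
         sample_rate = as.integer(sample_rate), duration_s = duration_s,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a study cohort
#'
#' Draws subject profiles with body weights from a normal distribution
#' (mean 179 lb, SD 35 by default) truncated below at `weight_min`, and sex
#' assigned female with probability `prop_female`.
#'
#' @param config A [simulation_config()].
#' @return A list of [subject_profile()] objects, length `n_subjects`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      w <- stats::rnorm(1, config$weight_mean, config$weight_sd)
      while (w <= config$weight_min) {
        w <- stats::rnorm(1, config$weight_mean, config$weight_sd)
      }
      sex <- if (stats::runif(1) < config$prop_female) "female" else "male"
      subject_profile(sprintf("s%02d", i), sex, w)
    })
  })
}

# Draw one episode drink total: rounded truncated normal in
# [drinks_min, drinks_max]. Caller controls the RNG state.
draw_episode_total <- function(config) {
  repeat {
    d <- round(stats::rnorm(1, config$drinks_mean, config$drinks_sd))
    if (d >= config$drinks_min && d <= config$drinks_max) return(as.integer(d))
  }
}

#' Simulate hourly EMA drink reports
#'
#' For each subject and evening, decides whether it is a drinking evening
#' (probability `drinking_evening_fraction`), draws an episode drink total,
#' and spreads it over a contiguous block of early-evening hours (the
#' ascending limb). Each hourly slot is then independently observed with
#' probability `ema_completion_rate`; unobserved slots are `NA`.
#'
#' @param cohort List of [subject_profile()] from [simulate_cohort()].
#' @param config A [simulation_config()].
#' @return A list of [drink_report_series()], one per subject-evening.
#'   Each series additionally carries the generator's ground truth in a
#'   `true_drinks` field (the pre-masking hourly drinks), which
#'   [simulate_dataset()] uses to label recordings with the eBAC actually
#'   driving the simulated gait.
#' @export
simulate_reports <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_hours <- config$hours_per_evening
  with_seed(config$seed + 1L, {
    out <- vector("list", length(cohort) * config$n_evenings)
    k <- 0L
    for (p in cohort) {
      for (ev in seq_len(config$n_evenings)) {
        drinks <- integer(n_hours)
        if (stats::runif(1) < config$drinking_evening_fraction) {
          total <- draw_episode_total(config)
          start <- sample.int(min(2L, n_hours), 1L) - 1L   # hour 0 or 1
          dur <- sample.int(min(3L, n_hours - start), 1L)  # 1-3 drinking hours
          split <- stats::rmultinom(1, total, rep(1, dur))[, 1]
          drinks[start + seq_len(dur)] <- split
        }
        drinks[drinks > 30L] <- 30L  # menu cap
        true_drinks <- drinks
        observed <- stats::runif(n_hours) < config$ema_completion_rate
        drinks[!observed] <- NA_integer_
        k <- k + 1L
        series <- drink_report_series(p$subject_id, sprintf("e%02d", ev),
                                      seq_len(n_hours) - 1L, drinks)
        series$true_drinks <- true_drinks
        out[[k]] <- series
      }
    }
    out
  })
}

#' Construct a gait recording
#'
#' Paired tri-axial linear-acceleration and attitude (Euler-angle) sample
#' sequences at a fixed sampling rate.
#'
#' @param subject_id,evening_id,hour_index Identifiers.
#' @param sample_rate Sampling rate in Hz.
#' @param acceleration Numeric matrix, columns `ax`, `ay`, `az` (g).
#' @param attitude Numeric matrix, columns `roll`, `pitch`, `yaw` (rad).
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(subject_id, evening_id, hour_index,
                           sample_rate, acceleration, attitude) {
  acceleration <- as.matrix(acceleration)
  attitude <- as.matrix(attitude)
  if (nrow(acceleration) != nrow(attitude)) {
    stop("acceleration and attitude must have identical lengths",
         call. = FALSE)
  }
  if (!all(is.finite(acceleration)) || !all(is.finite(attitude))) {
    stop("all samples must be finite", call. = FALSE)
  }
  colnames(acceleration) <- c("ax", "ay", "az")
  colnames(attitude) <- c("roll", "pitch", "yaw")
  structure(
    list(subject_id = as.character(subject_id),
         evening_id = as.character(evening_id),
         hour_index = as.integer(hour_index),
         sample_rate = as.integer(sample_rate),
         acceleration = acceleration,
         attitude = attitude),
    class = "gait_recording"
  )
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s/%s/h%d: %d samples @ %d Hz\n",
              x$subject_id, x$evening_id, x$hour_index,
              nrow(x$acceleration), x$sample_rate))
  invisible(x)
}

# Low-pass smoothed zero-mean noise with target SD, length n.
smoothed_noise <- function(n, sd, alpha = 0.95) {
  x <- as.numeric(stats::filter(stats::rnorm(n), alpha, method = "recursive"))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s * sd
}

#' Simulate one tandem-gait recording
#'
#' Generates a 30 s, 100 Hz (by default) recording of a tandem walk. The
#' anteroposterior acceleration axis carries a step-periodic signal
#' (fundamental near 1.8 Hz plus two harmonics) whose instantaneous phase is
#' jittered by a random walk; the lateral axis carries zero-mean postural
#' sway, and roll/pitch carry slow body-sway oscillation. The sway standard
#' deviation and the step-interval jitter both scale as
#' `(1 + impairment_gain * ebac)`, which is the generator's defining
#' property: gait degradation is monotone in eBAC. White sensor noise with
#' SD `noise_sd` is added to all channels.
#'
#' @param ebac Estimated blood alcohol concentration in g/dL (>= 0).
#' @param profile A [subject_profile()].
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical `(ebac, profile, seed)` give
#'   bit-identical recordings.
#' @param evening_id,hour_index Optional identifiers stored in the result.
#' @return A [gait_recording()].
#' @export
simulate_gait <- function(ebac, profile, config, seed,
                          evening_id = "e00", hour_index = 0L) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "simulation_config"))
  if (!is.finite(ebac) || ebac < 0) {
    stop("'ebac' must be a non-negative finite value", call. = FALSE)
  }
  n <- as.integer(round(config$sample_rate * config$duration_s))
  dt <- 1 / config$sample_rate
  scale <- 1 + config$impairment_gain * ebac

  with_seed(seed, {
    # step-phase random walk: jitter SD grows with impairment
    jitter_sd <- 0.03 * scale
    phase <- 2 * pi * config$step_hz * dt * seq_len(n) +
      cumsum(stats::rnorm(n, 0, jitter_sd * sqrt(dt)))

    ay <- 0.50 * cos(phase) + 0.20 * cos(2 * phase + 0.8) +
      0.10 * cos(3 * phase + 1.9)                       # anteroposterior
    az <- 0.30 * cos(2 * phase + 0.3)                   # vertical bounce
    ax <- smoothed_noise(n, config$sway_sd * scale)     # lateral sway

    sway_phase <- 2 * pi * 0.5 * dt * seq_len(n) + stats::runif(1, 0, 2 * pi)
    roll <- 0.08 * scale * sin(sway_phase) +
      smoothed_noise(n, 0.02 * scale)
    pitch <- 0.06 * scale * sin(sway_phase + pi / 3) +
      smoothed_noise(n, 0.02 * scale)
    yaw <- smoothed_noise(n, 0.03)                      # heading wander

    acc <- cbind(ax, ay, az) + matrix(stats::rnorm(3 * n, 0, config$noise_sd),
                                      ncol = 3)
    att <- cbind(roll, pitch, yaw) +
      matrix(stats::rnorm(3 * n, 0, config$noise_sd), ncol = 3)

    gait_recording(profile$subject_id, evening_id, hour_index,
                   config$sample_rate, acc, att)
  })
}

#' Simulate a complete labelled dataset
#'
#' Composes [simulate_cohort()], [simulate_reports()], [ebac_trajectory()]
#' and [simulate_gait()]: for every observed EMA slot a gait recording is
#' generated at the eBAC prevailing at that hour, yielding aligned
#' recordings and labels ready for feature extraction. Because simulated
#' impairment is driven by the alcohol actually consumed, the eBAC
#' trajectory is computed from the generator's ground-truth drink series
#' (pre-masking); the missing-as-zero reporting convention of
#' [ebac_trajectory()] applies when analysing real report data.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `recordings` (list of [gait_recording()]),
#'   `labels` (numeric eBAC vector, g/dL), `meta` (data frame with
#'   `subject_id`, `evening_id`, `hour_index`, `ebac`, `limb`) and
#'   `cohort` (the subject profiles).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- simulate_cohort(config)
  profiles <- stats::setNames(cohort, vapply(cohort, `[[`, "", "subject_id"))
  reports <- simulate_reports(cohort, config)

  n_max <- length(reports) * config$hours_per_evening
  rec_seeds <- with_seed(config$seed + 2L,
                         sample.int(.Machine$integer.max, n_max))

  recordings <- list()
  meta <- vector("list", 0)
  slot <- 0L
  for (rs in reports) {
    prof <- profiles[[rs$subject_id]]
    truth <- if (is.null(rs$true_drinks)) rs else
      drink_report_series(rs$subject_id, rs$evening_id, rs$hour_index,
                          rs$true_drinks)
    traj <- ebac_trajectory(prof, truth)
    for (j in seq_along(rs$hour_index)) {
      slot <- slot + 1L
      if (is.na(rs$drinks[j])) next  # missed EMA: no walk recorded
      rec <- simulate_gait(traj$ebac[j], prof, config, rec_seeds[slot],
                           evening_id = rs$evening_id,
                           hour_index = rs$hour_index[j])
      recordings[[length(recordings) + 1L]] <- rec
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rs$subject_id, evening_id = rs$evening_id,
        hour_index = rs$hour_index[j], ebac = traj$ebac[j],
        limb = traj$limb[j], stringsAsFactors = FALSE)
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(subject_id = character(), evening_id = character(),
               hour_index = integer(), ebac = numeric(), limb = character())
  list(recordings = recordings, labels = meta$ebac, meta = meta,
       cohort = cohort)
}

#' Write a gait recording to CSV
#'
#' Columns: `t` (seconds), `ax`, `ay`, `az`, `roll`, `pitch`, `yaw`.
#'
#' @param recording A [gait_recording()].
#' @param path Output CSV path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  n <- nrow(recording$acceleration)
  df <- data.frame(t = (seq_len(n) - 1L) / recording$sample_rate,
                   recording$acceleration, recording$attitude)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gait recording from CSV
#'
#' @param path CSV path with columns `t`, `ax`, `ay`, `az`, `roll`,
#'   `pitch`, `yaw`.
#' @param subject_id,evening_id,hour_index Identifiers to attach.
#' @return A [gait_recording()].
#' @export
read_recording <- function(path, subject_id = "s00", evening_id = "e00",
                           hour_index = 0L) {
  df <- utils::read.csv(path)
  needed <- c("t", "ax", "ay", "az", "roll", "pitch", "yaw")
  if (!all(needed %in% names(df))) {
    stop("recording CSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  rate <- if (nrow(df) > 1L) round(1 / stats::median(diff(df$t))) else 100L
  gait_recording(subject_id, evening_id, hour_index, rate,
                 as.matrix(df[, c("ax", "ay", "az")]),
                 as.matrix(df[, c("roll", "pitch", "yaw")]))
}
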