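#' Default forearm channel labels
#'
#' Electrode sites used for grip-force sEMG: brachioradialis, flexor carpi
#' radialis, flexor digitorum superficialis, flexor carpi ulnaris, extensor
#' carpi ulnaris, extensor digitorum.
#' @export
semg_channels <- c("BRA", "FCR", "FDS", "FCU", "ECU", "ED")

#' Simulation configuration for a synthetic sEMG study
#'
#' Bundles every parameter of the synthetic study: cohort sizes, recording
#' setup (sampling rate, channels, trial schedule), the motor-unit pool
#' model (pool size, recruitment, rate coding, action-potential shape,
#' discharge variability, additive noise), and the sarcopenia contrast
#' factors that separate the two groups.
#'
#' The sarcopenia contrast encodes the accepted physiology of the disease:
#' denervation removes motor units (`count_factor` < 1 shrinks the pool),
#' reinnervation by surviving motoneurons enlarges the remaining units
#' (`muap_amp_scale` > 1, and the unit-size range is compressed as the pool
#' shrinks, see [build_mu_pool()]), neuromuscular-junction instability
#' raises discharge-timing variability (`jitter_factor` > 1), and the
#' fast-to-slow fibre-type shift stretches action potentials in time
#' (`duration_factor` > 1), lowering the spectral content.  Setting all
#' four factors to 1 yields a null study in which both groups are drawn
#' from the identical generating process.
#'
#' @param n_healthy,n_sarcopenic number of subjects per group.
#' @param fs sampling rate in Hz.
#' @param n_channels number of electrode channels (<= 6; labels are taken
#'   from [semg_channels]).
#' @param mvc_trials number of maximal-voluntary-contraction trials.
#' @param submax_trials_per_level sub-maximal trials at each force level.
#' @param levels sub-maximal force levels as fractions of MVC.
#' @param trial_duration sub-maximal trial length in seconds.
#' @param mvc_duration MVC trial length in seconds.
#' @param mu_count_mean mean motor-unit pool size of a healthy muscle.
#' @param recruit_range fold range of recruitment thresholds across the
#'   pool (largest / smallest threshold).
#' @param recruit_max recruitment threshold of the last unit, as a
#'   fraction of MVC.
#' @param amp_range fold range of action-potential amplitudes across a
#'   healthy pool (size principle: later-recruited units are larger).
#' @param sigma_ms_range action-potential Gaussian width (ms) from the
#'   slowest (first-recruited) to the fastest (last-recruited) unit.
#' @param firing_rate_range minimum and maximum discharge rates
#'   (pulses/s); each unit ramps linearly from the minimum at recruitment
#'   to the maximum at MVC.
#' @param isi_cv coefficient of variation of inter-spike intervals.
#' @param jitter_sd SD of per-discharge timing jitter in milliseconds
#'   (healthy value).
#' @param noise_sd SD of additive white measurement noise, in the same
#'   arbitrary amplitude units as the templates.  The default gives a
#'   signal-to-noise ratio of roughly 25 dB at MVC and 10 dB at 20% MVC
#'   for the default healthy pool.
#' @param muap_amp_scale sarcopenic multiplier on action-potential
#'   amplitudes.
#' @param count_factor sarcopenic multiplier on the pool size.
#' @param jitter_factor sarcopenic multiplier on discharge jitter.
#' @param duration_factor sarcopenic multiplier on action-potential
#'   duration.
#' @param p_male probability that a simulated subject is male.
#' @param seed integer seed making the whole study reproducible.
#' @return an object of class `semg_sim_config` (a validated list).
#' @export
simulation_config <- function(n_healthy = 45, n_sarcopenic = 48,
                              fs = 2000, n_channels = 6,
                              mvc_trials = 3, submax_trials_per_level = 2,
                              levels = c(0.2, 0.5),
                              trial_duration = 10, mvc_duration = 4,
                              mu_count_mean = 120,
                              recruit_range = 30, recruit_max = 0.75,
                              amp_range = 30,
                              sigma_ms_range = c(2.2, 1.1),
                              firing_rate_range = c(8, 30),
                              isi_cv = 0.15,
                              jitter_sd = 0.5,
                              noise_sd = 2.0,
                              muap_amp_scale = 1.6,
                              count_factor = 0.5,
                              jitter_factor = 2,
                              duration_factor = 1.3,
                              p_male = 0.35,
                              seed = 1L) {
  cfg <- list(n_healthy = as.integer(n_healthy),
              n_sarcopenic = as.integer(n_sarcopenic),
              fs = fs, n_channels = as.integer(n_channels),
              mvc_trials = as.integer(mvc_trials),
              submax_trials_per_level = as.integer(submax_trials_per_level),
              levels = sort(levels),
              trial_duration = trial_duration, mvc_duration = mvc_duration,
              mu_count_mean = mu_count_mean,
              recruit_range = recruit_range, recruit_max = recruit_max,
              amp_range = amp_range,
              sigma_ms_range = sigma_ms_range,
              firing_rate_range = firing_rate_range,
              isi_cv = isi_cv, jitter_sd = jitter_sd, noise_sd = noise_sd,
              muap_amp_scale = muap_amp_scale, count_factor = count_factor,
              jitter_factor = jitter_factor,
              duration_factor = duration_factor,
              p_male = p_male, seed = as.integer(seed))
  stopifnot(cfg$n_healthy >= 1, cfg$n_sarcopenic >= 1,
            cfg$n_channels >= 1, cfg$n_channels <= length(semg_channels),
            cfg$mvc_trials >= 1, cfg$submax_trials_per_level >= 1,
            all(cfg$levels > 0), all(cfg$levels < 1),
            cfg$fs > 2 * 500,
            cfg$trial_duration > 0, cfg$mvc_duration > 0,
            cfg$mu_count_mean >= 1,
            cfg$recruit_range > 1, cfg$recruit_max > 0, cfg$recruit_max <= 1,
            cfg$jitter_sd >= 0, cfg$noise_sd >= 0,
            length(cfg$firing_rate_range) == 2,
            diff(cfg$firing_rate_range) > 0,
            cfg$muap_amp_scale > 0, cfg$count_factor > 0,
            cfg$jitter_factor > 0, cfg$duration_factor > 0)
  class(cfg) <- "semg_sim_config"
  cfg
}

#' Null-effect variant of a simulation configuration
#'
#' Returns the same configuration with every sarcopenia contrast factor
#' set to 1, so that both groups share one generating process.
#'
#' @param config a `semg_sim_config`.
#' @return the null-effect `semg_sim_config`.
#' @export
null_config <- function(config) {
  config$muap_amp_scale <- 1
  config$count_factor <- 1
  config$jitter_factor <- 1
  config$duration_factor <- 1
  config
}

#' Build a motor-unit pool
#'
#' Draws one subject's motor-unit pool.  Recruitment thresholds follow the
#' classic exponential spread (size principle: the pool is dominated by
#' low-threshold units and thresholds rise exponentially with recruitment
#' order); action-potential amplitudes grow exponentially with recruitment
#' order; templates are first derivatives of Gaussians whose width shrinks
#' from slow, early-recruited units to fast, late-recruited ones.
#'
#' For a sarcopenic pool the size is reduced by `count_factor`, amplitudes
#' are multiplied by `muap_amp_scale`, discharge jitter by `jitter_factor`
#' and template durations by `duration_factor`.  In addition the amplitude
#' fold range is compressed to `amp_range^count_factor`: preferential
#' denervation of large fast units with reinnervation of their fibres by
#' surviving small units flattens the unit-size distribution, which is
#' what makes sub-maximal contractions of sarcopenic muscle relatively
#' "loud" once normalized to MVC.
#'
#' @param config a [simulation_config()].
#' @param group `"healthy"` or `"sarcopenic"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (so pools drawn inside a seeded study remain reproducible).
#' @return an object of class `semg_mu_pool`.
#' @export
build_mu_pool <- function(config, group, seed = NULL) {
  if (!group %in% c("healthy", "sarcopenic")) {
    stop("unknown group label: ", group)
  }
  if (!is.null(seed)) set.seed(seed)
  sarco <- group == "sarcopenic"
  f_count <- if (sarco) config$count_factor else 1
  f_amp <- if (sarco) config$muap_amp_scale else 1
  f_jit <- if (sarco) config$jitter_factor else 1
  f_dur <- if (sarco) config$duration_factor else 1

  n_mu <- max(1L, rpois(1L, config$mu_count_mean * f_count))
  u <- seq_len(n_mu) / n_mu
  # subject-to-subject variation in the recruitment spread
  rr <- config$recruit_range * exp(rnorm(1, 0, 0.15))
  thresholds <- config$recruit_max * rr^(u - 1)
  # amplitude range compression follows the pool reduction
  amp_range_eff <- config$amp_range^f_count
  amps <- f_amp * amp_range_eff^u * exp(rnorm(n_mu, 0, 0.1))
  sig <- config$sigma_ms_range
  sigma_ms <- f_dur * sig[1] * (sig[2] / sig[1])^((seq_len(n_mu) - 1) /
                                                    max(1L, n_mu - 1L))
  fs <- config$fs
  templates <- lapply(seq_len(n_mu), function(i) {
    s <- sigma_ms[i] / 1000 * fs            # width in samples
    half <- max(2L, ceiling(4 * s))
    t <- seq(-half, half)
    w <- -(t / s) * exp(-t^2 / (2 * s^2))
    amps[i] * w / max(abs(w))               # peak-normalized, scaled
  })
  n_ch <- config$n_channels
  gains <- matrix(exp(rnorm(n_mu * n_ch, 0, 0.5)), n_mu, n_ch)
  delays <- matrix(sample.int(round(0.002 * fs) + 1L, n_mu * n_ch,
                              replace = TRUE) - 1L, n_mu, n_ch)
  pool <- list(group = group, n_mu = n_mu,
               thresholds = thresholds, amps = amps, sigma_ms = sigma_ms,
               templates = templates, gains = gains, delays = delays,
               min_rate = config$firing_rate_range[1],
               max_rate = config$firing_rate_range[2],
               isi_cv = config$isi_cv,
               jitter_ms = config$jitter_sd * f_jit,
               fs = fs, n_channels = n_ch)
  class(pool) <- "semg_mu_pool"
  pool
}

# Discharge times of one unit as a renewal process with Gaussian
# inter-spike intervals (CV isi_cv) plus per-discharge jitter; seconds.
discharge_times <- function(rate, duration, isi_cv, jitter_ms) {
  mu_isi <- 1 / rate
  n_max <- ceiling(duration * rate * 1.5) + 10L
  isi <- rnorm(n_max, mu_isi, isi_cv * mu_isi)
  isi <- pmax(isi, 0.2 * mu_isi)
  t <- runif(1, 0, mu_isi) + cumsum(isi) - isi[1]
  t <- t[t < duration]
  t + rnorm(length(t), 0, jitter_ms / 1000)
}

#' Simulate one grip-force trial
#'
#' All units with recruitment threshold at or below the force level fire
#' as renewal processes; their action-potential trains, shifted and
#' attenuated per channel, are superposed and white measurement noise is
#' added.
#'
#' @param pool a [build_mu_pool()] result.
#' @param level force level as a fraction of MVC (use 1 for MVC trials).
#' @param config the study [simulation_config()].
#' @param duration trial length in seconds (defaults to the sub-maximal
#'   trial duration in `config`).
#' @param subject,trial identifiers stored in the recording.
#' @param seed optional integer seed.
#' @return an object of class `semg_recording`: channel labels, sampling
#'   rate, level tag and a channels-by-samples signal matrix.
#' @export
generate_trial <- function(pool, level, config,
                           duration = config$trial_duration,
                           subject = "S1", trial = 1L, seed = NULL) {
  stopifnot(level > 0, level <= 1)
  if (!is.null(seed)) set.seed(seed)
  fs <- pool$fs
  ns <- round(duration * fs)
  active <- which(pool$thresholds <= level)
  if (length(active) == 0L && pool$n_mu > 0L &&
      length(pool$templates) > 0L) {
    warning("force level below every recruitment threshold; ",
            "noise-only trial generated")
  }
  starts <- list()
  templates <- list()
  keep <- integer(0)
  for (i in active) {
    thr <- pool$thresholds[i]
    rate <- pool$min_rate + (pool$max_rate - pool$min_rate) *
      min(1, (level - thr) / max(1e-9, 1 - thr))
    tt <- discharge_times(rate, duration, pool$isi_cv, pool$jitter_ms)
    if (length(tt) == 0L) next
    half <- (length(pool$templates[[i]]) - 1L) %/% 2L
    starts[[length(starts) + 1L]] <- as.integer(round(tt * fs)) - half
    templates[[length(templates) + 1L]] <- pool$templates[[i]]
    keep <- c(keep, i)
  }
  n_ch <- pool$n_channels
  if (length(keep) > 0L) {
    sig <- cpp_superpose(ns, n_ch, starts, templates,
                         pool$gains[keep, , drop = FALSE],
                         matrix(as.integer(pool$delays[keep, , drop = FALSE]),
                                length(keep), n_ch))
  } else {
    sig <- matrix(0, n_ch, ns)
  }
  if (config$noise_sd > 0) {
    sig <- sig + matrix(rnorm(n_ch * ns, 0, config$noise_sd), n_ch, ns)
  }
  labels <- semg_channels[seq_len(n_ch)]
  rownames(sig) <- labels
  rec <- list(subject = subject, trial = trial,
              level = if (level >= 1) "MVC" else sprintf("%g", level),
              channels = labels, fs = fs, samples = sig,
              n_active = length(active))
  class(rec) <- "semg_recording"
  rec
}

# Group/sex-conditional AWGS measurement distributions (means and SDs of
# grip strength kg, skeletal muscle index kg/m^2 and five-times chair
# stand s in community-dwelling elderly cohorts).
awgs_params <- list(
  healthy = list(M = list(grip = c(34.1, 5.4), smi = c(7.7, 0.7),
                          cst = c(10.3, 2.7)),
                 F = list(grip = c(22.4, 3.0), smi = c(6.4, 0.6),
                          cst = c(9.7, 1.5))),
  sarcopenic = list(M = list(grip = c(23.8, 2.2), smi = c(6.5, 0.3),
                             cst = c(10.1, 3.3)),
                    F = list(grip = c(14.4, 2.8), smi = c(5.1, 0.4),
                             cst = c(10.9, 3.2))))

# Draw AWGS measurements consistent with the requested group label
# (rejection sampling against the screening rule).
draw_awgs <- function(group, sex) {
  p <- awgs_params[[group]][[sex]]
  for (i in 1:10000) {
    rec <- list(sex = sex,
                grip = max(0.1, rnorm(1, p$grip[1], p$grip[2])),
                smi = max(0.1, rnorm(1, p$smi[1], p$smi[2])),
                cst = max(0.1, rnorm(1, p$cst[1], p$cst[2])))
    if (awgs_screen(rec$sex, rec$grip, rec$smi, rec$cst) == group) {
      return(rec)
    }
  }
  stop("could not draw AWGS measurements consistent with group ", group)
}

# Per-subject seeds derived once from the study seed, shared by the
# in-memory and the streaming generation paths.
subject_seeds <- function(config) {
  set.seed(config$seed)
  n <- config$n_healthy + config$n_sarcopenic
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a single subject
#'
#' Draws sex and AWGS measurements for the requested group, builds the
#' subject's motor-unit pool and generates all MVC and sub-maximal trials.
#'
#' @inheritParams build_mu_pool
#' @param id subject identifier.
#' @param seed integer seed for this subject.
#' @return a list with `id`, `group`, `sex`, `awgs` and `trials`.
#' @export
generate_subject <- function(config, group, id, seed) {
  set.seed(seed)
  sex <- if (runif(1) < config$p_male) "M" else "F"
  awgs <- draw_awgs(group, sex)
  pool <- build_mu_pool(config, group)
  trials <- list()
  tid <- 0L
  for (k in seq_len(config$mvc_trials)) {
    tid <- tid + 1L
    trials[[tid]] <- generate_trial(pool, 1, config,
                                    duration = config$mvc_duration,
                                    subject = id, trial = tid)
  }
  for (lev in config$levels) {
    for (k in seq_len(config$submax_trials_per_level)) {
      tid <- tid + 1L
      trials[[tid]] <- generate_trial(pool, lev, config,
                                      duration = config$trial_duration,
                                      subject = id, trial = tid)
    }
  }
  list(id = id, group = group, sex = sex, awgs = awgs, trials = trials)
}

#' Simulate a complete study
#'
#' Generates `n_healthy + n_sarcopenic` subjects, each with the full trial
#' schedule.  Identical configurations (including the seed) produce
#' bit-identical studies.
#'
#' @param config a [simulation_config()].
#' @return an object of class `semg_study`: a list of subjects plus the
#'   configuration.
#' @export
simulate_study <- function(config) {
  seeds <- subject_seeds(config)
  groups <- c(rep("healthy", config$n_healthy),
              rep("sarcopenic", config$n_sarcopenic))
  ids <- sprintf("S%03d", seq_along(groups))
  subjects <- lapply(seq_along(groups), function(i) {
    generate_subject(config, groups[i], ids[i], seeds[i])
  })
  study <- list(subjects = subjects, config = config)
  class(study) <- "semg_study"
  study
}

#' @export
print.semg_study <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  cat("sEMG study:", length(x$subjects), "subjects (",
      sum(groups == "healthy"), "healthy /",
      sum(groups == "sarcopenic"), "sarcopenic ),",
      x$config$n_channels, "channels @", x$config$fs, "Hz\n")
  invisible(x)
}
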