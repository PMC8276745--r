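# per-category baseline levels of the synthetic stimulus features
LUMINANCE_LEVELS <- c(aggressive = 0.45, affiliative = 0.55, ambiguous = 0.50,
                      single_actor = 0.52, nonsocial = 0.58,
                      unclassified = 0.50, blank = 0.05, none = 0.05)
MOTION_LEVELS <- c(aggressive = 1.6, affiliative = 0.9, ambiguous = 1.1,
                   single_actor = 0.7, nonsocial = 0.5, unclassified = 0.8,
                   blank = 0, none = 0)

ar1 <- function(n, rho, sd) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive"))
}

#' Generate synthetic confound and behavior series for a session
#'
#' Emulates the measured nuisance structure of a naturalistic-viewing
#' session: frame-rate luminance and motion energy with condition-specific
#' means (their separation from the grand clip mean scales with
#' `separation`; 0 gives a null with indistinguishable condition means),
#' a frame-rate gaze trace as a reflected random walk inside the screen
#' bounds, a per-volume fixation fraction around a session-level mean, a
#' slow AR(1) CSF series, and reward pulses about every 3 s during
#' well-fixated video volumes. Deterministic given the seed.
#'
#' @param events session-clock [event_table].
#' @param config a [pipeline_config].
#' @param seed integer seed.
#' @param fixation_mean,fixation_sd subject-level mean and between-session
#'   SD of the fixation fraction.
#' @param separation scaling of the condition-mean separation of luminance
#'   and motion (1 = default synthetic effect; 0 = null).
#' @param duration_s session duration; defaults to the end of the last
#'   event.
#' @return a [confound_bundle].
#' @export
generate_confounds <- function(events, config, seed, fixation_mean = 0.9,
                               fixation_sd = 0.03, separation = 1,
                               duration_s = NULL) {
  dur <- duration_s %||% max(events$onset_s + events$duration_s)
  n_vol <- as.integer(round(dur / config$tr_s))
  fps <- config$behavior_rate_hz
  n_frames <- as.integer(round(dur * fps))
  frame_mid <- (seq_len(n_frames) - 0.5) / fps
  fidx <- interval_index(frame_mid, events$onset_s,
                                    events$duration_s)
  frame_lab <- ifelse(fidx > 0, events$category[pmax(fidx, 1L)], "none")
  clip_cats <- setdiff(unique(frame_lab), c("blank", "none"))
  with_seed(seed, {
    lum_mu <- LUMINANCE_LEVELS
    mot_mu <- MOTION_LEVELS
    if (length(clip_cats)) {
      g_l <- mean(LUMINANCE_LEVELS[clip_cats])
      g_m <- mean(MOTION_LEVELS[clip_cats])
      lum_mu[clip_cats] <- g_l + separation * (LUMINANCE_LEVELS[clip_cats] - g_l)
      mot_mu[clip_cats] <- g_m + separation * (MOTION_LEVELS[clip_cats] - g_m)
    }
    luminance <- pmin(pmax(lum_mu[frame_lab] + ar1(n_frames, 0.9, 0.03), 0), 1)
    motion <- pmax(mot_mu[frame_lab] + ar1(n_frames, 0.9, 0.1), 0)
    step <- matrix(stats::rnorm(2 * n_frames, 0, 0.15), ncol = 2)
    gaze <- apply(step, 2, cumsum)
    gaze <- 6.5 * (2 / pi) * asin(sin(gaze * pi / (2 * 6.5)))  # reflect at +-6.5 deg
    session_mean <- min(max(stats::rnorm(1, fixation_mean, fixation_sd), 0.2), 1)
    fixation <- pmin(pmax(stats::rnorm(n_vol, session_mean, 0.08), 0), 1)
    csf <- ar1(n_vol, 0.95, 1)
    lab_vol <- volume_labels(events, n_vol, config$tr_s)
    ok_vol <- which(!(lab_vol %in% c("blank", "none")) &
                      fixation >= config$fixation_min_frac)
    hit <- stats::runif(length(ok_vol)) < config$tr_s / 3
    reward <- sort((ok_vol[hit] - 1) * config$tr_s +
                     stats::runif(sum(hit), 0, config$tr_s))
    confound_bundle(unname(luminance), unname(motion), gaze, fixation, csf,
                    reward)
  })
}

#' Simulate one complete synthetic session
#'
#' Replays the unique-content schedule `n_repeats` times (runs follow the
#' four sequences in order), simulates phase-coupled BOLD with
#' [simulate_bold()] and confounds with [generate_confounds()].
#'
#' @param schedule the unique-content [event_table] from
#'   [generate_schedule()].
#' @param roster the [roi_roster].
#' @param spec a [coupling_spec].
#' @param config a [pipeline_config].
#' @param seed integer seed.
#' @param subject,session identifier strings.
#' @param n_repeats number of viewings of the unique content.
#' @param fixation_mean,fixation_sd,separation passed to
#'   [generate_confounds()].
#' @return a `session_bundle`: timeseries, events (session clock),
#'   confounds, schedule, run_sequence, subject, session.
#' @export
simulate_session <- function(schedule, roster, spec, config, seed,
                             subject = "M1", session = "s01", n_repeats = 3,
                             fixation_mean = 0.9, fixation_sd = 0.03,
                             separation = 1) {
  seq_dur <- attr(schedule, "sequence_dur_s") %||% 220
  n_runs <- attr(schedule, "n_runs") %||% max(schedule$run)
  total <- seq_dur * n_runs
  ev <- do.call(rbind, lapply(seq_len(n_repeats) - 1L, function(rep) {
    shift_events(schedule, rep * total, rep * n_runs)
  }))
  ev <- event_table(ev$onset_s, ev$duration_s, ev$category, ev$n_actors, ev$run)
  seeds <- derive_seeds(seed, 2)
  ts <- simulate_bold(ev, roster, spec, config, seeds[1], run_dur_s = seq_dur)
  conf <- generate_confounds(ev, config, seeds[2], fixation_mean,
                             fixation_sd, separation)
  structure(list(timeseries = ts, events = ev, schedule = schedule,
                 confounds = conf,
                 run_sequence = rep(seq_len(n_runs), n_repeats),
                 sequence_dur_s = seq_dur,
                 subject = subject, session = session),
            class = "session_bundle")
}

#' Simulate a complete multi-subject study
#'
#' Default design: three subjects with twelve sessions each, every session
#' presenting the same four 220-s unique sequences three times (twelve
#' 110-volume runs). Subject-level fixation behavior follows the emulated
#' study's
#' reported levels (means 0.90, 0.89, 0.62 with SDs 0.03, 0.07, 0.08).
#' All randomness derives from the single master seed.
#'
#' @param config a [pipeline_config].
#' @param spec a [coupling_spec] (default: baseline coupling only).
#' @param roster the [roi_roster].
#' @param n_subjects,sessions_per_subject,n_repeats design sizes.
#' @param seed master seed.
#' @param fixation_means,fixation_sds per-subject fixation parameters
#'   (recycled across subjects).
#' @param separation condition separation of the synthetic confounds.
#' @return a `study_bundle`: schedule, roster, spec, config and a list of
#'   `session_bundle`s.
#' @export
simulate_study <- function(config = pipeline_config(),
                           spec = default_coupling_spec(roster),
                           roster = default_roster(),
                           n_subjects = 3, sessions_per_subject = 12,
                           n_repeats = 3, seed = 1,
                           fixation_means = c(0.90, 0.89, 0.62),
                           fixation_sds = c(0.03, 0.07, 0.08),
                           separation = 1) {
  seeds <- derive_seeds(seed, 1 + n_subjects * sessions_per_subject)
  schedule <- generate_schedule(config, seeds[1])
  fixation_means <- rep_len(fixation_means, n_subjects)
  fixation_sds <- rep_len(fixation_sds, n_subjects)
  sessions <- list()
  k <- 1L
  for (m in seq_len(n_subjects)) {
    for (s in seq_len(sessions_per_subject)) {
      sessions[[k]] <- simulate_session(
        schedule, roster, spec, config, seeds[1 + k],
        subject = sprintf("M%d", m), session = sprintf("M%d_s%02d", m, s),
        n_repeats = n_repeats, fixation_mean = fixation_means[m],
        fixation_sd = fixation_sds[m], separation = separation)
      k <- k + 1L
    }
  }
  structure(list(schedule = schedule, roster = roster, spec = spec,
                 config = config, sessions = sessions, seed = seed),
            class = "study_bundle")
}
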