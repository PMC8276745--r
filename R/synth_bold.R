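#' Phase-coupling specification for the BOLD simulator
#'
#' The simulator represents each ROI's band-limited activity as a sum of
#' noisy oscillators at `base_freqs_hz`. Coupling is imposed by blending
#' each ROI's oscillator phase, as a convex combination of unit phasors,
#' from three sources: a network-wide shared phase with weight
#' `baseline_coupling`, a community-shared phase with weight equal to the
#' (hemodynamically lagged) condition boost on the ROI's designated edges,
#' and a private phase carrying the remaining weight. Designated edges are
#' grouped into communities (connected components of the designated-edge
#' graph); within a community every edge experiences the full boost, and
#' expected windowed synchrony increases monotonically with the total
#' shared weight.
#'
#' @param designated_edges data.frame with columns `i`, `j` (1-based ROI
#'   indices) naming the edges that receive condition boosts; may be empty.
#' @param baseline_coupling network-wide baseline phase-sharing weight in
#'   `[0, 1]`.
#' @param condition_boost named numeric vector mapping condition labels to
#'   boost weights; `baseline_coupling + max(boost)` must not exceed 1.
#' @param base_freqs_hz oscillator frequencies (defaults 0.02 and 0.04 Hz,
#'   the spectral peaks the simulator emulates).
#' @param amplitudes oscillator amplitudes (BOLD units).
#' @param noise_sd white measurement noise SD (BOLD units).
#' @param drive_amplitude amplitude of the shared HRF-convolved video-on
#'   evoked response (BOLD units).
#' @param phase_jitter_rad phase-diffusion SD in rad/sqrt(s), recycled
#'   across base frequencies (the default narrows the 0.04 Hz line so both
#'   spectral peaks stay resolvable).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(designated_edges = NULL, baseline_coupling = 0.15,
                          condition_boost = c(ambiguous = 0),
                          base_freqs_hz = c(0.02, 0.04),
                          amplitudes = c(1, 0.9), noise_sd = 0.5,
                          drive_amplitude = 0.3,
                          phase_jitter_rad = c(0.45, 0.3)) {
  if (is.null(designated_edges)) {
    designated_edges <- data.frame(i = integer(0), j = integer(0))
  }
  if (baseline_coupling < 0 || baseline_coupling > 1) {
    stop_sync("baseline_coupling must lie in [0, 1]")
  }
  if (any(condition_boost < 0) ||
      baseline_coupling + max(c(condition_boost, 0)) > 1 + 1e-12) {
    stop_sync("condition boosts must be >= 0 with baseline + boost <= 1")
  }
  if (length(amplitudes) != length(base_freqs_hz)) {
    stop_sync("amplitudes and base_freqs_hz must have equal length")
  }
  if (noise_sd < 0 || drive_amplitude < 0) stop_sync("negative noise/drive")
  phase_jitter_rad <- rep_len(phase_jitter_rad, length(base_freqs_hz))
  structure(list(designated_edges = designated_edges,
                 baseline_coupling = baseline_coupling,
                 condition_boost = condition_boost,
                 base_freqs_hz = base_freqs_hz, amplitudes = amplitudes,
                 noise_sd = noise_sd, drive_amplitude = drive_amplitude,
                 phase_jitter_rad = phase_jitter_rad),
            class = "coupling_spec")
}

#' Default coupling specification for the 16-ROI roster
#'
#' Designates 18 cingulate-temporal and temporo-temporal edges, arranged
#' as four vertex-disjoint cliques (one cingulate ROI plus one to four
#' temporal ROIs each: 10 + 6 + 1 + 1 edges) so that boosting them leaves
#' every non-designated edge uncoupled beyond baseline. The boosted
#' condition defaults to ambiguous behavior with boost `delta`.
#'
#' @param roster the [default_roster()] (or any roster with at least four
#'   cingulate and nine temporal ROIs).
#' @param delta boost weight for the boosted condition.
#' @param condition boosted condition label.
#' @param ... passed to [coupling_spec()].
#' @return a `coupling_spec` with 18 designated edges.
#' @export
default_coupling_spec <- function(roster = default_roster(), delta = 0,
                                  condition = "ambiguous", ...) {
  cing <- which(roster$group == "cingulate")
  temp <- which(roster$group == "temporal")
  if (length(cing) < 4 || length(temp) < 9) {
    stop_sync("default designated-edge layout needs >= 4 cingulate and >= 9 temporal ROIs")
  }
  cliques <- list(c(cing[1], temp[1:4]), c(cing[2], temp[5:7]),
                  c(cing[3], temp[8]), c(cing[4], temp[9]))
  ed <- do.call(rbind, lapply(cliques, function(v) {
    v <- sort(v)
    ei <- edge_index(length(v))
    data.frame(i = v[ei$i], j = v[ei$j])
  }))
  boost <- stats::setNames(delta, condition)
  coupling_spec(designated_edges = ed, condition_boost = boost, ...)
}

# connected components of the designated-edge graph -> community id per ROI
# (0 = not in any community)
edge_communities <- function(designated_edges, n_rois) {
  A <- matrix(0L, n_rois, n_rois)
  if (nrow(designated_edges)) {
    A[cbind(designated_edges$i, designated_edges$j)] <- 1L
    A[cbind(designated_edges$j, designated_edges$i)] <- 1L
  }
  comp <- graph_components(A)
  in_comm <- rowSums(A) > 0
  ids <- integer(n_rois)
  ids[in_comm] <- match(comp[in_comm], sort(unique(comp[in_comm])))
  ids
}

# noisy oscillator phase: linear drift at freq_hz plus Brownian jitter
random_phase <- function(n, freq_hz, tr_s, jitter) {
  stats::runif(1, -pi, pi) +
    cumsum(2 * pi * freq_hz * tr_s + stats::rnorm(n, 0, jitter * sqrt(tr_s)))
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Simulate phase-coupled ROI BOLD for an event schedule
#'
#' Each ROI's signal is a sum of oscillators at the spec's base
#' frequencies whose phases are convex phasor blends of a network-shared,
#' a community-shared and a private noisy oscillator (see
#' [coupling_spec()]), plus an HRF-convolved video-on evoked response
#' shared by all ROIs and white noise. The community-shared weight follows
#' the boosted condition's event time course convolved with the gamma
#' hemodynamic kernel, so simulated coupling changes lag clip onsets
#' hemodynamically. Runs are simulated independently. Deterministic given
#' the seed.
#'
#' @param events an [event_table] with a `run` column covering the session.
#' @param roster the [roi_roster].
#' @param spec a [coupling_spec].
#' @param config a [pipeline_config].
#' @param seed integer seed.
#' @param run_dur_s duration of each run, seconds.
#' @return an [roi_ts]; the attribute `truth` records the spec, the
#'   per-volume boost weight and the designated edges.
#' @export
simulate_bold <- function(events, roster, spec, config, seed,
                          run_dur_s = 220) {
  stopifnot(inherits(spec, "coupling_spec"))
  n_rois <- nrow(roster)
  runs <- sort(unique(events$run))
  if (any(is.na(runs))) stop_sync("events need a run column")
  vol_per_run <- as.integer(round(run_dur_s / config$tr_s))
  n_vol <- vol_per_run * length(runs)
  comm <- edge_communities(spec$designated_edges, n_rois)
  n_comm <- max(comm, 0L)
  boosted_cond <- names(spec$condition_boost)
  lab <- volume_labels(events, n_vol, config$tr_s)
  kernel <- gamma_hrf(config, dt = config$tr_s)
  boost_series <- rep(0, n_vol)
  for (bc in boosted_cond) {
    if (spec$condition_boost[[bc]] > 0) {
      ind <- as.numeric(lab == bc)
      boost_series <- boost_series + spec$condition_boost[[bc]] *
        as.numeric(convolve_causal(matrix(ind), kernel))
    }
  }
  boost_series <- pmin(boost_series, 1 - spec$baseline_coupling)
  video_on <- as.numeric(!(lab %in% c("blank", "none")))
  drive <- spec$drive_amplitude *
    as.numeric(convolve_causal(matrix(video_on), kernel))

  w_g <- spec$baseline_coupling
  nf <- length(spec$base_freqs_hz)
  x <- with_seed(seed, {
    out <- matrix(0, n_vol, n_rois)
    for (r in seq_along(runs)) {
      idx <- ((r - 1) * vol_per_run + 1):(r * vol_per_run)
      V <- vol_per_run
      wb_run <- boost_series[idx]
      for (f in seq_len(nf)) {
        fr <- spec$base_freqs_hz[f]
        dphi <- 2 * pi * fr * config$tr_s
        jit_f <- spec$phase_jitter_rad[f]
        psi_g <- random_phase(V, fr, config$tr_s, jit_f)
        # community phases are themselves pulled toward the global phase
        # with the baseline weight, so boosting a community does not drain
        # its members' baseline network-wide coherence
        psi_c <- if (n_comm > 0) {
          vapply(seq_len(n_comm), function(cc) {
            pc <- numeric(V)
            nz <- stats::rnorm(V, 0, jit_f * sqrt(config$tr_s))
            z0 <- stats::runif(1, -pi, pi)
            pc[1] <- z0 + w_g * wrap_pi(psi_g[1] - z0)
            for (t in 2:V) {
              zc <- pc[t - 1] + dphi + nz[t]
              pc[t] <- zc + w_g * wrap_pi(psi_g[t] - zc)
            }
            pc
          }, numeric(V))
        } else NULL
        # incremental circular-weighted blend: each volume, every ROI's
        # phase advances privately, then moves the fraction w_g of the
        # remaining angular gap toward the network-shared phase and the
        # fraction w_b(t) toward its community-shared phase; w_g = 1 pins
        # the phase to the shared oscillator exactly
        noise <- matrix(stats::rnorm(V * n_rois, 0,
                                     jit_f * sqrt(config$tr_s)),
                        V, n_rois)
        in_comm <- as.numeric(comm > 0)
        tc_mat <- matrix(0, V, n_rois)
        if (n_comm > 0) tc_mat[, comm > 0] <- psi_c[, comm[comm > 0]]
        z <- stats::runif(n_rois, -pi, pi)
        phi <- matrix(0, V, n_rois)
        wb <- wb_run[1] * in_comm
        phi[1, ] <- z + w_g * wrap_pi(psi_g[1] - z) +
          wb * wrap_pi(tc_mat[1, ] - z)
        for (t in 2:V) {
          z <- phi[t - 1, ] + dphi + noise[t, ]
          wb <- wb_run[t] * in_comm
          phi[t, ] <- z + w_g * wrap_pi(psi_g[t] - z) +
            wb * wrap_pi(tc_mat[t, ] - z)
        }
        out[idx, ] <- out[idx, ] + spec$amplitudes[f] * cos(phi)
      }
    }
    out + drive + matrix(stats::rnorm(n_vol * n_rois, 0, spec$noise_sd),
                         n_vol, n_rois)
  })
  ts <- roi_ts(x, tr_s = config$tr_s,
               run_starts = (seq_along(runs) - 1L) * vol_per_run,
               roi_labels = roster$label)
  attr(ts, "truth") <- list(spec = spec, boost_series = boost_series,
                            designated_edges = spec$designated_edges,
                            communities = comm)
  ts
}
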