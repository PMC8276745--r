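#' Instantaneous phase of the analytic signal
#'
#' Discrete analytic signal by the frequency-domain method (zeroing
#' negative frequencies and doubling positive ones); the phase is the
#' complex argument, wrapped to (-pi, pi].
#'
#' @param x numeric vector.
#' @return phase vector in radians.
#' @export
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

# Band-limiting filter for phase estimation. The upper band edge is clamped
# just below the Nyquist frequency of the volume sampling rate; when the
# configured upper edge reaches Nyquist (the default 0.5 Hz at TR = 2 s)
# the filter reduces to a 4th-order high-pass at the lower edge.
design_band_filter <- function(config) {
  nyq <- 1 / (2 * config$tr_s)
  lo <- config$band_lo_hz / nyq
  hi <- config$band_hi_hz / nyq
  if (hi >= 0.98) {
    signal::butter(4, lo, type = "high")
  } else {
    signal::butter(4, c(lo, hi), type = "pass")
  }
}

mirror_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
}

#' Band-limited instantaneous phase per ROI
#'
#' Per run and ROI: zero-phase band-pass filtering (forward-backward
#' 4th-order Butterworth) to the configured band, then the analytic-signal
#' phase. Each run is mirror-padded by one window length before filtering
#' and phase extraction to suppress edge transients, and the pad is
#' discarded. No phase is ever estimated across a run boundary.
#'
#' @param ts an [roi_ts] (typically residualized).
#' @param config a [pipeline_config].
#' @return object of class `phase_matrix`: phases (volumes x ROIs, radians),
#'   plus the run structure and band.
#' @export
instantaneous_phase <- function(ts, config) {
  stopifnot(inherits(ts, "roi_ts"))
  W <- window_volumes(config)
  rr <- run_ranges(ts)
  short <- rr$end - rr$start + 1L < 2L * W
  if (any(short)) {
    stop_sync("run(s) %s shorter than two window lengths (%d volumes)",
              paste(rr$run[short], collapse = ", "), 2L * W)
  }
  bf <- design_band_filter(config)
  if (!is.null(config$highpass_s)) {
    hp <- signal::butter(2, (1 / config$highpass_s) / (1 / (2 * config$tr_s)),
                         type = "high")
  }
  phases <- matrix(NA_real_, n_volumes(ts), ncol(ts$values))
  for (r in seq_len(nrow(rr))) {
    idx <- rr$start[r]:rr$end[r]
    for (k in seq_len(ncol(ts$values))) {
      x <- ts$values[idx, k]
      if (!is.null(config$highpass_s)) x <- signal::filtfilt(hp, x)
      xp <- mirror_pad(x, W)
      pad <- (length(xp) - length(x)) / 2
      xf <- signal::filtfilt(bf, xp)
      ph <- analytic_phase(xf)
      phases[idx, k] <- ph[(pad + 1):(pad + length(x))]
    }
  }
  structure(list(phases = phases, tr_s = ts$tr_s, run_starts = ts$run_starts,
                 band = c(config$band_lo_hz, config$band_hi_hz),
                 roi_labels = ts$roi_labels),
            class = "phase_matrix")
}

#' Sliding-window phase synchrony tensor
#'
#' For every ROI pair and every window of `window_s` seconds (advancing by
#' `window_step_s`), the phase-locking value: the modulus of the average
#' unit phasor of the within-window phase difference. 1 means perfect
#' locking; independent phases give values near `sqrt(pi / (4 N))` for
#' N-sample windows. Windows never straddle run boundaries; a run of V
#' volumes yields `V - W + 1` windows at a one-volume step. Window centers
#' are timestamped at the midpoint of the covered interval.
#'
#' @param phases a `phase_matrix` from [instantaneous_phase()].
#' @param config a [pipeline_config].
#' @return object of class `synchrony_tensor`: `values` (edges x windows),
#'   `window_center_s`, `window_run`, `edges`, `window_len_volumes`,
#'   `transformed` flag.
#' @export
windowed_synchrony <- function(phases, config) {
  stopifnot(inherits(phases, "phase_matrix"))
  W <- window_volumes(config)
  S <- step_volumes(config)
  R <- ncol(phases$phases)
  ed <- edge_index(R)
  E <- exp(1i * phases$phases)
  n <- nrow(phases$phases)
  run_start_idx <- phases$run_starts + 1L
  run_end_idx <- c(phases$run_starts[-1], n)
  vals <- list(); centers <- list(); runs <- list()
  for (r in seq_along(run_start_idx)) {
    idx <- run_start_idx[r]:run_end_idx[r]
    V <- length(idx)
    nW <- (V - W) %/% S + 1L
    Z <- E[idx, ed$i, drop = FALSE] * Conj(E[idx, ed$j, drop = FALSE])
    cs <- rbind(0, apply(Z, 2, cumsum))
    starts <- (seq_len(nW) - 1L) * S
    w <- (cs[starts + W + 1L, , drop = FALSE] - cs[starts + 1L, , drop = FALSE]) / W
    plv <- t(Mod(w))
    if (config$plv_estimator == "circvar") plv <- 1 - plv
    vals[[r]] <- plv
    centers[[r]] <- (run_start_idx[r] - 1L + starts + W / 2) * phases$tr_s
    runs[[r]] <- rep(r, nW)
  }
  structure(list(values = do.call(cbind, vals),
                 window_center_s = unlist(centers),
                 window_run = unlist(runs),
                 edges = ed,
                 edge_labels = paste(phases$roi_labels[ed$i],
                                     phases$roi_labels[ed$j], sep = "--"),
                 window_len_volumes = W, tr_s = phases$tr_s,
                 transformed = FALSE),
            class = "synchrony_tensor")
}

#' @export
print.synchrony_tensor <- function(x, ...) {
  cat(sprintf("<synchrony_tensor> %d edges x %d windows (%d-volume windows%s)\n",
              nrow(x$values), ncol(x$values), x$window_len_volumes,
              if (x$transformed) ", arcsine-transformed" else ""))
  invisible(x)
}

# design columns sampled at the window-center volumes
design_at_centers <- function(design, tensor) {
  v <- floor(tensor$window_center_s / tensor$tr_s) + 1L
  v <- pmin(pmax(v, 1L), nrow(design$values))
  design$values[v, , drop = FALSE]
}

#' Remove nuisance structure from synchrony time series
#'
#' Per edge, OLS residuals of the synchrony series on an intercept plus the
#' luminance, motion, gaze-change and fixation regressors (sampled at each
#' window's center volume), with the intercept fitted value added back so
#' cleaned values stay on the synchrony scale. Residuals are orthogonal to
#' every nuisance column in-sample.
#'
#' @param tensor a `synchrony_tensor` (untransformed).
#' @param design a `regressor_matrix` on the same session's volume grid.
#' @param config a [pipeline_config].
#' @param nuisance nuisance column names to use.
#' @return the cleaned `synchrony_tensor`.
#' @export
clean_synchrony <- function(tensor, design, config,
                            nuisance = c("luminance", "motion",
                                         "gaze_change", "fixation_frac")) {
  stopifnot(inherits(tensor, "synchrony_tensor"))
  miss <- setdiff(nuisance, colnames(design$values))
  if (length(miss)) stop_sync("design lacks nuisance column(s): %s",
                              paste(miss, collapse = ", "))
  N <- design_at_centers(design, tensor)[, nuisance, drop = FALSE]
  # mean-center the nuisance columns so the intercept added back below is
  # exactly each edge's mean synchrony
  N <- sweep(N, 2, colMeans(N))
  X <- cbind(intercept = 1, N)
  keep <- c(TRUE, apply(N, 2, function(c) stats::sd(c) > 0))
  fit <- ols_residualize(t(tensor$values), X[, keep, drop = FALSE],
                         warn_drop = FALSE)
  b0 <- fit$coef[1, ]
  tensor$values <- t(fit$resid) + b0
  tensor
}

#' Variance-stabilizing arcsine transform
#'
#' Maps each synchrony value r to `asin(r)` (or `asin(sqrt(r))` when
#' `config$arcsine_sqrt` is set), a strictly monotone map of `[0, 1]` onto
#' `[0, pi/2]` that decompresses values near the extremes. Values pushed
#' outside `[0, 1]` by nuisance cleaning are clipped first; the clip count
#' is recorded in the `n_clipped` attribute.
#'
#' @param tensor a `synchrony_tensor` with `transformed = FALSE`.
#' @param config a [pipeline_config].
#' @return the transformed tensor (`transformed = TRUE`).
#' @export
arcsine_transform <- function(tensor, config = pipeline_config()) {
  stopifnot(inherits(tensor, "synchrony_tensor"))
  if (tensor$transformed) stop_sync("tensor already arcsine-transformed")
  v <- tensor$values
  n_clip <- sum(v < 0 | v > 1)
  v <- pmin(pmax(v, 0), 1)
  tensor$values <- if (config$arcsine_sqrt) asin(sqrt(v)) else asin(v)
  tensor$transformed <- TRUE
  attr(tensor, "n_clipped") <- n_clip
  tensor
}

#' Average synchrony across repeated viewings
#'
#' Runs replay a small set of unique video sequences. Given the sequence
#' identity of each run, windows are mapped onto the unique-content clock
#' (sequence start + within-run offset) and averaged pointwise across
#' repeats. All repeats of a sequence must present identical within-run
#' window grids.
#'
#' @param tensor a `synchrony_tensor` over all runs of a session.
#' @param run_sequence integer vector, one unique-sequence id per run.
#' @param sequence_dur_s duration of one unique sequence, seconds.
#' @return a `synchrony_tensor` on the unique-content clock.
#' @export
average_repeats <- function(tensor, run_sequence, sequence_dur_s = 220) {
  stopifnot(inherits(tensor, "synchrony_tensor"))
  n_runs <- max(tensor$window_run)
  if (length(run_sequence) != n_runs) {
    stop_sync("run_sequence length (%d) != number of runs (%d)",
              length(run_sequence), n_runs)
  }
  run_t0 <- tapply(tensor$window_center_s, tensor$window_run, min)
  seqs <- sort(unique(run_sequence))
  out_vals <- list(); out_centers <- list(); out_run <- list()
  for (s in seqs) {
    rs <- which(run_sequence == s)
    offs <- lapply(rs, function(r) {
      w <- which(tensor$window_run == r)
      tensor$window_center_s[w] - tensor$window_center_s[w][1]
    })
    if (length(unique(vapply(offs, length, 1L))) != 1 ||
        any(vapply(offs[-1], function(o) max(abs(o - offs[[1]])), 0) > 1e-9)) {
      stop_sync("repeats of sequence %d have misaligned window timelines", s)
    }
    acc <- 0
    for (r in rs) acc <- acc + tensor$values[, tensor$window_run == r, drop = FALSE]
    first_w <- which(tensor$window_run == rs[1])
    out_vals[[as.character(s)]] <- acc / length(rs)
    out_centers[[as.character(s)]] <- (s - 1) * sequence_dur_s +
      (tensor$window_center_s[first_w] - run_t0[[as.character(rs[1])]]) +
      tensor$window_len_volumes / 2 * tensor$tr_s
    out_run[[as.character(s)]] <- rep(s, length(first_w))
  }
  structure(list(values = do.call(cbind, out_vals),
                 window_center_s = unlist(out_centers),
                 window_run = unlist(out_run),
                 edges = tensor$edges, edge_labels = tensor$edge_labels,
                 window_len_volumes = tensor$window_len_volumes,
                 tr_s = tensor$tr_s, transformed = tensor$transformed),
            class = "synchrony_tensor")
}

#' Global network synchrony summaries
#'
#' Per window, the mean and the (population) variance of synchrony across
#' all edges: the two global traces used to visualize network-wide
#' dynamics.
#'
#' @param tensor a `synchrony_tensor` with at least 2 edges.
#' @return list with `mean_series` and `variance_series`.
#' @export
network_summary <- function(tensor) {
  stopifnot(inherits(tensor, "synchrony_tensor"))
  if (nrow(tensor$values) < 2) stop_sync("need at least 2 edges")
  m <- colMeans(tensor$values)
  v <- colMeans(tensor$values^2) - m^2
  list(mean_series = m, variance_series = pmax(v, 0))
}

#' Assign each window to a stimulus state
#'
#' Under the default `"center"` rule a window carries the category of the
#' event covering its center volume after shifting events forward by the
#' hemodynamic lag. Under `"majority"`, more than `state_min_frac` of the
#' window's volumes must carry the label.
#'
#' @param tensor a `synchrony_tensor`.
#' @param events an [event_table] on the same clock as the tensor.
#' @param config a [pipeline_config].
#' @return character vector, one label per window (`"none"` if unassigned).
#' @export
assign_windows <- function(tensor, events, config) {
  lag <- config$hemo_lag_s
  if (config$state_rule == "center") {
    lab <- rep("none", ncol(tensor$values))
    on <- events$onset_s + lag
    off <- on + events$duration_s
    t <- tensor$window_center_s
    for (k in seq_len(nrow(events))) {
      lab[t >= on[k] & t < off[k]] <- events$category[k]
    }
    lab
  } else {
    W <- tensor$window_len_volumes
    half <- W / 2 * tensor$tr_s
    vapply(seq_along(tensor$window_center_s), function(w) {
      t0 <- tensor$window_center_s[w] - half
      vols <- t0 + (seq_len(W) - 0.5) * tensor$tr_s
      lab <- rep("none", W)
      on <- events$onset_s + lag
      off <- on + events$duration_s
      for (k in seq_len(nrow(events))) {
        lab[vols >= on[k] & vols < off[k]] <- events$category[k]
      }
      tb <- table(lab)
      top <- names(tb)[which.max(tb)]
      if (tb[top] > config$state_min_frac * W && top != "none") top else "none"
    }, character(1))
  }
}

#' State-specific mean network and suprathreshold structure
#'
#' Averages each edge's synchrony over the windows assigned to the given
#' state(s), binarizes at the strongest `top_edge_frac` of edges, and
#' summarizes the suprathreshold connections by anatomical lobe pairing
#' (interhemispheric and intrahemispheric temporo-temporal,
#' fronto-temporal, fronto-frontal, other); the reported proportions sum
#' to 1.
#'
#' @param tensor a `synchrony_tensor`.
#' @param events an [event_table] on the tensor's clock.
#' @param state character vector of category labels defining the state.
#' @param roster the [roi_roster].
#' @param config a [pipeline_config].
#' @return list with `edge_means`, `network` (a `binary_network`),
#'   `proportions` (named fractions), `n_windows`.
#' @export
state_network <- function(tensor, events, state, roster, config) {
  lab <- assign_windows(tensor, events, config)
  sel <- lab %in% state
  if (!any(sel)) stop_sync("no windows assigned to state: %s",
                           paste(state, collapse = "/"))
  edge_means <- rowMeans(tensor$values[, sel, drop = FALSE])
  net <- threshold_by_value(edge_means, tensor$edges, nrow(roster),
                            config$top_edge_frac,
                            labels = roster$label,
                            provenance = sprintf("top %.0f%% during state %s",
                                                 100 * config$top_edge_frac,
                                                 paste(state, collapse = "/")))
  keep <- net$selected
  lobe <- roi_lobe(roster)
  l1 <- lobe[tensor$edges$i[keep]]
  l2 <- lobe[tensor$edges$j[keep]]
  same_hemi <- roster$hemisphere[tensor$edges$i[keep]] ==
    roster$hemisphere[tensor$edges$j[keep]]
  cls <- ifelse(l1 == "temporal" & l2 == "temporal",
                ifelse(same_hemi, "temporo-temporal intrahemispheric",
                       "temporo-temporal interhemispheric"),
                ifelse(l1 == "frontal" & l2 == "frontal", "fronto-frontal",
                       ifelse((l1 == "frontal") != (l2 == "frontal"),
                              "fronto-temporal", "other")))
  props <- table(factor(cls, levels = c("temporo-temporal interhemispheric",
                                        "temporo-temporal intrahemispheric",
                                        "fronto-temporal", "fronto-frontal",
                                        "other"))) / sum(keep)
  list(edge_means = edge_means, network = net,
       proportions = c(props), n_windows = sum(sel))
}
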