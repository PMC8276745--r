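#' Gamma hemodynamic kernel
#'
#' The hemodynamic response is modeled as a gamma density parameterized by
#' its mean lag and SD (defaults 3 s and 1.5 s), the unique two-parameter
#' gamma with those moments: shape `(mean/sd)^2`, scale `sd^2/mean`. The
#' kernel is sampled on a `dt` grid, truncated at `trunc_s` and renormalized
#' to unit sum so convolution preserves the scale of sustained input.
#'
#' @param config a [pipeline_config] (supplies mean lag and SD).
#' @param dt sample step in seconds (defaults to the TR).
#' @param trunc_s truncation length in seconds.
#' @return numeric kernel vector, `sum(kernel) == 1`.
#' @export
gamma_hrf <- function(config, dt = config$tr_s, trunc_s = 30) {
  shape <- (config$hrf_mean_lag_s / config$hrf_sd_s)^2
  scale <- config$hrf_sd_s^2 / config$hrf_mean_lag_s
  tt <- seq(0, trunc_s, by = dt)
  k <- stats::dgamma(tt, shape = shape, scale = scale)
  k / sum(k)
}

# causal same-length convolution of each column with a kernel
convolve_causal <- function(x, kernel) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- apply(x, 2, function(col) {
    stats::convolve(col, rev(kernel), type = "open")[seq_len(n)]
  })
  matrix(out, nrow = n, dimnames = dimnames(x))
}

#' Per-volume regressor matrix
#'
#' Named design columns at the volume rate (0.5 Hz for TR = 2 s), with a
#' per-column flag recording whether the hemodynamic convolution has been
#' applied yet. Stimulus-derived columns are binary before convolution.
#'
#' @param columns named list or data.frame of equal-length numeric columns.
#' @param rate_hz sampling rate of the columns.
#' @param convolved logical flag per column.
#' @return an object of class `regressor_matrix`.
#' @export
regressor_matrix <- function(columns, rate_hz, convolved = NULL) {
  m <- as.matrix(as.data.frame(columns))
  if (is.null(convolved)) convolved <- rep(FALSE, ncol(m))
  if (length(convolved) != ncol(m)) stop_sync("convolved flag length mismatch")
  structure(list(values = m, rate_hz = rate_hz,
                 convolved = stats::setNames(as.logical(convolved), colnames(m))),
            class = "regressor_matrix")
}

#' Build the per-volume design matrix from events and confounds
#'
#' Produces, at the volume rate, the stimulus and behavior regressors used
#' throughout the pipeline: a binary video ON/OFF column; frame-level
#' luminance averaged within each volume; frame-level motion energy summed
#' within each volume; exclusive actor-count indicators (`actors_0`,
#' `actors_1`, `actors_2plus`); one binary indicator per social behavior
#' (`beh_aggressive`, `beh_affiliative`, `beh_ambiguous`); gaze change as
#' the summed Euclidean step distance of the eye trace per volume; and the
#' fixation fraction itself. All columns are unconvolved.
#'
#' @param events an [event_table] on the session clock.
#' @param confounds a [confound_bundle] for the same session.
#' @param config a [pipeline_config].
#' @param n_vol number of volumes; defaults to the confound volume grid.
#' @return a `regressor_matrix`.
#' @export
build_design <- function(events, confounds, config, n_vol = NULL) {
  n_vol <- n_vol %||% length(confounds$csf)
  tr <- config$tr_s
  fpv <- config$behavior_rate_hz * tr     # frames per volume
  need_frames <- ceiling(n_vol * fpv)
  if (length(confounds$luminance) < need_frames) {
    stop_sync("frame series too short: %d frames for %d volumes at %g Hz",
              length(confounds$luminance), n_vol, config$behavior_rate_hz)
  }
  if (length(confounds$fixation_frac) != n_vol) {
    stop_sync("fixation_frac length (%d) != n_volumes (%d)",
              length(confounds$fixation_frac), n_vol)
  }
  # frames-per-volume is integral for all supported rates; reduce by
  # reshaping the frame series into an fpv x n_vol matrix
  fpv_i <- as.integer(round(fpv))
  if (abs(fpv - fpv_i) > 1e-9) {
    stop_sync("behavior_rate_hz * tr_s must be an integer (got %g)", fpv)
  }
  vol_sum <- function(x) colSums(matrix(x[seq_len(fpv_i * n_vol)], nrow = fpv_i))
  vol_mean <- function(x) vol_sum(x) / fpv_i

  idx <- volume_event_index(events, n_vol, tr)
  lab <- ifelse(idx > 0, events$category[pmax(idx, 1L)], "none")
  video_on <- as.numeric(!(lab %in% c("blank", "none")))
  act <- ifelse(video_on > 0, events$n_actors[pmax(idx, 1L)], "off")
  step <- sqrt(rowSums(diff(confounds$gaze_xy)^2))
  gaze_change <- vol_sum(c(0, step))

  regressor_matrix(list(
    video_on = video_on,
    luminance = vol_mean(confounds$luminance),
    motion = vol_sum(confounds$motion),
    actors_0 = as.numeric(act == "0"),
    actors_1 = as.numeric(act == "1"),
    actors_2plus = as.numeric(act == "2+"),
    beh_aggressive = as.numeric(lab == "aggressive"),
    beh_affiliative = as.numeric(lab == "affiliative"),
    beh_ambiguous = as.numeric(lab == "ambiguous"),
    gaze_change = gaze_change,
    fixation_frac = confounds$fixation_frac
  ), rate_hz = 1 / tr)
}

#' Zero regressors during poorly fixated volumes
#'
#' Volumes in which the subject fixated for less than
#' `config$fixation_min_frac` of the volume (strictly below; exactly the
#' threshold is retained) are set to zero in every unconvolved column.
#' Masking must precede hemodynamic convolution, so convolved input is an
#' error. When `config$mask_confounds` is `FALSE`, the continuous confound
#' columns (luminance, motion, gaze change) are left unmasked.
#'
#' @param matrix a `regressor_matrix` with unconvolved columns.
#' @param fixation_frac per-volume fixated fraction.
#' @param config a [pipeline_config].
#' @return the masked `regressor_matrix`.
#' @export
apply_fixation_mask <- function(matrix, fixation_frac, config) {
  stopifnot(inherits(matrix, "regressor_matrix"))
  if (any(matrix$convolved)) {
    stop_sync("fixation masking must be applied before convolution (convolved columns: %s)",
              paste(names(which(matrix$convolved)), collapse = ", "))
  }
  if (length(fixation_frac) != nrow(matrix$values)) {
    stop_sync("fixation_frac length mismatch")
  }
  mask <- fixation_frac < config$fixation_min_frac
  cols <- colnames(matrix$values)
  if (!config$mask_confounds) {
    cols <- setdiff(cols, c("luminance", "motion", "gaze_change"))
  }
  cols <- setdiff(cols, "fixation_frac")
  matrix$values[mask, cols] <- 0
  attr(matrix, "n_masked") <- sum(mask)
  matrix
}

#' Convolve design columns with the hemodynamic kernel
#'
#' Causal convolution with the [gamma_hrf()] kernel, same output length.
#' Already-convolved columns and columns listed in `skip` are passed
#' through untouched.
#'
#' @param matrix a `regressor_matrix`.
#' @param config a [pipeline_config].
#' @param skip column names to leave unconvolved (default: the fixation
#'   fraction, which is a behavioral state, not a stimulus).
#' @return the convolved `regressor_matrix`.
#' @export
hrf_convolve <- function(matrix, config, skip = "fixation_frac") {
  stopifnot(inherits(matrix, "regressor_matrix"))
  kernel <- gamma_hrf(config, dt = 1 / matrix$rate_hz)
  todo <- setdiff(colnames(matrix$values)[!matrix$convolved], skip)
  if (length(todo)) {
    matrix$values[, todo] <- convolve_causal(matrix$values[, todo, drop = FALSE],
                                             kernel)
    matrix$convolved[todo] <- TRUE
  }
  matrix
}
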