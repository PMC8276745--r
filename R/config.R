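#' Pipeline configuration
#'
#' Collects every numeric parameter of the analysis in one validated object.
#' Defaults reproduce the study design the package emulates: fMRI sampled at
#' TR = 2 s, phase synchrony over 32-s windows offset by 2 s in the
#' 0.01-0.5 Hz band, a gamma hemodynamic kernel with 3-s mean lag and 1.5-s
#' SD, fixation masking at 80%, motion outliers at mean + 2.5 SD,
#' suprathreshold edges at z > 2.05 (equivalently the strongest 15%), and
#' clip-aligned segments from 4 s before to 6 s after onset with a 2-s
#' hemodynamic lag, interpolated to a 0.5-s grid.
#'
#' @param tr_s repetition time in seconds.
#' @param window_s sliding-window length in seconds.
#' @param window_step_s offset between adjacent windows in seconds.
#' @param band_lo_hz,band_hi_hz phase-estimation band in Hz. The upper edge
#'   is clamped just below the Nyquist frequency of the volume sampling rate
#'   at filter-design time (for TR = 2 s the printed 0.5 Hz upper edge equals
#'   Nyquist, so the band acts as a 0.01 Hz high-pass).
#' @param hrf_mean_lag_s,hrf_sd_s mean lag and SD of the gamma hemodynamic
#'   kernel, seconds.
#' @param fixation_min_frac minimum fixated fraction of a volume; volumes
#'   below it are zeroed in pre-convolution regressors.
#' @param outlier_sd_mult multiplier on the session SD of the volume-to-volume
#'   variance statistic used to flag motion outliers.
#' @param z_threshold absolute z threshold for suprathreshold edges.
#' @param top_edge_frac proportional threshold (fraction of edges retained).
#' @param align_pre_s,align_post_s clip-aligned segment extent around the
#'   (lagged) onset, seconds.
#' @param hemo_lag_s hemodynamic lag applied before aligning or assigning
#'   windows to stimulus states, seconds.
#' @param interp_step_s grid step of the spline-interpolated aligned
#'   segments, seconds.
#' @param regressor_rate_hz rate of the volume-level design matrix (1/TR).
#' @param behavior_rate_hz frame rate of video and eye-trace series, Hz.
#' @param state_rule how a synchrony window is assigned to a stimulus state:
#'   `"center"` (default) uses the hemodynamically shifted label of the
#'   window's center volume; `"majority"` requires more than
#'   `state_min_frac` of the window's volumes to carry the label.
#' @param state_min_frac overlap fraction for `state_rule = "majority"`.
#' @param mask_confounds logical; mask luminance/motion/gaze columns with the
#'   fixation rule as well as the stimulus columns.
#' @param plv_estimator `"plv"` (modulus of the mean relative-phase phasor)
#'   or `"circvar"` (1 - circular variance equivalent, a monotone remap).
#' @param arcsine_sqrt logical; if `TRUE` the variance-stabilizing transform
#'   is `asin(sqrt(r))` instead of `asin(r)`.
#' @param p_tail `"one"` or `"two"`: tail convention of the p-to-z mapping.
#' @param anova_interaction logical; include the subject-by-condition
#'   interaction in the edge-wise repeated-measures ANOVA.
#' @param highpass_s optional additional high-pass cutoff (seconds) applied
#'   to ROI series before phase estimation; `NULL` disables it.
#' @return an object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(tr_s = 2, window_s = 32, window_step_s = 2,
                            band_lo_hz = 0.01, band_hi_hz = 0.5,
                            hrf_mean_lag_s = 3, hrf_sd_s = 1.5,
                            fixation_min_frac = 0.8, outlier_sd_mult = 2.5,
                            z_threshold = 2.05, top_edge_frac = 0.15,
                            align_pre_s = 4, align_post_s = 6,
                            hemo_lag_s = 2, interp_step_s = 0.5,
                            regressor_rate_hz = 0.5, behavior_rate_hz = 25,
                            state_rule = c("center", "majority"),
                            state_min_frac = 0.5, mask_confounds = TRUE,
                            plv_estimator = c("plv", "circvar"),
                            arcsine_sqrt = FALSE,
                            p_tail = c("one", "two"),
                            anova_interaction = FALSE,
                            highpass_s = NULL) {
  cfg <- list(
    tr_s = tr_s, window_s = window_s, window_step_s = window_step_s,
    band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
    hrf_mean_lag_s = hrf_mean_lag_s, hrf_sd_s = hrf_sd_s,
    fixation_min_frac = fixation_min_frac, outlier_sd_mult = outlier_sd_mult,
    z_threshold = z_threshold, top_edge_frac = top_edge_frac,
    align_pre_s = align_pre_s, align_post_s = align_post_s,
    hemo_lag_s = hemo_lag_s, interp_step_s = interp_step_s,
    regressor_rate_hz = regressor_rate_hz, behavior_rate_hz = behavior_rate_hz,
    state_rule = match.arg(state_rule), state_min_frac = state_min_frac,
    mask_confounds = isTRUE(mask_confounds),
    plv_estimator = match.arg(plv_estimator),
    arcsine_sqrt = isTRUE(arcsine_sqrt),
    p_tail = match.arg(p_tail),
    anova_interaction = isTRUE(anova_interaction),
    highpass_s = highpass_s
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("tr_s", "window_s", "window_step_s", "hrf_mean_lag_s",
               "hrf_sd_s", "interp_step_s", "regressor_rate_hz",
               "behavior_rate_hz", "align_pre_s", "align_post_s")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_sync("config field '%s' must be a single positive number", f)
    }
  }
  if (cfg$hemo_lag_s < 0) stop_sync("hemo_lag_s must be >= 0")
  if (cfg$band_lo_hz <= 0 || cfg$band_hi_hz <= cfg$band_lo_hz) {
    stop_sync("need 0 < band_lo_hz < band_hi_hz")
  }
  if (cfg$band_hi_hz > 1 / cfg$tr_s) {
    stop_sync("band_hi_hz (%.3g) exceeds the sampling rate 1/tr_s", cfg$band_hi_hz)
  }
  for (f in c("fixation_min_frac", "top_edge_frac", "state_min_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1) stop_sync("%s must lie in (0,1)", f)
  }
  if (cfg$window_s < cfg$tr_s) stop_sync("window_s shorter than one volume")
  if (abs(cfg$window_step_s %% cfg$tr_s) > 1e-9 &&
      abs(cfg$tr_s - cfg$window_step_s %% cfg$tr_s) > 1e-9) {
    stop_sync("window_step_s must be a multiple of tr_s")
  }
  invisible(cfg)
}

window_volumes <- function(cfg) as.integer(round(cfg$window_s / cfg$tr_s))
step_volumes <- function(cfg) as.integer(round(cfg$window_step_s / cfg$tr_s))

#' Read / write a pipeline configuration as YAML
#'
#' Only fields present in the file override defaults, so a config file may be
#' partial.
#'
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_sync("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_sync("unknown config fields: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-18s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}
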