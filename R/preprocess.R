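#' Flag motion-contaminated volumes from volume-to-volume variance
#'
#' The per-volume statistic is the root-mean-square across ROIs of the
#' signal change from the previous volume (a DVARS analogue); the first
#' volume of each run has no predecessor and scores 0. Volumes whose
#' statistic exceeds `mean + outlier_sd_mult * SD` of the session's
#' statistic series are flagged. A constant series has SD 0 and yields no
#' flags. Flags are returned as indices plus an indicator matrix suitable
#' for use as nuisance regressors.
#'
#' @param ts an [roi_ts].
#' @param config a [pipeline_config].
#' @return list with `flagged` (1-based volume indices), `stat_series`,
#'   `threshold`, and `indicators` (volumes x n_flagged 0/1 matrix).
#' @export
flag_outliers <- function(ts, config) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- n_volumes(ts)
  if (n < 3) stop_sync("need at least 3 volumes to flag outliers")
  d <- diff(ts$values)
  stat <- c(0, sqrt(rowMeans(d^2)))
  stat[ts$run_starts + 1L] <- 0          # no predecessor across run breaks
  thr <- mean(stat) + config$outlier_sd_mult * stats::sd(stat)
  flagged <- which(stat > thr)
  ind <- matrix(0, n, length(flagged))
  if (length(flagged)) {
    ind[cbind(flagged, seq_along(flagged))] <- 1
    colnames(ind) <- paste0("outlier_v", flagged)
  }
  list(flagged = flagged, stat_series = stat, threshold = thr,
       indicators = ind)
}

# OLS residuals of Y (matrix, one response per column) on design X,
# dropping collinear columns by pivoted QR. Returns list(resid, coef, kept).
ols_residualize <- function(Y, X, warn_drop = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    kept <- sort(qx$pivot[seq_len(qx$rank)])
    if (warn_drop) {
      warn_sync("dropping %d collinear design column(s): %s",
                ncol(X) - qx$rank,
                paste(colnames(X)[setdiff(seq_len(ncol(X)), kept)],
                      collapse = ", "))
    }
    X <- X[, kept, drop = FALSE]
    qx <- qr(X)
  }
  beta <- qr.coef(qx, Y)
  list(resid = Y - X %*% beta, coef = beta, X = X)
}

#' Residualize ROI time series against session confounds
#'
#' Per ROI, ordinary least squares of the BOLD series on an intercept, the
#' CSF signal, a reward regressor (unit impulses at the reward-pulse onsets
#' binned to volumes and convolved with the gamma hemodynamic kernel), and
#' optionally one indicator column per flagged outlier volume. Residuals
#' are returned as a new [roi_ts]; they are orthogonal to every confound
#' column in-sample, and the operation is idempotent.
#'
#' @param ts an [roi_ts].
#' @param csf per-volume CSF series.
#' @param reward_times_s reward onsets in seconds (session clock).
#' @param config a [pipeline_config].
#' @param outlier_indicators optional 0/1 volume indicator matrix from
#'   [flag_outliers()].
#' @return the residual [roi_ts].
#' @export
residualize <- function(ts, csf, reward_times_s = numeric(0), config,
                        outlier_indicators = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- n_volumes(ts)
  if (length(csf) != n) stop_sync("csf length (%d) != n_volumes (%d)",
                                  length(csf), n)
  reward <- numeric(n)
  if (length(reward_times_s)) {
    v <- floor(reward_times_s / ts$tr_s) + 1L
    v <- v[v >= 1 & v <= n]
    reward[unique(v)] <- tabulate(v, nbins = n)[unique(v)]
    reward <- as.numeric(convolve_causal(matrix(reward), gamma_hrf(config, dt = ts$tr_s)))
  }
  X <- cbind(intercept = 1, csf = as.numeric(csf), reward = reward)
  if (!is.null(outlier_indicators) && ncol(outlier_indicators)) {
    X <- cbind(X, outlier_indicators)
  }
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(c) stats::sd(c) > 0))
  fit <- ols_residualize(ts$values, X[, keep, drop = FALSE])
  roi_ts(fit$resid, tr_s = ts$tr_s, run_starts = ts$run_starts,
         roi_labels = ts$roi_labels)
}
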