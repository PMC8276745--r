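#' Extract clip-onset-aligned synchrony segments
#'
#' For every clip of the requested categories, collects the synchrony
#' samples whose window centers fall around the hemodynamically lagged
#' onset: from `align_pre_s` before to `align_post_s` after
#' `onset + hemo_lag_s` (one extra sample of slack is kept on each side for
#' interpolation). Segments that do not fully cover the aligned extent or
#' that straddle a run boundary are dropped and counted.
#'
#' @param tensor the unique-clock `synchrony_tensor` of a session.
#' @param events the unique-content [event_table].
#' @param config a [pipeline_config].
#' @param categories clip categories to align (default: the social three).
#' @return object of class `aligned_segments` (uninterpolated).
#' @export
extract_segments <- function(tensor, events, config,
                             categories = SOCIAL_CATEGORIES) {
  clips <- events[events$category %in% categories, , drop = FALSE]
  if (!nrow(clips)) stop_sync("no clips of categories %s",
                              paste(categories, collapse = "/"))
  lag <- config$hemo_lag_s
  pre <- config$align_pre_s
  post <- config$align_post_s
  step <- config$window_step_s
  keep_rel <- list(); keep_val <- list(); cond <- character(0)
  clip_id <- integer(0); onset <- numeric(0)
  dropped <- 0L
  for (k in seq_len(nrow(clips))) {
    t0 <- clips$onset_s[k] + lag
    sel <- which(tensor$window_center_s >= t0 - pre - step &
                   tensor$window_center_s <= t0 + post + step)
    rel <- tensor$window_center_s[sel] - t0
    ok <- length(sel) >= 2 &&
      length(unique(tensor$window_run[sel])) == 1 &&
      max(diff(tensor$window_center_s[sel])) <= step + 1e-9 &&
      min(rel) <= -pre + 1e-9 && max(rel) >= post - 1e-9
    if (!ok) { dropped <- dropped + 1L; next }
    keep_rel[[length(keep_rel) + 1L]] <- rel
    keep_val[[length(keep_val) + 1L]] <- tensor$values[, sel, drop = FALSE]
    cond <- c(cond, clips$category[k])
    clip_id <- c(clip_id, k)
    onset <- c(onset, clips$onset_s[k])
  }
  if (!length(keep_rel)) stop_sync("all %d candidate clips dropped", nrow(clips))
  structure(list(rel_s = keep_rel, values = keep_val, condition = cond,
                 clip_id = clip_id, onset_s = onset, dropped = dropped,
                 edges = tensor$edges, edge_labels = tensor$edge_labels,
                 interpolated = FALSE),
            class = "aligned_segments")
}

#' Interpolate aligned segments to a uniform grid
#'
#' Natural cubic-spline interpolation of every segment onto the grid from
#' `-align_pre_s` to `+align_post_s` in steps of `interp_step_s` (21 points
#' for the default 4 + 6 s extent at 0.5 s). Sample points are reproduced
#' exactly; segments with fewer than 4 samples fall back to linear
#' interpolation with a warning.
#'
#' @param segments an uninterpolated `aligned_segments`.
#' @param config a [pipeline_config].
#' @return an `aligned_segments` with a `values` array
#'   (edges x grid x segments) and `grid_s`.
#' @export
interpolate_segments <- function(segments, config) {
  stopifnot(inherits(segments, "aligned_segments"), !segments$interpolated)
  grid <- seq(-config$align_pre_s, config$align_post_s,
              by = config$interp_step_s)
  nseg <- length(segments$values)
  nedge <- nrow(segments$values[[1]])
  out <- array(NA_real_, c(nedge, length(grid), nseg))
  n_linear <- 0L
  for (s in seq_len(nseg)) {
    x <- segments$rel_s[[s]]
    if (length(x) < 4) {
      n_linear <- n_linear + 1L
      for (e in seq_len(nedge)) {
        out[e, , s] <- stats::approx(x, segments$values[[s]][e, ],
                                     xout = grid, rule = 2)$y
      }
    } else {
      for (e in seq_len(nedge)) {
        out[e, , s] <- stats::spline(x, segments$values[[s]][e, ],
                                     xout = grid, method = "natural")$y
      }
    }
  }
  if (n_linear) warn_sync("%d segment(s) had < 4 samples; linear fallback used",
                          n_linear)
  structure(list(values = out, grid_s = grid, condition = segments$condition,
                 clip_id = segments$clip_id, onset_s = segments$onset_s,
                 dropped = segments$dropped, edges = segments$edges,
                 edge_labels = segments$edge_labels, interpolated = TRUE),
            class = "aligned_segments")
}

ALIGN_GROUPS <- c("temporo-temporal", "cingulate-temporal",
                  "cingulate-cingulate", "premotor-temporal",
                  "premotor-cingulate")

#' Baseline-normalized group-average aligned time courses
#'
#' Pools interpolated segments within each of the five anatomical edge
#' groups, restricted to suprathreshold edges. Each contributing
#' edge-by-clip segment is first normalized by subtracting its own
#' pre-onset mean (grid points strictly before 0); segments are then
#' averaged over contributing edges to give one clip-level course, and
#' clip-level courses are summarized per condition by their mean and SEM.
#' Groups with no suprathreshold edges are flagged and carry `NA` courses.
#'
#' @param segments an interpolated `aligned_segments` (may concatenate
#'   several sessions; see [pool_segments()]).
#' @param roster the [roi_roster].
#' @param supra a `binary_network` of suprathreshold edges.
#' @return object of class `group_timecourses`.
#' @export
group_timecourses <- function(segments, roster, supra) {
  stopifnot(inherits(segments, "aligned_segments"), segments$interpolated)
  gclass <- edge_groups(roster, segments$edges)
  grid <- segments$grid_s
  base_idx <- which(grid < 0)
  conds <- sort(unique(segments$condition))
  groups <- list()
  for (g in ALIGN_GROUPS) {
    esel <- which(gclass == g & supra$selected)
    if (!length(esel)) {
      groups[[g]] <- list(flagged = TRUE, n_edges = 0L, conditions = list())
      next
    }
    # clip-level courses: baseline-subtract per edge segment, then average edges
    nseg <- dim(segments$values)[3]
    clip_course <- matrix(NA_real_, nseg, length(grid))
    for (s in seq_len(nseg)) {
      seg <- segments$values[esel, , s, drop = FALSE][, , 1, drop = FALSE]
      seg <- matrix(seg, nrow = length(esel))
      bl <- rowMeans(seg[, base_idx, drop = FALSE])
      clip_course[s, ] <- colMeans(seg - bl)
    }
    cond_res <- list()
    for (cc in conds) {
      rows <- which(segments$condition == cc)
      cv <- clip_course[rows, , drop = FALSE]
      m <- colMeans(cv)
      sem <- if (nrow(cv) >= 2) {
        apply(cv, 2, stats::sd) / sqrt(nrow(cv))
      } else rep(NA_real_, length(grid))
      cond_res[[cc]] <- list(mean = m, sem = sem, clip_values = cv,
                             n_clips = nrow(cv))
    }
    groups[[g]] <- list(flagged = FALSE, n_edges = length(esel),
                        conditions = cond_res)
  }
  structure(list(groups = groups, grid_s = grid, conditions = conds),
            class = "group_timecourses")
}

#' Pool aligned segments across sessions
#'
#' Concatenates interpolated `aligned_segments` objects (e.g., one per
#' session) along the segment dimension so clip-level statistics draw on
#' every session.
#'
#' @param seg_list list of interpolated `aligned_segments` on identical
#'   grids and edge sets.
#' @return a pooled `aligned_segments`.
#' @export
pool_segments <- function(seg_list) {
  stopifnot(length(seg_list) >= 1)
  g0 <- seg_list[[1]]$grid_s
  for (s in seg_list) {
    stopifnot(inherits(s, "aligned_segments"), s$interpolated)
    if (length(s$grid_s) != length(g0) || any(abs(s$grid_s - g0) > 1e-9)) {
      stop_sync("segments have mismatched grids")
    }
  }
  structure(list(
    values = array(unlist(lapply(seg_list, function(s) s$values)),
                   c(dim(seg_list[[1]]$values)[1:2],
                     sum(vapply(seg_list, function(s) dim(s$values)[3], 1L)))),
    grid_s = g0,
    condition = unlist(lapply(seg_list, `[[`, "condition")),
    clip_id = unlist(lapply(seg_list, `[[`, "clip_id")),
    onset_s = unlist(lapply(seg_list, `[[`, "onset_s")),
    dropped = sum(vapply(seg_list, `[[`, 1L, "dropped")),
    edges = seg_list[[1]]$edges, edge_labels = seg_list[[1]]$edge_labels,
    interpolated = TRUE), class = "aligned_segments")
}

#' One-tailed t tests of aligned synchrony against baseline
#'
#' Per group, condition and grid timepoint: a one-sample, one-tailed
#' (greater) t test of the clip-level baseline-subtracted values against
#' zero. The Bonferroni family is timepoints x conditions within each
#' group. Timepoints with degenerate variance get p = 1.
#'
#' @param tc a `group_timecourses`.
#' @return data.frame: group, condition, time_s, mean, sem, t, p, p_bonf.
#' @export
test_vs_baseline <- function(tc) {
  stopifnot(inherits(tc, "group_timecourses"))
  out <- list()
  for (g in names(tc$groups)) {
    grp <- tc$groups[[g]]
    if (grp$flagged) next
    fam <- length(tc$grid_s) * length(grp$conditions)
    for (cc in names(grp$conditions)) {
      cv <- grp$conditions[[cc]]$clip_values
      n <- nrow(cv)
      tt <- pp <- rep(NA_real_, length(tc$grid_s))
      for (i in seq_along(tc$grid_s)) {
        v <- cv[, i]
        s <- stats::sd(v)
        if (n < 2 || !is.finite(s) || s == 0) {
          tt[i] <- NA_real_; pp[i] <- 1
        } else {
          tt[i] <- mean(v) / (s / sqrt(n))
          pp[i] <- stats::pt(tt[i], df = n - 1, lower.tail = FALSE)
        }
      }
      out[[paste(g, cc)]] <- data.frame(
        group = g, condition = cc, time_s = tc$grid_s,
        mean = grp$conditions[[cc]]$mean, sem = grp$conditions[[cc]]$sem,
        t = tt, p = pp, p_bonf = pmin(pp * fam, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

CONTRAST_NAMES <- c("ambiguous>others", "affiliative>others",
                    "aggressive>others")

#' Per-timepoint condition contrasts of aligned synchrony
#'
#' At each grid timepoint, OLS of the clip-level values on the three
#' condition cells, with the three contrasts each reading one condition
#' against the mean of the other two (weights (2, -1, -1)/3 up to
#' permutation, so the estimate is "condition minus mean of the others").
#' t statistics use the pooled residual variance; p values are one-tailed
#' (greater) and Bonferroni-corrected over timepoints x contrasts within
#' the group. Contrasts involving a missing condition are NA-flagged.
#'
#' @param tc a `group_timecourses`.
#' @return data.frame: group, contrast, time_s, estimate, t, p, p_bonf.
#' @export
contrast_glm <- function(tc) {
  stopifnot(inherits(tc, "group_timecourses"))
  specs <- list("ambiguous>others" = c(ambiguous = 2, affiliative = -1,
                                       aggressive = -1) / 3,
                "affiliative>others" = c(affiliative = 2, ambiguous = -1,
                                         aggressive = -1) / 3,
                "aggressive>others" = c(aggressive = 2, ambiguous = -1,
                                        affiliative = -1) / 3)
  out <- list()
  for (g in names(tc$groups)) {
    grp <- tc$groups[[g]]
    if (grp$flagged) next
    conds <- names(grp$conditions)
    fam <- length(tc$grid_s) * length(specs)
    for (cn in names(specs)) {
      w <- specs[[cn]]
      if (!all(names(w) %in% conds)) {
        out[[paste(g, cn)]] <- data.frame(group = g, contrast = cn,
                                          time_s = tc$grid_s,
                                          estimate = NA_real_, t = NA_real_,
                                          p = NA_real_, p_bonf = NA_real_,
                                          stringsAsFactors = FALSE)
        next
      }
      est <- tt <- pp <- rep(NA_real_, length(tc$grid_s))
      for (i in seq_along(tc$grid_s)) {
        vals <- lapply(names(w), function(cc) grp$conditions[[cc]]$clip_values[, i])
        ns <- vapply(vals, length, 1L)
        mus <- vapply(vals, mean, 0)
        dfree <- sum(ns) - length(ns)
        if (dfree < 1) { pp[i] <- 1; next }
        s2 <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0)) / dfree
        est[i] <- sum(w * mus)
        se <- sqrt(s2 * sum(w^2 / ns))
        if (se == 0) { tt[i] <- NA_real_; pp[i] <- 1 } else {
          tt[i] <- est[i] / se
          pp[i] <- stats::pt(tt[i], df = dfree, lower.tail = FALSE)
        }
      }
      out[[paste(g, cn)]] <- data.frame(group = g, contrast = cn,
                                        time_s = tc$grid_s, estimate = est,
                                        t = tt, p = pp,
                                        p_bonf = pmin(pp * fam, 1),
                                        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
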