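#' ROI time-series container
#'
#' A volumes-by-ROIs BOLD matrix with its repetition time and run structure.
#' `run_starts` holds the 0-based volume index at which each run begins
#' (first entry 0); runs partition the volumes and no windowing or phase
#' estimation ever crosses a run boundary.
#'
#' @param values numeric matrix, volumes x ROIs.
#' @param tr_s repetition time, seconds.
#' @param run_starts integer vector of 0-based run start indices.
#' @param roi_labels character vector of column labels.
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(values, tr_s, run_starts = 0L, roi_labels = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_sync("time-series values must be numeric")
  if (anyNA(values)) stop_sync("time-series contains missing values")
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(ncol(values)))
  if (length(roi_labels) != ncol(values)) stop_sync("roi_labels length mismatch")
  if (anyDuplicated(roi_labels)) stop_sync("duplicate ROI labels")
  run_starts <- as.integer(run_starts)
  n <- nrow(values)
  if (length(run_starts) == 0 || run_starts[1] != 0L ||
      is.unsorted(run_starts, strictly = TRUE) || any(run_starts >= n)) {
    stop_sync("run_starts must be strictly increasing, start at 0 and lie in [0, n_volumes)")
  }
  colnames(values) <- roi_labels
  structure(list(values = values, tr_s = as.numeric(tr_s),
                 run_starts = run_starts, roi_labels = roi_labels),
            class = "roi_ts")
}

n_volumes <- function(ts) nrow(ts$values)

# per-run index ranges (1-based, inclusive)
run_ranges <- function(ts) {
  starts <- ts$run_starts + 1L
  ends <- c(ts$run_starts[-1], n_volumes(ts))
  data.frame(run = seq_along(starts), start = starts, end = ends)
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d volumes x %d ROIs, TR = %g s, %d run(s)\n",
              nrow(x$values), ncol(x$values), x$tr_s, length(x$run_starts)))
  invisible(x)
}

fmt_num <- function(x) {
  # fixed significant-digit text so write/read round-trips are stable
  out <- sprintf("%.12g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

read_tsv_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- strsplit(sub("^#\\s*", "", l), "\t", fixed = TRUE)[[1]]
    if (length(kv) >= 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(body)]
  list(meta = meta, body = body, meta_lines = length(meta_idx))
}

#' Read / write ROI time-series TSV
#'
#' The on-disk dialect is UTF-8 tab-separated text: `#`-prefixed metadata
#' lines (`tr_s`, `run_boundaries` as comma-separated 0-based run start
#' indices), a header row of ROI labels, then one numeric row per volume.
#' `write_timeseries` and `read_timeseries` are exact inverses on valid
#' files.
#'
#' @param path file path.
#' @return `read_timeseries` returns an [roi_ts].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_sync("file not found: %s", path)
  p <- read_tsv_body(path)
  if (is.null(p$meta$tr_s)) stop_sync("%s: missing '# tr_s' metadata line", path)
  if (is.null(p$meta$run_boundaries)) {
    stop_sync("%s: missing '# run_boundaries' metadata line", path)
  }
  tr <- as.numeric(p$meta$tr_s)
  runs <- as.integer(strsplit(p$meta$run_boundaries, ",", fixed = TRUE)[[1]])
  if (length(p$body) < 2) stop_sync("%s: no data rows", path)
  labels <- strsplit(p$body[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(labels)) stop_sync("%s: duplicate ROI labels in header", path)
  rows <- strsplit(p$body[-1], "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != length(labels))) {
    bad <- which(nc != length(labels))[1]
    stop_sync("%s: ragged row at data line %d (%d cells, expected %d)",
              path, bad, nc[bad], length(labels))
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(length(labels))))
  vals <- if (length(labels) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop_sync("%s: non-numeric or missing cell at data row %d", path, bad)
  }
  roi_ts(vals, tr_s = tr, run_starts = runs, roi_labels = labels)
}

#' @rdname read_timeseries
#' @param ts an [roi_ts].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# tr_s\t%s", fmt_num(ts$tr_s)),
               sprintf("# run_boundaries\t%s",
                       paste(ts$run_starts, collapse = ","))), con)
  writeLines(paste(ts$roi_labels, collapse = "\t"), con)
  writeLines(apply(ts$values, 1, function(r) paste(fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' Read / write event tables as TSV
#'
#' Columns: `onset_s`, `duration_s`, `category`, `n_actors`, `run`.
#' Unknown categories and overlapping events are rejected at read time.
#'
#' @param path file path.
#' @return `read_events` returns an [event_table].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_sync("file not found: %s", path)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "category")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_sync("%s: missing column(s) %s", path,
                              paste(miss, collapse = ", "))
  event_table(d$onset_s, d$duration_s, d$category,
              n_actors = d$n_actors,
              run = if ("run" %in% names(d)) d$run else NULL)
}

#' @rdname read_events
#' @param events an [event_table].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  d <- as.data.frame(events)
  d$onset_s <- fmt_num(d$onset_s)
  d$duration_s <- fmt_num(d$duration_s)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Confound bundle
#'
#' Frame-rate stimulus features (luminance, motion energy), the 2-D gaze
#' trace at the eye-tracker rate, per-volume fixation fraction and CSF
#' signal, and reward-pulse onset times.
#'
#' @param luminance,motion numeric frame-rate series (same length).
#' @param gaze_xy two-column matrix of gaze position in degrees, frame rate.
#' @param fixation_frac per-volume fixated fraction in `[0, 1]`.
#' @param csf per-volume CSF signal.
#' @param reward_times_s reward pulse onsets, seconds.
#' @return an object of class `confound_bundle`.
#' @export
confound_bundle <- function(luminance, motion, gaze_xy, fixation_frac, csf,
                            reward_times_s = numeric(0)) {
  gaze_xy <- as.matrix(gaze_xy)
  if (length(luminance) != length(motion) || nrow(gaze_xy) != length(luminance)) {
    stop_sync("luminance, motion and gaze_xy must share the frame grid")
  }
  if (ncol(gaze_xy) != 2) stop_sync("gaze_xy needs two columns")
  if (any(fixation_frac < -1e-12 | fixation_frac > 1 + 1e-12)) {
    stop_sync("fixation_frac outside [0,1]")
  }
  if (length(csf) != length(fixation_frac)) {
    stop_sync("csf and fixation_frac must both be per-volume series")
  }
  structure(list(luminance = as.numeric(luminance),
                 motion = as.numeric(motion),
                 gaze_xy = gaze_xy,
                 fixation_frac = pmin(pmax(as.numeric(fixation_frac), 0), 1),
                 csf = as.numeric(csf),
                 reward_times_s = sort(as.numeric(reward_times_s))),
            class = "confound_bundle")
}

#' Read / write a confound bundle
#'
#' Persists a [confound_bundle] across three sibling TSV files:
#' `<prefix>_frames.tsv` (luminance, motion, gaze_x, gaze_y),
#' `<prefix>_volumes.tsv` (fixation_frac, csf) and `<prefix>_rewards.tsv`
#' (reward_time_s).
#'
#' @param prefix path prefix for the three files.
#' @return `read_confounds` returns a [confound_bundle].
#' @export
read_confounds <- function(prefix) {
  fr <- utils::read.delim(paste0(prefix, "_frames.tsv"), stringsAsFactors = FALSE)
  vo <- utils::read.delim(paste0(prefix, "_volumes.tsv"), stringsAsFactors = FALSE)
  rw_path <- paste0(prefix, "_rewards.tsv")
  rw <- if (file.exists(rw_path) && length(readLines(rw_path, warn = FALSE)) > 1) {
    utils::read.delim(rw_path)$reward_time_s
  } else numeric(0)
  confound_bundle(fr$luminance, fr$motion, cbind(fr$gaze_x, fr$gaze_y),
                  vo$fixation_frac, vo$csf, rw)
}

#' @rdname read_confounds
#' @param bundle a [confound_bundle].
#' @export
write_confounds <- function(bundle, prefix) {
  stopifnot(inherits(bundle, "confound_bundle"))
  fr <- data.frame(luminance = fmt_num(bundle$luminance),
                   motion = fmt_num(bundle$motion),
                   gaze_x = fmt_num(bundle$gaze_xy[, 1]),
                   gaze_y = fmt_num(bundle$gaze_xy[, 2]))
  utils::write.table(fr, paste0(prefix, "_frames.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vo <- data.frame(fixation_frac = fmt_num(bundle$fixation_frac),
                   csf = fmt_num(bundle$csf))
  utils::write.table(vo, paste0(prefix, "_volumes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rw <- data.frame(reward_time_s = fmt_num(bundle$reward_times_s))
  utils::write.table(rw, paste0(prefix, "_rewards.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read / write an ROI roster TSV
#'
#' Columns: `label`, `hemisphere`, `group`, `x`, `y`, `z`.
#'
#' @param path file path.
#' @return `read_roster` returns an [roi_roster].
#' @export
read_roster <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  roi_roster(d$label, d$hemisphere, d$group,
             x = d$x %||% NA_real_, y = d$y %||% NA_real_, z = d$z %||% NA_real_)
}

#' @rdname read_roster
#' @param roster an [roi_roster].
#' @export
write_roster <- function(roster, path) {
  utils::write.table(as.data.frame(roster), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
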