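EVENT_CATEGORIES <- c("aggressive", "affiliative", "ambiguous",
                      "single_actor", "nonsocial", "unclassified", "blank")
SOCIAL_CATEGORIES <- c("aggressive", "affiliative", "ambiguous")

#' Timed, categorized clip/blank events
#'
#' One row per interval of the stimulus timeline: onset and duration in
#' seconds from session start, behavior category and actor count. Social
#' categories (aggressive/affiliative/ambiguous) imply two or more actors,
#' `single_actor` one, `nonsocial`/`blank` none. All timestamps use
#' half-open intervals `[onset, onset + duration)`.
#'
#' @param onset_s,duration_s numeric, seconds.
#' @param category one of aggressive, affiliative, ambiguous, single_actor,
#'   nonsocial, unclassified, blank.
#' @param n_actors `"0"`, `"1"` or `"2+"` (defaults inferred from category).
#' @param run optional integer run index per event.
#' @return a data.frame of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset_s, duration_s, category, n_actors = NULL,
                        run = NULL) {
  category <- as.character(category)
  bad <- setdiff(unique(category), EVENT_CATEGORIES)
  if (length(bad)) stop_sync("unknown category: %s", paste(bad, collapse = ", "))
  if (any(!is.finite(onset_s)) || any(!is.finite(duration_s))) {
    stop_sync("event onsets/durations must be finite")
  }
  if (any(duration_s <= 0)) stop_sync("event durations must be > 0")
  if (is.null(n_actors)) {
    n_actors <- ifelse(category %in% SOCIAL_CATEGORIES, "2+",
                       ifelse(category %in% c("single_actor", "unclassified"),
                              "1", "0"))
  }
  n_actors <- as.character(n_actors)
  if (!all(n_actors %in% c("0", "1", "2+"))) {
    stop_sync("n_actors must be one of '0', '1', '2+'")
  }
  incon <- (category %in% SOCIAL_CATEGORIES & n_actors != "2+") |
    (category == "single_actor" & n_actors != "1") |
    (category %in% c("nonsocial", "blank") & n_actors != "0")
  if (any(incon)) {
    stop_sync("category/n_actors inconsistent at row(s) %s",
              paste(which(incon), collapse = ", "))
  }
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   category = category, n_actors = n_actors,
                   run = if (is.null(run)) NA_integer_ else as.integer(run),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  # overlap check within run (or globally when run is absent)
  key <- if (all(is.na(ev$run))) rep(1L, nrow(ev)) else ev$run
  for (r in unique(key)) {
    sub <- ev[key == r, , drop = FALSE]
    if (nrow(sub) > 1) {
      ends <- sub$onset_s + sub$duration_s
      ov <- which(sub$onset_s[-1] < ends[-nrow(sub)] - 1e-9)
      if (length(ov)) {
        idx <- which(key == r)[ov[1] + 0:1]
        stop_sync("events overlap: rows %d and %d (onsets %.3f, %.3f)",
                  idx[1], idx[2], ev$onset_s[idx[1]], ev$onset_s[idx[2]])
      }
    }
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Index of the event covering each volume's midpoint (0 = none).
#' @keywords internal
volume_event_index <- function(events, n_volumes, tr_s, shift_s = 0) {
  mid <- (seq_len(n_volumes) - 0.5) * tr_s
  interval_index(mid, events$onset_s + shift_s, events$duration_s)
}

# index of the (sorted, non-overlapping) interval covering each time point,
# 0 where uncovered
interval_index <- function(t, onsets, durations) {
  ord <- order(onsets)
  k <- findInterval(t, onsets[ord])
  hit <- k > 0
  hit[hit] <- t[hit] < onsets[ord][k[hit]] + durations[ord][k[hit]]
  idx <- integer(length(t))
  idx[hit] <- ord[k[hit]]
  idx
}

#' Per-volume category labels from an event table
#'
#' Labels each volume by the category of the event covering the volume's
#' midpoint, optionally after shifting event times forward by `shift_s`
#' (used to apply the hemodynamic lag). Volumes covered by no event get
#' `"none"`.
#'
#' @param events an `event_table`.
#' @param n_volumes number of volumes.
#' @param tr_s repetition time, seconds.
#' @param shift_s forward time shift applied to events, seconds.
#' @return character vector of length `n_volumes`.
#' @export
volume_labels <- function(events, n_volumes, tr_s, shift_s = 0) {
  idx <- volume_event_index(events, n_volumes, tr_s, shift_s)
  ifelse(idx > 0, events$category[pmax(idx, 1L)], "none")
}

# Shift a whole event table in time (session-clock bookkeeping for repeats).
shift_events <- function(events, by_s, run_offset = 0L) {
  ev <- events
  ev$onset_s <- ev$onset_s + by_s
  if (!all(is.na(ev$run))) ev$run <- ev$run + as.integer(run_offset)
  ev
}
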