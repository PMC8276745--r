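# Fixed duration-by-category composition of the default 64-clip session:
# four 220-s sequences, each 16 clips (ten 5-s, five 10-s, one 20-s; 120 s
# of clip content) alternating with five 20-s blanks. Category time shares
# of the 480 s of clip content: aggressive 14.6%, affiliative 15.6%,
# ambiguous 13.5%, single actor 14.6%, nonsocial 17.7%, unclassified 24.0%
# (each within 1.1 points of the emulated study's printed mix). The
# ambiguous category carries three of the four 20-s exemplars: responses
# are read out through 32-s sliding windows, so the category whose
# condition-locked coupling the validation study must detect needs
# exposures on the window's own timescale.
SCHEDULE_COMPOSITION <- data.frame(
  category = c("unclassified", "nonsocial", "affiliative", "aggressive",
               "ambiguous", "single_actor"),
  n20 = c(0L, 1L, 0L, 0L, 3L, 0L),
  n10 = c(5L, 3L, 5L, 4L, 0L, 3L),
  n5 = c(13L, 7L, 5L, 6L, 1L, 8L),
  stringsAsFactors = FALSE
)

#' Generate a pseudo-random stimulus schedule
#'
#' Builds the unique-content event timeline: four 220-s sequences, each of
#' 16 clips (5, 10 or 20 s) grouped between 20-s blank periods, 880 s in
#' total. Clip categories follow a fixed duration-by-category composition
#' matching the emulated study's content mix to within about one
#' percentage point, and the clip order is drawn pseudo-randomly under the
#' constraint that every ordered pair of social behaviors (aggressive,
#' affiliative, ambiguous — including repeats of the same behavior) occurs
#' somewhere in the session's sequence of social clips. Deterministic
#' given the seed.
#'
#' @param config a [pipeline_config].
#' @param seed integer seed.
#' @param categories optional category subset. `"blank"` alone yields a
#'   blanks-only table; a clip-category subset redraws clip labels from the
#'   composition restricted to that subset (time shares then follow the
#'   renormalized mix).
#' @return an [event_table] with a `run` column (1-4) and attributes
#'   `sequence_dur_s` (220) and `n_runs` (4).
#' @export
generate_schedule <- function(config, seed, categories = NULL) {
  n_runs <- 4L
  seq_dur <- 220
  if (!is.null(categories)) {
    bad <- setdiff(categories, EVENT_CATEGORIES)
    if (length(bad)) stop_sync("unknown categories: %s", paste(bad, collapse = ", "))
    if (identical(sort(categories), "blank")) {
      ev <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
        data.frame(onset_s = (r - 1) * seq_dur + seq(0, seq_dur - 20, by = 20),
                   duration_s = 20, category = "blank", run = r)
      }))
      out <- event_table(ev$onset_s, ev$duration_s, ev$category, run = ev$run)
      attr(out, "sequence_dur_s") <- seq_dur
      attr(out, "n_runs") <- n_runs
      return(out)
    }
  }
  comp <- SCHEDULE_COMPOSITION
  if (!is.null(categories)) {
    comp <- comp[comp$category %in% categories, , drop = FALSE]
    if (!nrow(comp)) stop_sync("no clip categories left in the requested mix")
  }
  social <- intersect(SOCIAL_CATEGORIES, comp$category)
  need_pairs <- if (length(social) >= 2) {
    as.vector(outer(social, social, paste, sep = ">"))
  } else character(0)

  with_seed(seed, {
    if (is.null(categories)) {
      pool20 <- rep(comp$category, comp$n20)
      pool10 <- rep(comp$category, comp$n10)
      pool5 <- rep(comp$category, comp$n5)
    } else {
      # restricted mix: refill the 4/20/40 duration slots from the subset,
      # proportional to the subset's own composition
      pool20 <- sample_fill(comp$category, comp$n20, 4L)
      pool10 <- sample_fill(comp$category, comp$n10, 20L)
      pool5 <- sample_fill(comp$category, comp$n5, 40L)
    }
    for (attempt in seq_len(1000)) {
      runs20 <- sample(pool20)
      runs10 <- matrix(sample(pool10), nrow = n_runs)
      runs5 <- matrix(sample(pool5), nrow = n_runs)
      clips <- lapply(seq_len(n_runs), function(r) {
        cats <- c(runs20[r], runs10[r, ], runs5[r, ])
        durs <- c(20, rep(10, ncol(runs10)), rep(5, ncol(runs5)))
        ord <- sample(length(cats))
        data.frame(category = cats[ord], duration_s = durs[ord],
                   stringsAsFactors = FALSE)
      })
      # clips flush against a run's end cannot be resolved by the aligned
      # analysis (no post-onset windows); keep long clips out of the final
      # slot, as stimulus designs pad run ends for the hemodynamic lag
      ends_ok <- !any(vapply(clips, function(cl) {
        cl$duration_s[nrow(cl)] == 20
      }, TRUE))
      all_cats <- unlist(lapply(clips, `[[`, "category"))
      soc_seq <- all_cats[all_cats %in% social]
      have <- if (length(soc_seq) >= 2) {
        unique(paste(soc_seq[-length(soc_seq)], soc_seq[-1], sep = ">"))
      } else character(0)
      if (ends_ok && all(need_pairs %in% have)) break
      if (attempt == 1000) {
        stop_sync("could not arrange clips to cover all ordered behavior pairs")
      }
    }
    rows <- list()
    for (r in seq_len(n_runs)) {
      cl <- clips[[r]]
      sizes <- c(4L, 3L, 3L, 3L, 3L)
      t <- (r - 1) * seq_dur
      k <- 1L
      # each sequence opens with a blank baseline period, then alternates
      # clip groups with blanks
      for (gi in seq_along(sizes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          onset_s = t, duration_s = 20, category = "blank", run = r,
          stringsAsFactors = FALSE)
        t <- t + 20
        for (u in seq_len(sizes[gi])) {
          rows[[length(rows) + 1L]] <- data.frame(
            onset_s = t, duration_s = cl$duration_s[k],
            category = cl$category[k], run = r, stringsAsFactors = FALSE)
          t <- t + cl$duration_s[k]
          k <- k + 1L
        }
      }
    }
    ev <- do.call(rbind, rows)
    n_act <- ifelse(ev$category %in% SOCIAL_CATEGORIES, "2+",
                    ifelse(ev$category == "single_actor", "1",
                           ifelse(ev$category == "unclassified",
                                  sample(c("1", "2+"), nrow(ev), replace = TRUE),
                                  "0")))
    out <- event_table(ev$onset_s, ev$duration_s, ev$category,
                       n_actors = n_act, run = ev$run)
    attr(out, "sequence_dur_s") <- seq_dur
    attr(out, "n_runs") <- n_runs
    out
  })
}

# draw n category labels proportional to a weight vector (used when the
# schedule is restricted to a category subset)
sample_fill <- function(categories, weights, n) {
  if (sum(weights) == 0) weights <- rep(1, length(categories))
  sample(categories, n, replace = TRUE, prob = weights / sum(weights))
}
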