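#' Analyze one session: from raw ROI series to the unique-clock tensor
#'
#' Runs the session-level chain in the canonical order: motion-outlier
#' flagging; residualization against CSF, reward and outlier regressors;
#' design construction, fixation masking, hemodynamic convolution;
#' band-limited instantaneous phase; sliding-window phase-locking values;
#' window-level nuisance cleaning (luminance, motion, gaze change,
#' fixation); arcsine transform; and averaging across repeated viewings
#' onto the unique-content clock.
#'
#' @param bundle a `session_bundle` (or a list with the same fields).
#' @param config a [pipeline_config].
#' @return list: `tensor` (unique-clock `synchrony_tensor`), `flags`,
#'   `counts` (masked volumes, clipped values, flagged volumes).
#' @export
analyze_session <- function(bundle, config) {
  ts <- bundle$timeseries
  conf <- bundle$confounds
  flags <- flag_outliers(ts, config)
  resid <- residualize(ts, conf$csf, conf$reward_times_s, config,
                       outlier_indicators = flags$indicators)
  design <- build_design(bundle$events, conf, config, n_vol = n_volumes(ts))
  design <- apply_fixation_mask(design, conf$fixation_frac, config)
  n_masked <- attr(design, "n_masked")
  design <- hrf_convolve(design, config)
  phases <- instantaneous_phase(resid, config)
  tensor <- windowed_synchrony(phases, config)
  tensor <- clean_synchrony(tensor, design, config)
  tensor <- arcsine_transform(tensor, config)
  n_clipped <- attr(tensor, "n_clipped")
  avg <- average_repeats(tensor, bundle$run_sequence,
                         bundle$sequence_dur_s %||% 220)
  list(tensor = avg, flags = flags,
       counts = list(masked_volumes = n_masked, clipped_values = n_clipped,
                     flagged_volumes = length(flags$flagged)))
}

#' Analyze a whole study
#'
#' Applies [analyze_session()] to every session, stacks session-by-condition
#' edge means, fits the edge-wise repeated-measures ANOVA, converts p to z,
#' thresholds the socially modulated network (absolute z rule, with the
#' proportional top-fraction network alongside), computes degree and
#' eigenvector centrality, builds the blank- and nonsocial-state networks,
#' and runs the clip-aligned group time-course analysis (baseline t tests
#' and condition contrasts) on suprathreshold edges.
#'
#' @param study a `study_bundle` from [simulate_study()] (or an equivalent
#'   list of session bundles plus roster/schedule/config).
#' @param config a [pipeline_config]; defaults to the study's.
#' @param supra_mode which suprathreshold network feeds the aligned
#'   analysis: `"proportional"` (default) or `"absolute"`.
#' @param cache_dir optional directory; per-session stage outputs are
#'   stored there and reused on reruns (delete a file to recompute that
#'   session and everything downstream).
#' @return a `study_results` list; see the individual components.
#' @export
analyze_study <- function(study, config = study$config,
                          supra_mode = c("proportional", "absolute"),
                          cache_dir = NULL) {
  supra_mode <- match.arg(supra_mode)
  roster <- study$roster
  schedule <- study$schedule
  n_rois <- nrow(roster)
  ed <- edge_index(n_rois)
  means <- list()
  seg_list <- list()
  session_info <- list()
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE,
                                      showWarnings = FALSE)
  for (b in study$sessions) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0("session_", b$session, ".rds"))
    }
    res <- if (!is.null(cache_file) && file.exists(cache_file)) {
      readRDS(cache_file)
    } else analyze_session(b, config)
    if (!is.null(cache_file) && !file.exists(cache_file)) {
      saveRDS(res, cache_file)
    }
    means[[b$session]] <- condition_means(res$tensor, schedule, config,
                                          session = b$session,
                                          subject = b$subject)
    seg <- extract_segments(res$tensor, schedule, config)
    seg_list[[b$session]] <- interpolate_segments(seg, config)
    session_info[[b$session]] <- res$counts
  }
  means <- do.call(rbind, c(means, list(make.row.names = FALSE)))
  stats <- edge_stat_matrix(means, n_edges = nrow(ed), config = config)
  net_abs <- threshold_network(stats, config, n_rois, mode = "absolute",
                               labels = roster$label)
  net_prop <- threshold_network(stats, config, n_rois, mode = "proportional",
                                labels = roster$label)
  supra <- if (supra_mode == "proportional") net_prop else net_abs
  segments <- pool_segments(seg_list)
  tc <- group_timecourses(segments, roster, supra)
  structure(list(
    condition_means = means,
    edge_stats = stats,
    network_absolute = net_abs,
    network_proportional = net_prop,
    degree = network_degree(supra),
    eigencentrality = eigencentrality(supra),
    group_timecourses = tc,
    baseline_tests = test_vs_baseline(tc),
    contrasts = contrast_glm(tc),
    segments = segments,
    session_counts = session_info,
    roster = roster, config = config, supra_mode = supra_mode
  ), class = "study_results")
}

#' Write / read a simulated study as a TSV tree
#'
#' Lays a `study_bundle` out as plain text: `roster.tsv`, `config.yaml`,
#' `schedule.tsv`, and one directory per session holding `timeseries.tsv`,
#' `events.tsv`, the confound TSVs and a small `session.json` with the
#' subject id and run sequence.
#'
#' @param study a `study_bundle`.
#' @param dir output directory.
#' @return `read_study` returns a `study_bundle`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(study$roster, file.path(dir, "roster.tsv"))
  write_config(study$config, file.path(dir, "config.yaml"))
  write_events(study$schedule, file.path(dir, "schedule.tsv"))
  for (b in study$sessions) {
    sd <- file.path(dir, "sessions", b$session)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_timeseries(b$timeseries, file.path(sd, "timeseries.tsv"))
    write_events(b$events, file.path(sd, "events.tsv"))
    write_confounds(b$confounds, file.path(sd, "confounds"))
    jsonlite::write_json(list(subject = b$subject, session = b$session,
                              run_sequence = b$run_sequence,
                              sequence_dur_s = b$sequence_dur_s),
                         file.path(sd, "session.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_study
#' @param dir study directory written by `write_study`.
#' @export
read_study <- function(dir) {
  roster <- read_roster(file.path(dir, "roster.tsv"))
  config <- read_config(file.path(dir, "config.yaml"))
  schedule <- read_events(file.path(dir, "schedule.tsv"))
  attr(schedule, "sequence_dur_s") <- 220
  attr(schedule, "n_runs") <- max(schedule$run)
  sdirs <- list.dirs(file.path(dir, "sessions"), recursive = FALSE)
  sessions <- lapply(sdirs, function(sd) {
    meta <- jsonlite::read_json(file.path(sd, "session.json"),
                                simplifyVector = TRUE)
    structure(list(
      timeseries = read_timeseries(file.path(sd, "timeseries.tsv")),
      events = read_events(file.path(sd, "events.tsv")),
      schedule = schedule,
      confounds = read_confounds(file.path(sd, "confounds")),
      run_sequence = meta$run_sequence,
      sequence_dur_s = meta$sequence_dur_s %||% 220,
      subject = meta$subject, session = meta$session),
      class = "session_bundle")
  })
  structure(list(schedule = schedule, roster = roster, spec = NULL,
                 config = config, sessions = sessions, seed = NA),
            class = "study_bundle")
}

#' Write study results as TSV files plus a JSON run manifest
#'
#' Persists condition means, edge statistics, the two thresholded
#' networks, centrality, state networks, aligned time-course tests and
#' contrasts; the manifest records the config, seed, per-file MD5 digests
#' and bookkeeping counts (masked volumes, clipped values, dropped
#' segments, flagged volumes).
#'
#' @param results a `study_results`.
#' @param dir output directory.
#' @param seed seed recorded in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_results <- function(results, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  roster <- results$roster
  ed <- edge_index(nrow(roster))
  files <- c(
    w(results$condition_means, "condition_means.tsv"),
    w(cbind(edge_label = edge_labels(roster, ed),
            as.data.frame(results$edge_stats)), "edge_stats.tsv"),
    w(data.frame(edge_label = edge_labels(roster, ed),
                 absolute = as.integer(results$network_absolute$selected),
                 proportional = as.integer(results$network_proportional$selected)),
      "networks.tsv"),
    w(data.frame(roi = roster$label, degree = results$degree,
                 eigencentrality = results$eigencentrality), "centrality.tsv"),
    w(results$baseline_tests, "baseline_tests.tsv"),
    w(results$contrasts, "contrasts.tsv"))
  counts <- list(
    dropped_segments = results$segments$dropped,
    masked_volumes = sum(vapply(results$session_counts,
                                function(x) x$masked_volumes, 1)),
    clipped_values = sum(vapply(results$session_counts,
                                function(x) x$clipped_values, 1)),
    flagged_volumes = sum(vapply(results$session_counts,
                                 function(x) x$flagged_volumes, 1)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("socialsync")),
    seed = seed,
    config = unclass(results$config),
    counts = counts,
    files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' End-to-end pipeline over a study directory
#'
#' Reads a study tree written by [write_study()] (or simulates one when
#' `simulate_seed` is given), analyzes it and writes results plus a run
#' manifest to `out_dir`. Given identical inputs and seed the outputs are
#' bit-identical.
#'
#' @param data_dir study directory (ignored when `simulate_seed` is set).
#' @param out_dir output directory.
#' @param config optional [pipeline_config] override.
#' @param simulate_seed if non-NULL, simulate the default synthetic study
#'   with this seed instead of reading `data_dir`.
#' @param ... passed to [simulate_study()] when simulating.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(data_dir = NULL, out_dir, config = NULL,
                         simulate_seed = NULL, ...) {
  study <- if (!is.null(simulate_seed)) {
    simulate_study(config = config %||% pipeline_config(),
                   seed = simulate_seed, ...)
  } else {
    if (is.null(data_dir) || !dir.exists(data_dir)) {
      stop_sync("data_dir not found: %s", data_dir %||% "<missing>")
    }
    read_study(data_dir)
  }
  cfg <- config %||% study$config
  results <- analyze_study(study, cfg)
  write_results(results, out_dir,
                seed = if (!is.null(simulate_seed)) simulate_seed else study$seed)
}
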