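cfg <- pipeline_config()

test_that("analytic phase recovers the phase ramp of a pure tone", {
  t <- (0:439) * 2
  x <- cos(2 * pi * 0.02 * t)
  ts <- roi_ts(cbind(a = x, b = cos(2 * pi * 0.02 * (t - 12.5))), tr_s = 2)
  ph <- instantaneous_phase(ts, cfg)
  core <- 60:380
  slope <- diff(ph$phases[, 1])
  slope <- slope[core]
  slope <- (slope + pi) %% (2 * pi) - pi
  expect_lt(abs(mean(slope) / 2 - 2 * pi * 0.02), 0.01 * 2 * pi * 0.02)
  # quarter-period delay -> constant pi/2 phase difference away from edges
  dphi <- (ph$phases[core, 1] - ph$phases[core, 2] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - pi / 2)), 0.05)
})

test_that("out-of-band tones are strongly attenuated by the band filter", {
  cfg_band <- pipeline_config(band_hi_hz = 0.1)
  t <- (0:399) * 2
  tone <- cos(2 * pi * 0.2 * t)           # above the 0.1 Hz upper edge
  keep <- cos(2 * pi * 0.05 * t)          # inside the band
  bf <- socialsync:::design_band_filter(cfg_band)
  out_tone <- signal::filtfilt(bf, tone)
  out_keep <- signal::filtfilt(bf, keep)
  core <- 50:350
  att <- 20 * log10(sd(out_tone[core]) / sd(tone[core]))
  expect_lt(att, -20)
  expect_gt(sd(out_keep[core]) / sd(keep[core]), 0.7)
})

test_that("windowed synchrony equals the direct phasor-mean formula", {
  with_seed(1, {
    n <- 1015
    ph <- matrix(runif(n * 2, -pi, pi), n, 2)
    pm <- phase_matrix_from(ph)
    tn <- windowed_synchrony(pm, cfg)
    expect_equal(ncol(tn$values), n - 15)
    direct <- vapply(seq_len(n - 15), function(k) {
      d <- ph[k:(k + 15), 1] - ph[k:(k + 15), 2]
      Mod(mean(exp(1i * d)))
    }, numeric(1))
    expect_lt(max(abs(tn$values[1, ] - direct)), 1e-12)
  })
})

test_that("synchrony hits its closed-form extremes", {
  # constant phase offset -> 1; alternating 0/pi -> 0
  n <- 64
  ph1 <- cbind(rep(0.3, n), rep(-1.2, n))
  tn1 <- windowed_synchrony(phase_matrix_from(ph1), cfg)
  expect_true(all(abs(tn1$values - 1) < 1e-12))
  ph2 <- cbind(rep(c(0, pi), n / 2), rep(0, n))
  tn2 <- windowed_synchrony(phase_matrix_from(ph2), cfg)
  expect_true(all(abs(tn2$values) < 1e-12))
})

test_that("iid uniform phases reproduce the sqrt(pi/4N) null level", {
  with_seed(2, {
    N <- 16
    nwin <- 1e5
    d <- matrix(runif(nwin * N, -pi, pi), nwin, N)
    plv <- Mod(rowMeans(exp(1i * d)))
    expect_lt(abs(mean(plv) - sqrt(pi / (4 * N))), 0.005)
  })
})

test_that("synchrony is invariant to per-ROI amplitude rescaling", {
  ts <- tiny_ts(n = 220, r = 4, seed = 3)
  tn1 <- windowed_synchrony(instantaneous_phase(ts, cfg), cfg)
  ts2 <- ts
  ts2$values[, 2] <- ts2$values[, 2] * 1000
  tn2 <- windowed_synchrony(instantaneous_phase(ts2, cfg), cfg)
  expect_lt(max(abs(tn1$values - tn2$values)), 1e-10)
})

test_that("windows respect run boundaries and the V - 15 count", {
  ts <- tiny_ts(n = 440, r = 2, seed = 4)
  tn <- windowed_synchrony(instantaneous_phase(ts, cfg), cfg)
  expect_equal(ncol(tn$values), 425)
  ts2 <- tiny_ts(n = 440, r = 2, runs = c(0L, 220L), seed = 4)
  tn2 <- windowed_synchrony(instantaneous_phase(ts2, cfg), cfg)
  expect_equal(ncol(tn2$values), 2 * (220 - 15))
  expect_equal(as.numeric(tapply(tn2$window_center_s, tn2$window_run, min)),
               c(16, 456))
  expect_error(instantaneous_phase(tiny_ts(n = 20, r = 2), cfg), "shorter")
})

test_that("stored upper-triangle synchrony matches both orientations", {
  with_seed(5, {
    ph <- matrix(runif(80 * 3, -pi, pi), 80, 3)
    tn <- windowed_synchrony(phase_matrix_from(ph), cfg)
    for (e in seq_len(nrow(tn$edges))) {
      i <- tn$edges$i[e]; j <- tn$edges$j[e]
      flip <- vapply(seq_len(ncol(tn$values)), function(k) {
        d <- ph[k:(k + 15), j] - ph[k:(k + 15), i]
        Mod(mean(exp(1i * d)))
      }, numeric(1))
      expect_equal(tn$values[e, ], flip, tolerance = 1e-12)
    }
  })
})

test_that("nuisance cleaning removes the modeled structure and nothing else", {
  with_seed(6, {
    n_win <- 200
    lum <- as.numeric(arima.sim(list(ar = 0.8), n_win + 15))
    cols <- c("luminance", "motion", "gaze_change", "fixation_frac")
    dm <- regressor_matrix(
      list(luminance = lum, motion = rnorm(n_win + 15),
           gaze_change = rnorm(n_win + 15),
           fixation_frac = runif(n_win + 15, 0.7, 1)), rate_hz = 0.5)
    ph <- matrix(runif((n_win + 15) * 2, -pi, pi), n_win + 15, 2)
    tn <- windowed_synchrony(phase_matrix_from(ph), cfg)
    centers_v <- floor(tn$window_center_s / 2) + 1
    tn$values[1, ] <- 0.5 + 0.3 * dm$values[centers_v, "luminance"] +
      rnorm(ncol(tn$values), 0, 0.05)
    cl <- clean_synchrony(tn, dm, cfg)
    expect_lt(abs(cor(cl$values[1, ], dm$values[centers_v, "luminance"])), 1e-10)
    # intercept added back: mean preserved
    expect_equal(mean(cl$values[1, ]), mean(tn$values[1, ]), tolerance = 1e-10)
    # zero nuisance columns -> identity
    dm0 <- dm
    dm0$values[, cols] <- 0
    cl0 <- clean_synchrony(tn, dm0, cfg)
    expect_equal(cl0$values, tn$values, tolerance = 1e-12)
    # brute-force normal-equations oracle on a 6-window slice
    sl <- tn
    sl$values <- tn$values[, 1:6, drop = FALSE]
    sl$window_center_s <- tn$window_center_s[1:6]
    sl$window_run <- tn$window_run[1:6]
    Nc <- scale(dm$values[centers_v[1:6], cols], scale = FALSE)
    X <- cbind(1, Nc)
    y <- as.numeric(sl$values[1, ])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    manual <- y - as.numeric(X %*% beta) + beta[1]
    cl6 <- clean_synchrony(sl, dm, cfg)
    expect_equal(as.numeric(cl6$values[1, ]), manual, tolerance = 1e-10)
  })
})

test_that("the arcsine transform maps extremes and midpoints exactly", {
  tn <- windowed_synchrony(phase_matrix_from(matrix(0, 40, 2)), cfg)
  tn$values[1, 1:3] <- c(0, 1, 0.5)
  tn$values[1, 4] <- 1.2  # out of range after cleaning: clipped
  out <- arcsine_transform(tn, cfg)
  expect_equal(out$values[1, 1:4], c(0, pi / 2, asin(0.5), pi / 2),
               tolerance = 1e-12)
  expect_equal(asin(0.5), 0.5235988, tolerance = 1e-6)
  expect_equal(attr(out, "n_clipped"), 1)
  expect_true(out$transformed)
  expect_error(arcsine_transform(out, cfg), "already")
})

test_that("averaging repeats pools the unique-content timeline correctly", {
  ph <- matrix(runif(440 * 2, -pi, pi), 440, 2)
  pm <- phase_matrix_from(ph, run_starts = c(0L, 110L, 220L, 330L))
  tn <- windowed_synchrony(pm, cfg)
  # four runs replaying two unique sequences twice
  avg <- average_repeats(tn, run_sequence = c(1, 2, 1, 2), sequence_dur_s = 220)
  expect_equal(ncol(avg$values), 2 * 95)
  r1 <- which(tn$window_run == 1); r3 <- which(tn$window_run == 3)
  expect_equal(avg$values[, 1:95],
               (tn$values[, r1] + tn$values[, r3]) / 2, tolerance = 1e-12)
  # identical repeats average to themselves
  tn2 <- tn
  tn2$values[, tn$window_run == 3] <- tn$values[, tn$window_run == 1]
  tn2$values[, tn$window_run == 4] <- tn$values[, tn$window_run == 2]
  avg2 <- average_repeats(tn2, c(1, 2, 1, 2))
  expect_equal(avg2$values[, 1:95], tn$values[, r1], tolerance = 1e-12)
  expect_error(average_repeats(tn, c(1, 2, 1)), "length")
})

test_that("averaging repeats shrinks independent noise like 1/sqrt(k)", {
  with_seed(7, {
    base <- matrix(runif(3 * 2000, -pi, pi), 2000, 3)
    # build a fake tensor with three repeats of iid-noise synchrony
    k <- 3
    vals <- matrix(rnorm(10 * 3000), 10, 3000)
    tn <- structure(list(values = vals,
                         window_center_s = rep(16 + 2 * (0:999), k),
                         window_run = rep(1:k, each = 1000),
                         edges = edge_index(5), edge_labels = NULL,
                         window_len_volumes = 16, tr_s = 2,
                         transformed = FALSE), class = "synchrony_tensor")
    avg <- average_repeats(tn, rep(1, k), sequence_dur_s = 2030)
    expect_lt(abs(sd(avg$values) - 1 / sqrt(3)), 0.02)
  })
})

test_that("network summaries match a direct two-pass computation", {
  with_seed(8, {
    vals <- matrix(runif(6 * 50), 6, 50)
    tn <- structure(list(values = vals, window_center_s = 16 + 2 * (0:49),
                         window_run = rep(1, 50), edges = edge_index(4),
                         window_len_volumes = 16, tr_s = 2,
                         transformed = FALSE), class = "synchrony_tensor")
    ns <- network_summary(tn)
    expect_equal(ns$mean_series, colMeans(vals), tolerance = 1e-12)
    direct_var <- apply(vals, 2, function(c) mean((c - mean(c))^2))
    expect_equal(ns$variance_series, direct_var, tolerance = 1e-12)
    # two edges at 0 and 1 -> mean .5, population variance .25
    tn$values <- matrix(c(0, 1), 2, 50)
    tn$edges <- edge_index(2)
    ns2 <- network_summary(tn)
    expect_equal(unname(ns2$mean_series[1]), 0.5)
    expect_equal(unname(ns2$variance_series[1]), 0.25)
  })
})

test_that("state networks select, binarize and summarize by lobe pairing", {
  roster <- default_roster()
  ev <- event_table(c(0, 100), c(100, 120), c("blank", "nonsocial"),
                    run = c(1, 1))
  nwin <- 95
  vals <- matrix(0.2, 120, nwin)
  tt_edges <- which(edge_groups(roster) == "temporo-temporal")
  vals[tt_edges[1:20], ] <- 0.8   # blank-state coupling on temporal pairs
  tn <- structure(list(values = vals, window_center_s = 16 + 2 * (0:(nwin - 1)),
                       window_run = rep(1, nwin), edges = edge_index(16),
                       window_len_volumes = 16, tr_s = 2, transformed = FALSE),
                  class = "synchrony_tensor")
  sn <- suppressWarnings(state_network(tn, ev, "blank", roster, cfg))
  expect_equal(sum(sn$network$selected), 18)
  expect_true(all(which(sn$network$selected) %in% tt_edges[1:20]))
  expect_equal(sum(sn$proportions), 1)
  expect_equal(unname(sn$proportions["fronto-temporal"] +
                        sn$proportions["fronto-frontal"]), 0)
  # uniform tensor: deterministic tie rule takes the first 18 edges
  tn$values[] <- 0.4
  expect_warning(sn2 <- state_network(tn, ev, "blank", roster, cfg), "tie")
  expect_equal(which(sn2$network$selected), 1:18)
  expect_error(state_network(tn, ev, "aggressive", roster, cfg), "no windows")
})
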