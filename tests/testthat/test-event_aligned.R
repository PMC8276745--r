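cfg <- pipeline_config()

fake_tensor <- function(vals, centers = 16 + 2 * (0:(ncol(vals) - 1)),
                        runs = rep(1L, ncol(vals)), n_rois = 3) {
  structure(list(values = vals, window_center_s = centers,
                 window_run = runs, edges = edge_index(n_rois),
                 window_len_volumes = 16, tr_s = 2, transformed = TRUE),
            class = "synchrony_tensor")
}

test_that("segments cover onset+lag-4 to onset+lag+6 and drop boundary clips", {
  nwin <- 95
  vals <- matrix(rnorm(3 * nwin), 3, nwin)
  tn <- fake_tensor(vals)
  ev <- event_table(c(100, 200), c(10, 19.5),
                    c("ambiguous", "aggressive"), run = c(1, 1))
  seg <- extract_segments(tn, ev, cfg)
  # clip at t = 100 s with 2 s lag: samples span [98, 108]
  k <- which(seg$clip_id == 1)
  abs_t <- seg$rel_s[[k]] + 100 + 2
  expect_lte(min(abs_t), 98)
  expect_gte(max(abs_t), 108)
  # a clip 1 s from the run end cannot cover +6 s and is dropped
  ev2 <- event_table(c(100, 209), c(5, 10), c("ambiguous", "aggressive"),
                     run = c(1, 1))
  seg2 <- extract_segments(tn, ev2, cfg)
  expect_equal(seg2$dropped, 1L)
  expect_equal(seg2$condition, "ambiguous")
  expect_error(extract_segments(tn, event_table(0, 220, "blank", run = 1), cfg),
               "no clips")
})

test_that("constant tensors yield constant interpolated segments", {
  vals <- matrix(0.7, 3, 95)
  tn <- fake_tensor(vals)
  ev <- event_table(100, 10, "ambiguous", run = 1)
  seg <- interpolate_segments(extract_segments(tn, ev, cfg), cfg)
  expect_equal(length(seg$grid_s), 21)  # 11-s extent at 0.5-s steps
  expect_true(all(abs(seg$values - 0.7) < 1e-12))
})

test_that("natural splines reproduce polynomials and pass through samples", {
  x <- seq(-5, 7, by = 2)
  line <- 0.3 + 0.1 * x
  grid <- seq(-4, 6, by = 0.5)
  got_line <- spline(x, line, xout = grid, method = "natural")$y
  expect_equal(got_line, 0.3 + 0.1 * grid, tolerance = 1e-10)
  # through the module path: a linear segment stays linear
  nwin <- 95
  vals <- matrix(rep(0.1 + 0.002 * (16 + 2 * (0:(nwin - 1))), each = 3), 3)
  tn <- fake_tensor(vals)
  ev <- event_table(100, 10, "ambiguous", run = 1)
  seg <- interpolate_segments(extract_segments(tn, ev, cfg), cfg)
  t_abs <- seg$grid_s + 102
  expect_equal(seg$values[1, , 1], 0.1 + 0.002 * t_abs, tolerance = 1e-10)
  # spline error on a smooth sine stays below a dense-reference bound
  f <- function(t) sin(2 * pi * t / 30)
  xs <- seq(-6, 8, by = 2)
  dense <- seq(-4, 6, by = 0.01)
  err <- max(abs(spline(xs, f(xs), xout = dense, method = "natural")$y -
                   f(dense)))
  got <- spline(xs, f(xs), xout = grid, method = "natural")$y
  expect_lte(max(abs(got - f(grid))), err + 1e-12)
  expect_lt(err, 0.05)
})

make_group_fixture <- function(effects = c(ambiguous = 0, affiliative = 0,
                                           aggressive = 0),
                               n_per_cond = 8, noise = 0.01, seed = 99,
                               offset_sd = 0) {
  roster <- default_roster()
  ed <- edge_index(16)
  ct <- which(edge_groups(roster) == "cingulate-temporal")
  supra <- binary_network(seq_len(120) %in% ct[1:6], ed, 16)
  grid <- seq(-4, 6, by = 0.5)
  conds <- rep(names(effects), each = n_per_cond)
  with_seed(seed, {
    arr <- array(rnorm(120 * length(grid) * length(conds), 0, noise),
                 c(120, length(grid), length(conds)))
    for (s in seq_along(conds)) {
      bump <- effects[[conds[s]]] * pmax(grid, 0) / 6
      arr[, , s] <- arr[, , s] + rep(bump, each = 120) +
        rnorm(1, 0, offset_sd)   # per-segment additive offset
    }
    seg <- structure(list(values = arr, grid_s = grid, condition = conds,
                          clip_id = seq_along(conds),
                          onset_s = 10 * seq_along(conds), dropped = 0L,
                          edges = ed, edge_labels = NULL, interpolated = TRUE),
                     class = "aligned_segments")
    list(seg = seg, roster = roster, supra = supra)
  })
}

test_that("group courses are baseline-subtracted means with SEM over clips", {
  fx <- make_group_fixture(effects = c(ambiguous = 0.3, affiliative = 0,
                                       aggressive = 0), noise = 1e-6)
  tc <- group_timecourses(fx$seg, fx$roster, fx$supra)
  g <- tc$groups[["cingulate-temporal"]]
  expect_false(g$flagged)
  expect_equal(g$n_edges, 6)
  amb <- g$conditions$ambiguous
  expect_equal(unname(amb$mean[tc$grid_s == 6]), 0.3 * (1 - mean(pmax(tc$grid_s[tc$grid_s < 0], 0))),
               tolerance = 1e-3)
  expect_lt(max(amb$sem, na.rm = TRUE), 1e-5)
  # groups with no suprathreshold edges are flagged
  expect_true(tc$groups[["premotor-cingulate"]]$flagged)
})

test_that("baseline subtraction cancels per-segment additive offsets", {
  fx1 <- make_group_fixture(noise = 0.01, offset_sd = 0)
  fx2 <- make_group_fixture(noise = 0.01, offset_sd = 5)
  tc1 <- group_timecourses(fx1$seg, fx1$roster, fx1$supra)
  tc2 <- group_timecourses(fx2$seg, fx2$roster, fx2$supra)
  g1 <- tc1$groups[["cingulate-temporal"]]$conditions$ambiguous$clip_values
  g2 <- tc2$groups[["cingulate-temporal"]]$conditions$ambiguous$clip_values
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("baseline t tests match a hand-computed t and one-tailed p", {
  fx <- make_group_fixture(effects = c(ambiguous = 0.2, affiliative = 0,
                                       aggressive = 0), n_per_cond = 5)
  tc <- group_timecourses(fx$seg, fx$roster, fx$supra)
  bt <- test_vs_baseline(tc)
  row <- bt[bt$group == "cingulate-temporal" & bt$condition == "ambiguous" &
              abs(bt$time_s - 6) < 1e-9, ]
  cv <- tc$groups[["cingulate-temporal"]]$conditions$ambiguous$clip_values
  v <- cv[, ncol(cv)]
  t_hand <- mean(v) / (sd(v) / sqrt(length(v)))
  p_hand <- pt(t_hand, df = length(v) - 1, lower.tail = FALSE)
  expect_equal(row$t, t_hand, tolerance = 1e-10)
  expect_equal(row$p, p_hand, tolerance = 1e-10)
  expect_equal(row$p_bonf, min(1, p_hand * 21 * 3), tolerance = 1e-10)
})

test_that("all-zero courses are never significant; shifts always are", {
  fx0 <- make_group_fixture(noise = 1e-9)
  bt0 <- test_vs_baseline(group_timecourses(fx0$seg, fx0$roster, fx0$supra))
  expect_true(all(bt0$p_bonf[abs(bt0$mean) < 1e-9] > 0.049))
  fx1 <- make_group_fixture(effects = c(ambiguous = 0.5, affiliative = 0.5,
                                        aggressive = 0.5),
                            n_per_cond = 30, noise = 1e-4)
  bt1 <- test_vs_baseline(group_timecourses(fx1$seg, fx1$roster, fx1$supra))
  post <- bt1[bt1$time_s > 0.5 & bt1$group == "cingulate-temporal", ]
  expect_true(all(post$p_bonf < 0.05))
})

test_that("condition contrasts match the normal-equations oracle", {
  fx <- make_group_fixture(effects = c(ambiguous = 0.3, affiliative = 0.1,
                                       aggressive = 0.05), n_per_cond = 7,
                           noise = 0.02)
  tc <- group_timecourses(fx$seg, fx$roster, fx$supra)
  ct <- contrast_glm(tc)
  g <- tc$groups[["cingulate-temporal"]]$conditions
  i <- length(tc$grid_s)
  w <- c(ambiguous = 2, affiliative = -1, aggressive = -1) / 3
  vals <- lapply(names(w), function(cc) g[[cc]]$clip_values[, i])
  X <- do.call(rbind, lapply(seq_along(vals), function(k) {
    cbind(a = as.numeric(k == 1), b = as.numeric(k == 2),
          c = as.numeric(k == 3))[rep(1, length(vals[[k]])), , drop = FALSE]
  }))
  y <- unlist(vals)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  est_hand <- sum(w * beta)
  row <- ct[ct$group == "cingulate-temporal" &
              ct$contrast == "ambiguous>others" &
              abs(ct$time_s - 6) < 1e-9, ]
  expect_equal(row$estimate, est_hand, tolerance = 1e-10)
  # equal condition means -> all contrast estimates 0
  fx0 <- make_group_fixture(effects = c(ambiguous = 0.2, affiliative = 0.2,
                                        aggressive = 0.2), noise = 1e-9)
  ct0 <- contrast_glm(group_timecourses(fx0$seg, fx0$roster, fx0$supra))
  expect_lt(max(abs(ct0$estimate), na.rm = TRUE), 1e-7)
  # sign structure: boosted condition positive, the others negative
  late <- ct[ct$time_s == 6, ]
  expect_gt(late$estimate[late$contrast == "ambiguous>others"], 0)
  expect_lt(late$estimate[late$contrast == "aggressive>others"], 0)
})
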