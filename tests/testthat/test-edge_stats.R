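cfg <- pipeline_config()

balanced_table <- function(values, n_subj = 3, n_sess = 4,
                           conds = c("aggressive", "affiliative", "ambiguous")) {
  g <- expand.grid(condition = conds,
                   session = seq_len(n_subj * n_sess),
                   stringsAsFactors = FALSE)
  g$subject <- paste0("M", (g$session - 1) %/% n_sess + 1)
  g$session <- paste0("s", g$session)
  g$edge <- 1L
  g$value <- values
  g[, c("subject", "session", "edge", "condition", "value")]
}

# independent split-plot oracle: brute-force balanced sums of squares
split_plot_F <- function(tab) {
  y <- tab$value
  cond <- factor(tab$condition)
  sess <- factor(tab$session)
  grand <- mean(y)
  sess_means <- tapply(y, sess, mean)
  within_ss <- sum((y - sess_means[sess])^2)
  cond_means <- tapply(y, cond, mean)
  S <- nlevels(sess); C <- nlevels(cond)
  ss_cond <- S * sum((cond_means - grand)^2)
  ss_err <- within_ss - ss_cond
  df1 <- C - 1; df2 <- (C - 1) * (S - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df = c(df1, df2), p = pf(Fv, df1, df2, lower.tail = FALSE))
}

test_that("condition means average exactly the assigned windows", {
  roster <- default_roster()
  ev <- event_table(c(0, 20, 40, 60), c(20, 20, 20, 140),
                    c("aggressive", "affiliative", "ambiguous", "blank"),
                    run = rep(1, 4))
  nwin <- 95
  vals <- matrix(0.4, 3, nwin)
  tn <- structure(list(values = vals, window_center_s = 16 + 2 * (0:(nwin - 1)),
                       window_run = rep(1, nwin), edges = edge_index(3),
                       window_len_volumes = 16, tr_s = 2, transformed = TRUE),
                  class = "synchrony_tensor")
  m <- condition_means(tn, ev, cfg, session = "s1", subject = "M1")
  expect_true(all(m$value == 0.4))
  expect_equal(nrow(m), 3 * 3)
  # five known windows of values 0.1..0.5 average to 0.3
  lab <- assign_windows(tn, ev, cfg)
  amb <- which(lab == "ambiguous")[1:5]
  tn$values[1, ] <- NA_real_
  tn$values[1, lab == "ambiguous"] <- 0.3
  tn$values[1, amb] <- seq(0.1, 0.5, by = 0.1)
  tn$values[is.na(tn$values)] <- 0.3
  m2 <- condition_means(tn, ev, cfg)
  amb_mean <- m2$value[m2$edge == 1 & m2$condition == "ambiguous"]
  expect_equal(amb_mean, mean(tn$values[1, lab == "ambiguous"]))
})

test_that("the repeated-measures ANOVA matches the sums-of-squares oracle", {
  with_seed(13, {
    tab <- balanced_table(rnorm(36))
    got <- rm_anova_edge(tab, 1, cfg)
    want <- split_plot_F(tab)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  })
})

test_that("a pure condition shift produces a near-zero p", {
  shift <- rep(c(0, 0, 0.5), 12)   # ambiguous elevated in every session
  with_seed(14, {
    tab <- balanced_table(rnorm(36, sd = 1e-3) + shift)
    got <- rm_anova_edge(tab, 1, cfg)
    want <- split_plot_F(tab)
    expect_equal(got$F, want$F, tolerance = 1e-6)
    expect_lt(got$p, 1e-12)
  })
})

test_that("identical condition means give F near zero and p near one", {
  vals <- rep(rnorm(12, 0.4, 0.05), each = 3)  # session level, no condition effect
  tab <- balanced_table(as.numeric(vals))
  got <- rm_anova_edge(tab, 1, cfg)
  expect_lt(got$F, 1e-10)
  expect_gt(got$p, 0.999)
})

test_that("degenerate tables are marked untestable instead of failing", {
  tab <- balanced_table(rnorm(36))
  expect_equal(rm_anova_edge(tab, 99, cfg), list(F = 0, df = c(NA, NA), p = 1))
  one_sess <- tab[tab$session == "s1", ]
  expect_equal(rm_anova_edge(one_sess, 1, cfg)$p, 1)
  # sessions missing a condition are dropped with a warning
  holed <- tab[!(tab$session == "s2" & tab$condition == "ambiguous"), ]
  expect_warning(got <- rm_anova_edge(holed, 1, cfg), "missing condition")
  expect_true(is.finite(got$F))
})

test_that("the sphericity correction scales both degrees of freedom", {
  with_seed(19, {
    tab <- balanced_table(rnorm(36))
    plain <- rm_anova_edge(tab, 1, cfg)
    gg <- rm_anova_edge(tab, 1, cfg, gg = TRUE)
    expect_true(gg$epsilon >= 0.5 && gg$epsilon <= 1)
    expect_equal(gg$F, plain$F, tolerance = 1e-12)
    expect_equal(gg$df, plain$df * gg$epsilon, tolerance = 1e-10)
    expect_equal(gg$p, pf(gg$F, gg$df[1], gg$df[2], lower.tail = FALSE),
                 tolerance = 1e-12)
  })
})

test_that("p-to-z is the exact upper-tail normal quantile map", {
  expect_identical(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.0202), 2.05, tolerance = 1e-3)
  expect_equal(p_to_z(0.9), -1.2816, tolerance = 1e-4)
  grid <- c(1e-8, 1e-4, 0.01, 0.3, 0.5, 0.7, 0.999)
  expect_equal(p_to_z(grid), qnorm(grid, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(pnorm(p_to_z(grid), lower.tail = FALSE), grid, tolerance = 1e-9)
  expect_warning(z0 <- p_to_z(0), "clipped")
  expect_true(is.finite(z0))
  expect_error(p_to_z(-0.1), "lie in")
  # two-tailed option
  expect_equal(p_to_z(0.05, tail = "two"), qnorm(0.975), tolerance = 1e-12)
})

test_that("thresholding selects by rule with a deterministic tie break", {
  ed <- edge_index(16)
  st <- data.frame(edge = 1:120, F = 0, df1 = 2, df2 = 70, p = 1, z = 0)
  st$z[c(5, 17, 40, 77, 101)] <- 3
  net <- threshold_network(st, cfg, 16, mode = "absolute")
  expect_equal(which(net$selected), c(5, 17, 40, 77, 101))
  expect_true(isSymmetric(net$adjacency))
  expect_equal(sum(diag(net$adjacency)), 0)
  prop <- suppressWarnings(threshold_network(st, cfg, 16, mode = "proportional"))
  expect_equal(sum(prop$selected), 18)   # ceil(0.15 * 120)
  expect_true(all(c(5, 17, 40, 77, 101) %in% which(prop$selected)))
  st0 <- st; st0$z <- 0
  expect_equal(sum(threshold_network(st0, cfg, 16)$selected), 0)
  expect_warning(threshold_network(st0, cfg, 16, mode = "proportional"), "tie")
})

test_that("degree equals brute-force neighbor counting", {
  # star on five nodes
  ed5 <- edge_index(5)
  sel <- ed5$i == 1
  star <- binary_network(sel, ed5, 5)
  expect_equal(unname(network_degree(star)), c(4, 1, 1, 1, 1))
  expect_equal(unname(network_degree(binary_network(rep(FALSE, 10), ed5, 5))),
               rep(0, 5))
  with_seed(15, {
    for (rep_i in 1:20) {
      sel <- runif(120) < 0.25
      net <- binary_network(sel, edge_index(16), 16)
      brute <- vapply(1:16, function(v) sum(net$adjacency[v, ] != 0), 0)
      expect_equal(unname(network_degree(net)), brute)
    }
  })
})

test_that("eigencentrality matches dense eigendecomposition", {
  # complete graph K4: all scores exactly 1/2
  k4 <- binary_network(rep(TRUE, 6), edge_index(4), 4)
  expect_equal(unname(eigencentrality(k4)), rep(0.5, 4), tolerance = 1e-10)
  # path of three nodes: (1, sqrt 2, 1)/2
  p3 <- binary_network(c(TRUE, FALSE, TRUE), edge_index(3), 3)
  expect_equal(unname(eigencentrality(p3)), c(0.5, sqrt(2) / 2, 0.5),
               tolerance = 1e-8)
  expect_warning(z <- eigencentrality(binary_network(rep(FALSE, 6),
                                                     edge_index(4), 4)),
                 "empty")
  expect_equal(unname(z), rep(0, 4))
  with_seed(16, {
    for (rep_i in 1:20) {
      sel <- runif(120) < 0.2
      if (!any(sel)) next
      net <- binary_network(sel, edge_index(16), 16)
      got <- eigencentrality(net)
      comp <- socialsync:::graph_components(net$adjacency)
      big <- which(comp == which.max(tabulate(comp)))
      es <- eigen(net$adjacency[big, big], symmetric = TRUE)
      v <- abs(es$vectors[, 1])
      want <- numeric(16)
      want[big] <- v / sqrt(sum(v^2))
      expect_equal(unname(got), want, tolerance = 1e-8)
    }
  })
})

test_that("degree and centrality are equivariant under ROI relabeling", {
  with_seed(17, {
    sel <- runif(120) < 0.3
    net <- binary_network(sel, edge_index(16), 16)
    perm <- sample(16)
    A2 <- net$adjacency[perm, perm]
    ed <- edge_index(16)
    sel2 <- A2[cbind(ed$i, ed$j)] == 1
    net2 <- binary_network(sel2, ed, 16)
    expect_equal(unname(network_degree(net2)),
                 unname(network_degree(net))[perm])
    expect_equal(unname(eigencentrality(net2)),
                 unname(eigencentrality(net))[perm], tolerance = 1e-8)
  })
})

test_that("boosted edges show higher ambiguous than affiliative means", {
  roster <- default_roster()
  spec <- default_coupling_spec(delta = 0.6)
  ed <- edge_index(16)
  dk <- paste(spec$designated_edges$i, spec$designated_edges$j)
  desig <- paste(ed$i, ed$j) %in% dk
  cfg_l <- cfg
  wins <- 0L
  n_seeds <- 10
  sch <- generate_schedule(cfg_l, seed = 31)
  for (s in seq_len(n_seeds)) {
    b <- simulate_session(sch, roster, spec, cfg_l, seed = 40 + s,
                          n_repeats = 2)
    res <- suppressWarnings(analyze_session(b, cfg_l))
    m <- condition_means(res$tensor, sch, cfg_l)
    amb <- m$value[m$condition == "ambiguous"][desig]
    aff <- m$value[m$condition == "affiliative"][desig]
    wins <- wins + (mean(amb) > mean(aff))
  }
  expect_gte(wins, 8)
})
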