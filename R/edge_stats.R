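#' Binary network over ROIs
#'
#' Symmetric 0/1 adjacency with zero diagonal plus the per-edge selection
#' vector (canonical edge order) and a provenance note describing the
#' threshold rule that produced it.
#'
#' @param selected logical vector over canonical edges.
#' @param edges edge table from [edge_index()].
#' @param n_rois number of ROIs.
#' @param labels optional ROI labels.
#' @param provenance character note.
#' @return an object of class `binary_network`.
#' @export
binary_network <- function(selected, edges, n_rois, labels = NULL,
                           provenance = "") {
  adj <- matrix(0L, n_rois, n_rois, dimnames = list(labels, labels))
  sel <- which(selected)
  adj[cbind(edges$i[sel], edges$j[sel])] <- 1L
  adj[cbind(edges$j[sel], edges$i[sel])] <- 1L
  structure(list(adjacency = adj, selected = as.logical(selected),
                 edges = edges, provenance = provenance),
            class = "binary_network")
}

# Select the strongest ceil(frac * E) edges of a value vector with the
# canonical deterministic tie rule (earlier edge order wins); warns when a
# tie crosses the selection boundary.
threshold_by_value <- function(values, edges, n_rois, frac, labels = NULL,
                               provenance = "") {
  E <- length(values)
  m <- ceiling(frac * E)
  ord <- order(-values, seq_len(E))
  keep <- logical(E)
  keep[ord[seq_len(m)]] <- TRUE
  if (m < E && values[ord[m]] == values[ord[m + 1]]) {
    warn_sync("tie at the selection boundary (value %.6g); canonical edge order breaks it",
              values[ord[m]])
  }
  binary_network(keep, edges, n_rois, labels, provenance)
}

#' Session-by-condition mean synchrony per edge
#'
#' Averages a cleaned, transformed, repeat-averaged synchrony tensor over
#' the windows assigned (see [assign_windows()]) to each social-behavior
#' condition, yielding one row per edge and condition for the session.
#' Conditions with no qualifying windows are omitted (a note records how
#' many).
#'
#' @param tensor the session's unique-clock `synchrony_tensor`.
#' @param events the unique-content [event_table].
#' @param config a [pipeline_config].
#' @param session,subject identifiers stamped on the rows.
#' @param conditions condition labels (default: the three social behaviors).
#' @return data.frame with columns subject, session, edge, condition, value.
#' @export
condition_means <- function(tensor, events, config, session = "s1",
                            subject = "m1", conditions = SOCIAL_CATEGORIES) {
  lab <- assign_windows(tensor, events, config)
  out <- list()
  for (cond in conditions) {
    sel <- lab == cond
    if (!any(sel)) next
    out[[cond]] <- data.frame(subject = subject, session = session,
                              edge = seq_len(nrow(tensor$values)),
                              condition = cond,
                              value = rowMeans(tensor$values[, sel, drop = FALSE]),
                              stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warn_sync("session %s: no windows in any requested condition", session)
    return(data.frame(subject = character(0), session = character(0),
                      edge = integer(0), condition = character(0),
                      value = numeric(0)))
  }
  if (length(out) < length(conditions)) {
    warn_sync("session %s: no windows for condition(s) %s", session,
              paste(setdiff(conditions, names(out)), collapse = ", "))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Edge-wise repeated-measures ANOVA across social conditions
#'
#' For one edge's session-by-condition means, a split-plot ANOVA with
#' subject (monkey) as the between-session factor and social condition as
#' the within-session factor: `value ~ subject + condition + Error(session)`.
#' The reported statistic is the within-stratum condition F with its
#' degrees of freedom and p value. Sessions missing any condition are
#' dropped with a warning; an edge with fewer than two usable sessions per
#' subject is marked untestable (`F = 0`, `p = 1`). Sphericity is not
#' corrected, and the subject-by-condition interaction is pooled into the
#' error unless `config$anova_interaction` is set.
#'
#' @param means the table from [condition_means()] (stacked over sessions).
#' @param edge edge index to test.
#' @param config a [pipeline_config].
#' @param gg logical; apply the Greenhouse-Geisser sphericity correction
#'   (epsilon estimated from the session-by-condition covariance, both
#'   degrees of freedom scaled). Off by default to match the uncorrected
#'   degrees of freedom the emulated analysis reports.
#' @return list with `F`, `df` (numerator, denominator), `p`, and (when
#'   `gg = TRUE`) `epsilon`.
#' @export
rm_anova_edge <- function(means, edge, config = pipeline_config(),
                          gg = FALSE) {
  d <- means[means$edge == edge, , drop = FALSE]
  if (!nrow(d)) return(list(F = 0, df = c(NA, NA), p = 1))
  conds <- sort(unique(means$condition))
  counts <- table(d$session)
  complete <- names(counts)[counts == length(conds)]
  if (length(complete) < length(counts)) {
    warn_sync("edge %s: dropping %d session(s) with missing condition cells",
              edge, length(counts) - length(complete))
  }
  d <- d[d$session %in% complete, , drop = FALSE]
  per_subj <- table(unique(d[c("subject", "session")])$subject)
  if (!length(per_subj) || any(per_subj < 2)) {
    return(list(F = 0, df = c(NA, NA), p = 1))
  }
  d$subject <- factor(d$subject)
  d$session <- factor(d$session)
  d$condition <- factor(d$condition)
  # degenerate input: no within-session condition variation at all (the
  # F ratio would be 0/0) -> no evidence of a condition effect
  sess_means <- tapply(d$value, d$session, mean)
  if (max(abs(d$value - sess_means[as.character(d$session)])) < 1e-12) {
    return(list(F = 0, df = c(NA, NA), p = 1))
  }
  fml <- if (nlevels(d$subject) < 2) {
    value ~ condition + Error(session)
  } else if (config$anova_interaction) {
    value ~ subject * condition + Error(session)
  } else {
    value ~ subject + condition + Error(session)
  }
  fit <- stats::aov(fml, data = d)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  row <- grep("^condition\\s*$", trimws(rownames(within)))
  if (!length(row)) return(list(F = 0, df = c(NA, NA), p = 1))
  Fv <- within[row, "F value"]
  df1 <- within[row, "Df"]
  df2 <- within[nrow(within), "Df"]
  if (!gg) {
    return(list(F = Fv, df = c(df1, df2), p = within[row, "Pr(>F)"]))
  }
  # Greenhouse-Geisser: epsilon from the session x condition covariance
  wide <- stats::reshape(d[, c("session", "condition", "value")],
                         idvar = "session", timevar = "condition",
                         direction = "wide")
  S <- stats::cov(as.matrix(wide[, -1]))
  k <- ncol(S)
  num <- (k * (mean(diag(S)) - mean(S)))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
  eps <- max(min(num / den, 1), 1 / (k - 1))
  list(F = Fv, df = c(df1 * eps, df2 * eps),
       p = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
       epsilon = eps)
}

#' Per-edge statistics for every edge
#'
#' Runs [rm_anova_edge()] over all edges and converts p values to z with
#' [p_to_z()].
#'
#' @param means stacked [condition_means()] table.
#' @param n_edges total edge count (defaults to the max edge index present).
#' @param config a [pipeline_config].
#' @return data.frame of class `edge_stat_matrix`: edge, F, df1, df2, p, z.
#' @export
edge_stat_matrix <- function(means, n_edges = max(means$edge), config = pipeline_config()) {
  rows <- lapply(seq_len(n_edges), function(e) {
    st <- rm_anova_edge(means, e, config)
    data.frame(edge = e, F = st$F, df1 = st$df[1], df2 = st$df[2], p = st$p)
  })
  out <- do.call(rbind, rows)
  out$z <- p_to_z(out$p, tail = config$p_tail)
  class(out) <- c("edge_stat_matrix", "data.frame")
  out
}

#' Convert p values to z statistics
#'
#' One-tailed mapping by default: `z = qnorm(1 - p)`, the upper-tail
#' standard-normal quantile, so `p = 0.5` maps to `z = 0` and the
#' conventional neuroimaging threshold z > 2.05 corresponds to a tail mass
#' of about 0.0202. `tail = "two"` maps `z = qnorm(1 - p/2)`. p values of
#' exactly 0 are clipped to the smallest representable positive double
#' with a warning.
#'
#' @param p probabilities in (0, 1].
#' @param tail `"one"` (default) or `"two"`.
#' @return z values (possibly `-Inf` at p = 1 under the one-tailed map).
#' @export
p_to_z <- function(p, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_sync("p values must lie in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warn_sync("p = 0 clipped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  if (tail == "one") stats::qnorm(p, lower.tail = FALSE)
  else stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Threshold an edge-statistic matrix into a binary network
#'
#' Default mode `"absolute"` keeps edges with `z > z_threshold` (the
#' z > 2.05 rule); mode `"proportional"` keeps the strongest
#' `ceiling(top_edge_frac * E)` edges by z (18 of 120 for 16 ROIs at 15%).
#' Boundary ties are broken by canonical edge order with a warning.
#'
#' @param stats an `edge_stat_matrix`.
#' @param config a [pipeline_config].
#' @param n_rois number of ROIs.
#' @param mode `"absolute"` or `"proportional"`.
#' @param labels optional ROI labels.
#' @return a `binary_network`.
#' @export
threshold_network <- function(stats, config, n_rois,
                              mode = c("absolute", "proportional"),
                              labels = NULL) {
  mode <- match.arg(mode)
  ed <- edge_index(n_rois)
  if (nrow(stats) != nrow(ed)) stop_sync("edge coverage incomplete: %d of %d",
                                         nrow(stats), nrow(ed))
  if (mode == "absolute") {
    binary_network(stats$z > config$z_threshold, ed, n_rois, labels,
                   sprintf("z > %.3g", config$z_threshold))
  } else {
    threshold_by_value(stats$z, ed, n_rois, config$top_edge_frac, labels,
                       sprintf("top %.0f%% by z", 100 * config$top_edge_frac))
  }
}

#' Node degree of a binary network
#'
#' @param net a `binary_network`.
#' @return named integer vector of per-ROI connection counts.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  rowSums(net$adjacency)
}

#' Eigenvector centrality of a binary network
#'
#' The entrywise-nonnegative leading eigenvector of the adjacency matrix,
#' normalized to unit Euclidean norm, computed by power iteration on the
#' largest connected component (ties between equal-sized components broken
#' by lowest node index); nodes outside that component score 0. An empty
#' network returns all zeros with a warning.
#'
#' @param net a `binary_network`.
#' @param tol convergence tolerance of the power iteration.
#' @return named numeric vector of centrality scores.
#' @export
eigencentrality <- function(net, tol = 1e-12) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$adjacency
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  if (sum(A) == 0) {
    warn_sync("empty network: eigenvector centrality undefined, returning zeros")
    return(out)
  }
  comp <- graph_components(A)
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  B <- A[big, big, drop = FALSE]
  v <- rep(1 / sqrt(length(big)), length(big))
  # shift by +I so bipartite components (paired +-lambda eigenvalues)
  # cannot make the iteration oscillate; eigenvectors are unchanged
  for (it in seq_len(10000)) {
    w <- as.numeric(B %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  out[big] <- abs(v)
  out
}

# connected components of an undirected adjacency matrix (BFS)
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(A[v, ] != 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}
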