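#' ROI roster
#'
#' A roster describes the network's regions of interest: a unique label, a
#' hemisphere, an anatomical group and (optionally) a coordinate triple in
#' template space. Edge-level analyses derive their anatomical edge classes
#' (temporo-temporal, cingulate-temporal, ...) from the `group` column.
#'
#' @param label character vector of unique ROI labels.
#' @param hemisphere `"left"` or `"right"` per ROI.
#' @param group anatomical group per ROI: one of `"temporal"`,
#'   `"cingulate"`, `"premotor"`, `"parietal"`, `"subcortical"`, `"other"`.
#' @param x,y,z optional template-space coordinates (mm).
#' @return a `data.frame` of class `roi_roster`.
#' @export
roi_roster <- function(label, hemisphere, group, x = NA_real_, y = NA_real_,
                       z = NA_real_) {
  label <- as.character(label)
  if (length(label) < 2) stop_sync("a roster needs at least 2 ROIs")
  if (anyDuplicated(label)) {
    stop_sync("duplicate ROI labels: %s",
              paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  hemisphere <- match.arg(as.character(hemisphere),
                          c("left", "right"), several.ok = TRUE)
  groups_ok <- c("temporal", "cingulate", "premotor", "parietal",
                 "subcortical", "other")
  group <- as.character(group)
  if (!all(group %in% groups_ok)) {
    stop_sync("unknown ROI group(s): %s",
              paste(setdiff(group, groups_ok), collapse = ", "))
  }
  r <- data.frame(label = label,
                  hemisphere = rep_len(hemisphere, length(label)),
                  group = rep_len(group, length(label)),
                  x = rep_len(x, length(label)),
                  y = rep_len(y, length(label)),
                  z = rep_len(z, length(label)),
                  stringsAsFactors = FALSE)
  class(r) <- c("roi_roster", "data.frame")
  r
}

#' Default synthetic 16-ROI social-network roster
#'
#' A symmetric stand-in roster (8 ROIs per hemisphere) for the temporal,
#' cingulate and premotor social-network nodes used throughout the package:
#' five temporal ROIs along the superior temporal sulcus, two cingulate
#' gyrus ROIs and one premotor ROI per hemisphere. Coordinates are synthetic
#' placeholders, not template-derived.
#'
#' @return a `roi_roster` with 16 rows.
#' @export
default_roster <- function() {
  base <- data.frame(
    stem = c("STSa", "STSm", "STSp", "TEa", "TPO", "CGa", "CGp", "PMv"),
    group = c("temporal", "temporal", "temporal", "temporal", "temporal",
              "cingulate", "cingulate", "premotor"),
    x = c(22, 24, 25, 20, 26, 3, 4, 18),
    y = c(8, 2, -4, 6, -8, 14, 6, 12),
    z = c(2, 4, 6, -4, 8, 16, 18, 14)
  )
  roi_roster(
    label = c(paste0(base$stem, "_L"), paste0(base$stem, "_R")),
    hemisphere = rep(c("left", "right"), each = 8),
    group = rep(base$group, 2),
    x = c(-base$x, base$x), y = rep(base$y, 2), z = rep(base$z, 2)
  )
}

#' Canonical edge ordering of an ROI network
#'
#' Enumerates every unordered ROI pair exactly once in lexicographic order
#' of (i, j), i < j, over roster order. This ordering fixes the row layout
#' of every edge-indexed object in the package.
#'
#' @param n_rois number of ROIs (>= 2).
#' @return data.frame with integer columns `i`, `j` (1-based) and
#'   `n*(n-1)/2` rows.
#' @export
edge_index <- function(n_rois) {
  n <- as.integer(n_rois)
  if (is.na(n) || n < 2) stop_sync("edge_index needs n_rois >= 2")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

edge_labels <- function(roster, edges = edge_index(nrow(roster))) {
  paste(roster$label[edges$i], roster$label[edges$j], sep = "--")
}

# Map each ROI to a coarse lobe used in the simplified connection summaries.
roi_lobe <- function(roster) {
  ifelse(roster$group %in% c("cingulate", "premotor"), "frontal",
         ifelse(roster$group %in% c("temporal", "parietal"), "temporal",
                "other"))
}

#' Anatomical class of every edge
#'
#' Classifies each unordered ROI pair into one of the five anatomical edge
#' groups used in the clip-aligned analysis (temporo-temporal,
#' cingulate-temporal, cingulate-cingulate, premotor-temporal,
#' premotor-cingulate); pairs outside these classes get `"other"`.
#'
#' @param roster an `roi_roster`.
#' @param edges optional edge table from [edge_index()].
#' @return character vector, one class per edge.
#' @export
edge_groups <- function(roster, edges = edge_index(nrow(roster))) {
  g1 <- roster$group[edges$i]
  g2 <- roster$group[edges$j]
  pair <- function(a, b) (g1 == a & g2 == b) | (g1 == b & g2 == a)
  out <- rep("other", nrow(edges))
  out[pair("temporal", "temporal")] <- "temporo-temporal"
  out[pair("cingulate", "temporal")] <- "cingulate-temporal"
  out[g1 == "cingulate" & g2 == "cingulate"] <- "cingulate-cingulate"
  out[pair("premotor", "temporal")] <- "premotor-temporal"
  out[pair("premotor", "cingulate")] <- "premotor-cingulate"
  out
}

#' @export
print.roi_roster <- function(x, ...) {
  cat(sprintf("<roi_roster> %d ROIs (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
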