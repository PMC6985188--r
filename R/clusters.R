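#' Rule for calling PDX1-high cells
#'
#' The positivity threshold is a knob, not a claim: published positive-cell
#' frequencies are sensitive to it, so three modes are exposed.
#'
#' @param mode `"mean_plus_ksd"` (default, threshold = mean + k·sd of the
#'   nuclear means), `"percentile"` (top (100 − p)% by rank, ties broken
#'   stably by original order) or `"absolute"` (fixed intensity cutoff).
#' @param value `k` (> 0), the percentile `p` in (0, 100), or the absolute
#'   cutoff (> 0), respectively.
#' @return object of class `high_cell_rule`.
#' @export
high_cell_rule <- function(mode = c("mean_plus_ksd", "percentile", "absolute"),
                           value = 2) {
  mode <- match.arg(mode)
  ok <- switch(mode,
               mean_plus_ksd = value > 0,
               percentile = value > 0 && value < 100,
               absolute = value > 0)
  if (!ok) stop(sprintf("invalid parameter %g for mode %s", value, mode))
  structure(list(mode = mode, value = value), class = "high_cell_rule")
}

#' Flag PDX1-high cells from nuclear intensities
#'
#' @param nuclear_means numeric vector of background-subtracted per-nucleus
#'   mean intensities.
#' @param rule a [high_cell_rule()].
#' @return logical vector of flags with attribute `threshold` (the applied
#'   cutoff; for the percentile mode, the smallest flagged intensity).
#' @export
classify_high_cells <- function(nuclear_means, rule = high_cell_rule()) {
  stopifnot(inherits(rule, "high_cell_rule"))
  n <- length(nuclear_means)
  if (rule$mode != "absolute" && n < 10)
    stop("statistical high-cell rules need at least 10 cells")
  if (rule$mode == "percentile") {
    k <- floor(n * (100 - rule$value) / 100 + 1e-9)
    flags <- rep(FALSE, n)
    if (k > 0) {
      ord <- order(nuclear_means, seq_len(n), decreasing = c(TRUE, FALSE),
                   method = "radix")
      flags[ord[seq_len(k)]] <- TRUE
    }
    thr <- if (k > 0) min(nuclear_means[flags]) else Inf
  } else {
    thr <- switch(rule$mode,
      mean_plus_ksd = mean(nuclear_means) + rule$value * stats::sd(nuclear_means),
      absolute = rule$value)
    flags <- nuclear_means > thr
    if (rule$mode == "mean_plus_ksd" && stats::sd(nuclear_means) == 0)
      warning("constant intensities: no cells exceed mean + k*sd")
  }
  attr(flags, "threshold") <- thr
  flags
}

#' Detect spatial clusters of high cells
#'
#' Single-linkage grouping of the flagged cells: two cells are linked when
#' their centroid distance is at most `linkage_radius`; connected groups with
#' at least `min_cluster_size` members are reported with the geometry of
#' their centroid convex hull (area, equivalent-circle diameter,
#' circularity 4πA/P²).
#'
#' @param centroids two-column matrix or data.frame of (x, y) positions, µm.
#' @param flags logical vector marking high cells.
#' @param linkage_radius maximum link distance, µm (default 30, about two
#'   cell diameters).
#' @param min_cluster_size minimum member count (default 5).
#' @return data.frame with one row per cluster: `cluster`, `n_cells`,
#'   `hull_area_um2`, `equiv_diameter_um`, `circularity`, `cx_um`, `cy_um`,
#'   plus a list-column `members` of member indices (into the full input).
#'   No flagged cells gives an empty data.frame.
#' @export
detect_high_clusters <- function(centroids, flags, linkage_radius = 30,
                                 min_cluster_size = 5) {
  if (linkage_radius <= 0) stop("linkage_radius must be > 0")
  centroids <- as.matrix(centroids)[, 1:2, drop = FALSE]
  idx <- which(flags)
  empty <- data.frame(cluster = integer(0), n_cells = integer(0),
                      hull_area_um2 = numeric(0), equiv_diameter_um = numeric(0),
                      circularity = numeric(0), cx_um = numeric(0),
                      cy_um = numeric(0))
  empty$members <- list()
  if (length(idx) == 0) return(empty)
  pts <- centroids[idx, , drop = FALSE]
  grp <- if (length(idx) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(pts), method = "single")
    stats::cutree(hc, h = linkage_radius)
  }
  keep <- as.integer(names(which(table(grp) >= min_cluster_size)))
  if (!length(keep)) return(empty)
  rows <- lapply(seq_along(keep), function(i) {
    g <- keep[i]
    mem <- idx[grp == g]
    p <- centroids[mem, , drop = FALSE]
    geom <- hull_geometry(p)
    out <- data.frame(cluster = i, n_cells = length(mem),
                      hull_area_um2 = geom$area,
                      equiv_diameter_um = geom$equiv_diameter,
                      circularity = geom$circularity,
                      cx_um = mean(p[, 1]), cy_um = mean(p[, 2]))
    out$members <- list(mem)
    out
  })
  do.call(rbind, rows)
}

# Convex-hull area / perimeter metrics of a point set.
hull_geometry <- function(p) {
  if (nrow(p) < 3) {
    d <- if (nrow(p) == 2) sqrt(sum((p[1, ] - p[2, ])^2)) else 0
    return(list(area = 0, equiv_diameter = d, circularity = NA_real_))
  }
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) {
    d <- max(stats::dist(p))
    return(list(area = 0, equiv_diameter = d, circularity = NA_real_))
  }
  nxt <- c(2:nh, 1)
  area <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  per <- sum(sqrt(rowSums((hp[nxt, ] - hp)^2)))
  circ <- if (per > 0) min(4 * pi * area / per^2, 1) else NA_real_
  list(area = area, equiv_diameter = 2 * sqrt(area / pi), circularity = circ)
}
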