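# Shared fixtures and independent oracles for the test suite.

# A small, fast microwell spec for unit tests (sparser control ring, no noise
# unless asked). min_separation_frac = 1.15 keeps nuclei non-overlapping so
# segmentation counts are exact by construction.
quick_well_spec <- function(seed, ...) {
  args <- list(...)
  defaults <- list(well_diameter = 150, n_cells = 25, noise_sd = 0,
                   min_separation_frac = 1.15, control_density = 800,
                   seed = seed)
  do.call(synthetic_well_spec, utils::modifyList(defaults, args))
}

# Nearest-neighbour match of estimated centroids to truth positions; returns
# per-truth distances (Inf if no estimate nearby).
match_centroids <- function(truth_xy, est_xy) {
  vapply(seq_len(nrow(truth_xy)), function(i) {
    if (nrow(est_xy) == 0) return(Inf)
    min(sqrt((est_xy[, 1] - truth_xy[i, 1])^2 +
             (est_xy[, 2] - truth_xy[i, 2])^2))
  }, numeric(1))
}

# Brute-force single-linkage clustering via union-find over all pairs with
# distance <= radius. Independent of hclust.
union_find_clusters <- function(pts, radius) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sum((pts[i, ] - pts[j, ])^2) <= radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical partition signature so two clusterings can be compared as set
# partitions regardless of label values.
partition_signature <- function(labels) {
  groups <- split(seq_along(labels), labels)
  paste(sort(vapply(groups, function(g) paste(g, collapse = ","),
                    character(1))), collapse = "|")
}

# Hand-computed one-way ANOVA + Tukey-Kramer oracle (sums of squares and
# ptukey directly; no aov/TukeyHSD).
anova_tukey_oracle <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1; dfw <- N - k
  msw <- ssw / dfw
  Fval <- (ssb / dfb) / msw
  p <- stats::pf(Fval, dfb, dfw, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  tukey <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[j] - means[i]) / se
    stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
  })
  names(tukey) <- apply(pairs, 2, function(ij)
    paste(names(groups)[ij[2]], names(groups)[ij[1]], sep = "-"))
  list(F = Fval, p = p, tukey = tukey)
}
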