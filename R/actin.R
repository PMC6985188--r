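#' Averaged radial actin intensity profile of a microwell
#'
#' Samples the actin channel along `n_lines` full diameters through the well
#' centre at equally spaced angles (k * pi / n_lines), at 1-pixel spacing with
#' bilinear interpolation, and averages the lines pointwise. With
#' `fold = TRUE` symmetric positions are additionally averaged into a radial
#' profile over `0..R`, so 8 diameters contribute 16 half-line samples per
#' radius.
#'
#' @param actin numeric matrix (background-subtracted recommended).
#' @param well a [well_geometry()] (µm).
#' @param pixel_size µm/px.
#' @param n_lines number of diameters (default 8).
#' @param fold return the folded 0..R profile (default) or the full −R..+R
#'   diameter profile.
#' @return object of class `actin_profile`: list with `positions` (µm,
#'   strictly increasing), `intensity`, `n_lines`, `folded`, `R`.
#' @export
radial_profile <- function(actin, well, pixel_size, n_lines = 8, fold = TRUE) {
  stopifnot(inherits(well, "well_geometry"), n_lines >= 1)
  R_px <- well$R / pixel_size
  if (R_px < 8) stop("profile under-sampled: well radius < 8 px")
  m <- floor(R_px)
  t_um <- (-m:m) * pixel_size
  angles <- (seq_len(n_lines) - 1) * pi / n_lines
  acc <- numeric(length(t_um))
  for (th in angles) {
    xs <- (well$cx + t_um * cos(th)) / pixel_size
    ys <- (well$cy + t_um * sin(th)) / pixel_size
    acc <- acc + bilinear_sample(actin, xs, ys)
  }
  prof <- acc / n_lines
  out <- if (fold) {
    pos <- t_um[t_um >= 0]
    int <- (prof[(m + 1):(2 * m + 1)] + prof[(m + 1):1]) / 2
    list(positions = pos, intensity = int)
  } else {
    list(positions = t_um, intensity = prof)
  }
  structure(c(out, list(n_lines = n_lines, folded = fold, R = well$R)),
            class = "actin_profile")
}

#' Fold a diameter profile into a radial profile
#'
#' Averages symmetric positions of a −R..+R profile into 0..R. Folding an
#' already folded profile is a no-op.
#'
#' @param profile an `actin_profile`.
#' @return a folded `actin_profile`.
#' @export
fold_profile <- function(profile) {
  stopifnot(inherits(profile, "actin_profile"))
  if (profile$folded) return(profile)
  m <- (length(profile$positions) - 1) / 2
  structure(list(
    positions = profile$positions[(m + 1):(2 * m + 1)],
    intensity = (profile$intensity[(m + 1):(2 * m + 1)] +
                 profile$intensity[(m + 1):1]) / 2,
    n_lines = profile$n_lines, folded = TRUE, R = profile$R
  ), class = "actin_profile")
}

#' Classify the radial actin architecture of a well
#'
#' Assigns one of the three archetypes seen in confined colonies: `uniform`
#' (flat profile), `peripheral` (intensity highest at the well edge — the
#' contractile-ring signature) or `central` (highest at the centre). The rule
#' operates on the folded profile: with centre mean `C` (inner 30% of R),
#' edge mean `E` (outer 20%) and mid mean `M`, a profile is uniform when its
#' coefficient of variation is below `flatness_cv`; otherwise peripheral when
#' `E / max(C, M) > contrast_threshold`, central when
#' `C / max(E, M) > contrast_threshold`, and otherwise the larger of centre
#' and edge wins with the call flagged weak. All criteria are ratios, so the
#' label is invariant under positive gain.
#'
#' @param profile an `actin_profile` (folded, or foldable).
#' @param contrast_threshold minimum edge/centre contrast ratio (default
#'   1.25).
#' @param flatness_cv coefficient-of-variation bound below which the profile
#'   counts as flat (default 0.15).
#' @return object of class `actin_class`: list with `class` (factor level
#'   uniform/peripheral/central), `center_mean`, `edge_mean`, `mid_mean`,
#'   `cv`, `weak` (logical).
#' @export
classify_architecture <- function(profile, contrast_threshold = 1.25,
                                  flatness_cv = 0.15) {
  stopifnot(inherits(profile, "actin_profile"))
  profile <- fold_profile(profile)
  if (length(profile$positions) < 16)
    stop("profile too short: need >= 16 samples")
  r <- profile$positions; v <- profile$intensity; R <- max(r)
  C <- mean(v[r <= 0.3 * R])
  E <- mean(v[r >= 0.8 * R])
  M <- mean(v[r > 0.3 * R & r < 0.8 * R])
  mu <- mean(v)
  cv <- if (mu > 0) stats::sd(v) / mu else Inf
  weak <- FALSE
  cls <- if (cv < flatness_cv) {
    "uniform"
  } else if (E / max(C, M) > contrast_threshold) {
    "peripheral"
  } else if (C / max(E, M) > contrast_threshold) {
    "central"
  } else {
    weak <- TRUE
    if (C >= E) "central" else "peripheral"
  }
  structure(list(class = cls, center_mean = C, edge_mean = E, mid_mean = M,
                 cv = cv, weak = weak),
            class = "actin_class")
}

#' @export
print.actin_class <- function(x, ...) {
  cat(sprintf("<actin_class> %s (C=%.2f, E=%.2f, M=%.2f, cv=%.3f%s)\n",
              x$class, x$center_mean, x$edge_mean, x$mid_mean, x$cv,
              if (x$weak) ", weak" else ""))
  invisible(x)
}

#' Distribution of actin architectures over wells, by group
#'
#' Tabulates the proportion of wells per architecture class within each group
#' (typically a timepoint).
#'
#' @param labels character vector of class labels (or list of `actin_class`
#'   objects).
#' @param group grouping vector of the same length (e.g. hours in culture).
#' @return data.frame with `group`, `class`, `count`, `n`, `proportion`;
#'   proportions sum to 1 within each group.
#' @export
architecture_distribution <- function(labels, group = rep("all", length(labels))) {
  if (is.list(labels))
    labels <- vapply(labels, function(l) l$class, character(1))
  if (length(labels) == 0) stop("no labels supplied")
  if (length(group) != length(labels)) stop("group and labels lengths differ")
  if (any(tabulate(factor(group)) == 0)) stop("empty group")
  classes <- c("uniform", "peripheral", "central")
  out <- do.call(rbind, lapply(split(labels, group), function(l) {
    cnt <- table(factor(l, levels = classes))
    data.frame(class = classes, count = as.integer(cnt), n = length(l),
               proportion = as.integer(cnt) / length(l))
  }))
  out <- cbind(group = rep(names(split(labels, group)), each = length(classes)),
               out)
  rownames(out) <- NULL
  out
}
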