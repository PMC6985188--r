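#' Specification of a synthetic microwell colony image
#'
#' Describes one confined colony on a circular adhesive island, surrounded by
#' an unconfined monolayer ring that serves as the in-image normalization
#' control. All lengths are in µm. The defaults emulate pancreatic-endoderm
#' colonies on 150/300/500 µm micropatterns after 72 h of confined culture:
#' nuclei concentrated toward the well centre, nuclear-enriched transcription
#' factor channels with a configurable nuclear-to-cytoplasmic (N:C) ratio, and
#' one of three radial F-actin architectures.
#'
#' @param well_diameter well diameter in µm (conventionally 150, 300 or 500).
#' @param pixel_size µm per pixel.
#' @param n_cells number of nuclei in the well; `NULL` picks a
#'   diameter-dependent default reflecting the observed decrease of colony
#'   density with well diameter (50 / 160 / 300 cells for 150 / 300 / 500 µm).
#' @param radial_density_profile non-negative weights (length `n_zones`,
#'   summing to 1) giving the expected share of nuclei per equal-area
#'   concentric zone, innermost first.
#' @param n_zones number of equal-area zones the profile refers to.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius distribution, µm.
#' @param tf_nuclear_mean true mean nuclear intensity (a.u.) of the TF
#'   channels; scalar or named vector `c(tf1 = ..., tf2 = ...)`.
#' @param tf_nc_ratio true nuclear:cytoplasmic intensity ratio per TF channel;
#'   scalar or named vector.
#' @param tf_control_mean nuclear TF intensity of cells in the unconfined
#'   control ring (defaults to `tf_nuclear_mean`, i.e. no confinement effect).
#' @param actin_class one of `"uniform"`, `"peripheral"`, `"central"`.
#' @param actin_base baseline actin intensity over the tissue, a.u.
#' @param actin_peak_amplitude amplitude of the peripheral ring / central dome
#'   above baseline, a.u.
#' @param dapi_peak peak amplitude of the nuclear counterstain blobs, a.u.
#' @param background_level additive background, a.u. (all channels).
#' @param noise_sd standard deviation of additive Gaussian read noise, a.u.
#' @param control_density nuclei density of the unconfined control ring,
#'   cells/mm² (0 disables the ring entirely).
#' @param control_gap,control_width the control ring spans radii
#'   `R + control_gap` to `R + control_gap + control_width` around the well.
#' @param min_separation_frac two nuclei are accepted only if their centre
#'   distance exceeds this fraction of the sum of their radii.
#' @param max_retries placement attempts per nucleus before giving up.
#' @param zone_margin_um nuclei are kept this far away from zone boundaries so
#'   that the ground-truth zone label is unambiguous at sub-pixel centroid
#'   accuracy.
#' @param seed RNG seed used by the renderer (required for reproducibility).
#' @return a list of class `synthetic_well_spec`.
#' @export
synthetic_well_spec <- function(well_diameter = 300,
                                pixel_size = 0.65,
                                n_cells = NULL,
                                radial_density_profile = c(0.35, 0.30, 0.25, 0.10),
                                n_zones = length(radial_density_profile),
                                nucleus_radius_mean = 5,
                                nucleus_radius_sd = 0.5,
                                tf_nuclear_mean = 100,
                                tf_nc_ratio = 2,
                                tf_control_mean = NULL,
                                actin_class = c("uniform", "peripheral", "central"),
                                actin_base = 40,
                                actin_peak_amplitude = 60,
                                dapi_peak = 150,
                                background_level = 10,
                                noise_sd = 2,
                                control_density = 1500,
                                control_gap = 20,
                                control_width = 100,
                                min_separation_frac = 0.6,
                                max_retries = 1000,
                                zone_margin_um = 1,
                                seed = 1L) {
  actin_class <- match.arg(actin_class)
  if (well_diameter <= 0) stop("well_diameter must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(n_cells)) {
    n_cells <- round(stats::approx(c(150, 300, 500), c(50, 160, 300),
                                   xout = well_diameter, rule = 2)$y)
  }
  if (n_cells < 0) stop("n_cells must be >= 0")
  n_cells <- as.integer(round(n_cells))
  if (any(radial_density_profile < 0))
    stop("radial_density_profile weights must be non-negative")
  s <- sum(radial_density_profile)
  if (s <= 0) stop("radial_density_profile must have positive total weight")
  radial_density_profile <- radial_density_profile / s
  tf_nuclear_mean <- tf_param(tf_nuclear_mean, "tf_nuclear_mean")
  tf_nc_ratio <- tf_param(tf_nc_ratio, "tf_nc_ratio")
  if (any(tf_nc_ratio < 0)) stop("tf_nc_ratio must be >= 0")
  tf_control_mean <- if (is.null(tf_control_mean)) tf_nuclear_mean
                     else tf_param(tf_control_mean, "tf_control_mean")
  structure(list(
    well_diameter = well_diameter, pixel_size = pixel_size, n_cells = n_cells,
    radial_density_profile = radial_density_profile, n_zones = n_zones,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    tf_nuclear_mean = tf_nuclear_mean, tf_nc_ratio = tf_nc_ratio,
    tf_control_mean = tf_control_mean,
    actin_class = actin_class, actin_base = actin_base,
    actin_peak_amplitude = actin_peak_amplitude, dapi_peak = dapi_peak,
    background_level = background_level, noise_sd = noise_sd,
    control_density = control_density, control_gap = control_gap,
    control_width = control_width,
    min_separation_frac = min_separation_frac, max_retries = max_retries,
    zone_margin_um = zone_margin_um, seed = as.integer(seed)
  ), class = "synthetic_well_spec")
}

# Normalise a scalar-or-named TF parameter to a named c(tf1=, tf2=) vector.
tf_param <- function(x, what) {
  if (length(x) == 1L && is.null(names(x))) x <- c(tf1 = unname(x), tf2 = unname(x))
  if (!all(c("tf1", "tf2") %in% names(x)))
    stop(sprintf("%s must be a scalar or a named vector with tf1 and tf2", what))
  x[c("tf1", "tf2")]
}

#' Specification of a synthetic unconfined monolayer field
#'
#' Emulates an unconfined pancreatic-endoderm monolayer at the PE stage:
#' uniformly scattered nuclei, a small sporadic fraction of PDX1-high cells,
#' and `n_clusters` roughly circular aggregates (default 150 µm across) whose
#' member cells carry `high_intensity_fold`-elevated nuclear TF intensity.
#'
#' @param field_size field edge length in µm (scalar, square field) or
#'   `c(width, height)`.
#' @param cell_density nuclei density, cells/mm².
#' @param sampling `"fixed"` (rounded expected count) or `"poisson"`.
#' @param high_fraction probability that a non-cluster cell is PDX1-high.
#' @param cluster_diameter,n_clusters diameter (µm) and number of high-cell
#'   aggregates.
#' @param high_intensity_fold nuclear TF intensity multiplier of high cells.
#' @param tf_nuclear_mean,tf_nc_ratio baseline nuclear TF intensity (a.u.) and
#'   N:C ratio of the rendered PDX1 channel.
#' @inheritParams synthetic_well_spec
#' @return a list of class `synthetic_monolayer_spec`.
#' @export
synthetic_monolayer_spec <- function(field_size = 600,
                                     cell_density = 5000,
                                     sampling = c("fixed", "poisson"),
                                     high_fraction = 0.02,
                                     cluster_diameter = 150,
                                     n_clusters = 1,
                                     high_intensity_fold = 3,
                                     tf_nuclear_mean = 100,
                                     tf_nc_ratio = 2,
                                     pixel_size = 0.65,
                                     nucleus_radius_mean = 5,
                                     nucleus_radius_sd = 0.5,
                                     dapi_peak = 150,
                                     actin_base = 40,
                                     background_level = 10,
                                     noise_sd = 2,
                                     min_separation_frac = 0.6,
                                     max_retries = 1000,
                                     seed = 1L) {
  sampling <- match.arg(sampling)
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  if (any(field_size <= 0)) stop("field_size must be > 0")
  if (high_fraction < 0 || high_fraction > 1)
    stop("high_fraction must be in [0, 1]")
  if (cluster_diameter <= 0) stop("cluster_diameter must be > 0")
  if (n_clusters > 0 && cluster_diameter > min(field_size))
    stop("clusters of the requested diameter do not fit in the field")
  structure(list(
    field_size = field_size, cell_density = cell_density, sampling = sampling,
    high_fraction = high_fraction, cluster_diameter = cluster_diameter,
    n_clusters = n_clusters, high_intensity_fold = high_intensity_fold,
    tf_nuclear_mean = unname(tf_nuclear_mean[1]),
    tf_nc_ratio = unname(tf_nc_ratio[1]),
    pixel_size = pixel_size, nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd, dapi_peak = dapi_peak,
    actin_base = actin_base, background_level = background_level,
    noise_sd = noise_sd, min_separation_frac = min_separation_frac,
    max_retries = max_retries, seed = as.integer(seed)
  ), class = "synthetic_monolayer_spec")
}

# --- placement helpers -------------------------------------------------------

# Sample nucleus radii from a +/- 2 sd truncated normal (PE nuclei have a
# tight size distribution; unphysical tails are not generated).
sample_radii <- function(n, mean, sd) {
  pmax(pmin(pmax(stats::rnorm(n, mean, sd), mean - 2 * sd), mean + 2 * sd), 1)
}

# Sequential random placement with pairwise separation rejection.
# propose() must return c(x, y); accepted centres collected in a matrix.
place_with_rejection <- function(n, radii, propose, min_sep_frac, max_retries,
                                 context) {
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      p <- propose(i)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        d2 <- (xs[j] - p[1])^2 + (ys[j] - p[2])^2
        ok <- all(d2 >= (min_sep_frac * (radii[j] + radii[i]))^2)
      }
      if (ok) { xs[i] <- p[1]; ys[i] <- p[2]; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(
        "packing failure: could not place nucleus %d of %d after %d retries (%s)",
        i, n, max_retries, context))
  }
  cbind(x = xs, y = ys)
}

# --- raster painting ---------------------------------------------------------

# Add truncated (3 sigma) isotropic Gaussian blobs to `mat`. Looping inside
# one call keeps the working matrix un-shared so updates happen in place.
paint_gaussians <- function(mat, cx_um, cy_um, amp, sigma_um, pixel_size) {
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in seq_along(cx_um)) {
    ext <- 3 * sigma_um[i]
    c0 <- max(floor((cx_um[i] - ext) / pixel_size), 0)
    c1 <- min(ceiling((cx_um[i] + ext) / pixel_size), nc - 1)
    r0 <- max(floor((cy_um[i] - ext) / pixel_size), 0)
    r1 <- min(ceiling((cy_um[i] + ext) / pixel_size), nr - 1)
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows * pixel_size - cy_um[i])^2,
                (cols * pixel_size - cx_um[i])^2, "+")
    blob <- amp * exp(-d2 / (2 * sigma_um[i]^2))
    blob[d2 > ext^2] <- 0
    mat[rows + 1, cols + 1] <- mat[rows + 1, cols + 1] + blob
  }
  mat
}

# Set `value[i]` on all pixels whose centre lies within `rad_um[i]` of centre i.
paint_discs <- function(mat, cx_um, cy_um, rad_um, value, pixel_size) {
  nr <- nrow(mat); nc <- ncol(mat)
  value <- rep_len(value, length(cx_um))
  for (i in seq_along(cx_um)) {
    c0 <- max(floor((cx_um[i] - rad_um[i]) / pixel_size), 0)
    c1 <- min(ceiling((cx_um[i] + rad_um[i]) / pixel_size), nc - 1)
    r0 <- max(floor((cy_um[i] - rad_um[i]) / pixel_size), 0)
    r1 <- min(ceiling((cy_um[i] + rad_um[i]) / pixel_size), nr - 1)
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows * pixel_size - cy_um[i])^2,
                (cols * pixel_size - cx_um[i])^2, "+")
    sel <- d2 <= rad_um[i]^2
    sub <- mat[rows + 1, cols + 1]
    sub[sel] <- value[i]
    mat[rows + 1, cols + 1] <- sub
  }
  mat
}

# --- microwell renderer ------------------------------------------------------

#' Render a synthetic microwell colony image with ground truth
#'
#' Produces a multi-channel raster (channels `dapi`, `actin`, `tf1`, `tf2`)
#' of one confined colony plus its unconfined control ring, and the exact
#' generator-side truth used by the recovery tests. Nuclei positions are drawn
#' zone-first from `radial_density_profile` (uniform within the zone annulus),
#' rendered as truncated Gaussian blobs in the DAPI channel; TF channels carry
#' `tf_nuclear_mean` over each nucleus disc and
#' `tf_nuclear_mean / tf_nc_ratio` over the colony cytoplasm; the actin
#' channel follows the requested architecture archetype. Additive background
#' and Gaussian noise complete the model.
#'
#' @param spec a [synthetic_well_spec()].
#' @param channels channels to render (subset of dapi/actin/tf1/tf2);
#'   rendering fewer channels is faster.
#' @param return_clean also return the noise-free signal stack.
#' @return list with elements `image` (a [multichannel_image]), `truth`
#'   (class `well_ground_truth`: per-nucleus table, per-zone counts, true N:C,
#'   actin class, well geometry, the spec) and, if requested, `clean`.
#' @export
render_microwell_image <- function(spec,
                                   channels = c("dapi", "actin", "tf1", "tf2"),
                                   return_clean = FALSE) {
  stopifnot(inherits(spec, "synthetic_well_spec"))
  channels <- match.arg(channels, several.ok = TRUE)
  set.seed(spec$seed)
  px <- spec$pixel_size
  R <- spec$well_diameter / 2
  ring_in <- R + spec$control_gap
  ring_out <- ring_in + spec$control_width
  half <- ring_out + 10
  n_px <- 2L * as.integer(ceiling(half / px)) + 1L
  cx <- cy <- ((n_px - 1L) / 2) * px
  if (n_px < spec$well_diameter / px)
    stop("canvas too small to contain the well")  # defensive; cannot trigger

  zones <- equal_area_zones(R, spec$n_zones)
  b <- c(0, zones$boundaries)
  m <- spec$zone_margin_um

  # nucleus placement is only needed when a nuclear channel is rendered;
  # actin-only renders skip it (the architecture field is cell-free)
  place <- any(c("dapi", "tf1", "tf2") %in% channels)

  # well nuclei: zone first, uniform-in-annulus within (with boundary margin)
  n <- if (place) spec$n_cells else 0L
  radii <- sample_radii(n, spec$nucleus_radius_mean, spec$nucleus_radius_sd)
  zone_of <- if (n > 0)
    sample.int(spec$n_zones, n, replace = TRUE, prob = spec$radial_density_profile)
  else integer(0)
  propose_well <- function(i) {
    k <- zone_of[i]
    lo <- if (k == 1L) 0 else b[k] + m
    hi <- b[k + 1L] - m
    if (lo >= hi) stop(sprintf("zone %d too narrow for zone_margin_um", k))
    r <- sqrt(stats::runif(1, lo^2, hi^2))
    th <- stats::runif(1, 0, 2 * pi)
    c(cx + r * cos(th), cy + r * sin(th))
  }
  pos <- if (n > 0)
    place_with_rejection(n, radii, propose_well, spec$min_separation_frac,
                         spec$max_retries,
                         sprintf("n_cells=%d, well_diameter=%g um",
                                 n, spec$well_diameter))
  else cbind(x = numeric(0), y = numeric(0))

  # control ring nuclei
  ring_area_mm2 <- pi * (ring_out^2 - ring_in^2) / 1e6
  n_ctrl_target <- round(spec$control_density * ring_area_mm2)
  n_ctrl <- if (place) n_ctrl_target else 0L
  radii_c <- sample_radii(n_ctrl, spec$nucleus_radius_mean, spec$nucleus_radius_sd)
  rmean <- spec$nucleus_radius_mean
  propose_ctrl <- function(i) {
    r <- sqrt(stats::runif(1, (ring_in + rmean)^2, (ring_out - rmean)^2))
    th <- stats::runif(1, 0, 2 * pi)
    c(cx + r * cos(th), cy + r * sin(th))
  }
  pos_c <- if (n_ctrl > 0)
    place_with_rejection(n_ctrl, radii_c, propose_ctrl, spec$min_separation_frac,
                         spec$max_retries, "control ring")
  else cbind(x = numeric(0), y = numeric(0))

  grids <- pixel_grids(n_px, n_px, px)
  D <- sqrt((grids$x - cx)^2 + (grids$y - cy)^2)
  zero <- matrix(0, n_px, n_px)
  clean <- list()

  all_x <- c(pos[, 1], pos_c[, 1]); all_y <- c(pos[, 2], pos_c[, 2])
  all_rad <- c(radii, radii_c)
  n_all <- length(all_x)

  if ("dapi" %in% channels) {
    clean$dapi <- paint_gaussians(zero, all_x, all_y, spec$dapi_peak,
                                  all_rad / 2, px)
  }
  if ("actin" %in% channels) {
    ch <- zero
    if (spec$n_cells > 0) {
      colony <- D <= R
      base <- spec$actin_base
      amp <- spec$actin_peak_amplitude
      arch <- switch(spec$actin_class,
        uniform    = base,
        peripheral = base + amp * exp(-(D - 0.95 * R)^2 / (2 * (0.08 * R)^2)),
        central    = base + amp * exp(-D^2 / (2 * (0.3 * R)^2)))
      if (length(arch) == 1L) arch <- matrix(arch, n_px, n_px)
      ch[colony] <- arch[colony]
    }
    if (n_ctrl_target > 0) ch[D >= ring_in & D <= ring_out] <- spec$actin_base
    clean$actin <- ch
  }
  for (tf in intersect(c("tf1", "tf2"), channels)) {
    ch <- zero
    nmean <- spec$tf_nuclear_mean[[tf]]
    ncr <- spec$tf_nc_ratio[[tf]]
    cyto <- if (ncr > 0) nmean / ncr else 0
    if (n > 0) ch[D <= R] <- cyto
    if (n_ctrl > 0) {
      cmean <- spec$tf_control_mean[[tf]]
      ch[D >= ring_in & D <= ring_out] <- if (ncr > 0) cmean / ncr else 0
      ch <- paint_discs(ch, pos_c[, 1], pos_c[, 2], radii_c, cmean, px)
    }
    ch <- paint_discs(ch, pos[, 1], pos[, 2], radii, nmean, px)
    clean[[tf]] <- ch
  }
  clean <- lapply(clean, function(ch) ch + spec$background_level)

  noisy <- lapply(clean, function(ch) {
    if (spec$noise_sd > 0) ch + matrix(stats::rnorm(length(ch), 0, spec$noise_sd),
                                       nrow(ch), ncol(ch))
    else ch
  })

  r_um <- sqrt((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2)
  nuclei <- data.frame(
    id = seq_len(n_all),
    region = rep(c("well", "control"), c(n, n_ctrl)),
    x_um = all_x, y_um = all_y,
    r_um = c(r_um, sqrt((pos_c[, 1] - cx)^2 + (pos_c[, 2] - cy)^2)),
    zone = c(zone_of, rep(NA_integer_, n_ctrl)),
    radius_um = all_rad,
    tf1_nuclear = c(rep(spec$tf_nuclear_mean[["tf1"]], n),
                    rep(spec$tf_control_mean[["tf1"]], n_ctrl)),
    tf2_nuclear = c(rep(spec$tf_nuclear_mean[["tf2"]], n),
                    rep(spec$tf_control_mean[["tf2"]], n_ctrl))
  )
  zone_counts <- tabulate(zone_of, nbins = spec$n_zones)
  truth <- structure(list(
    nuclei = nuclei, zone_counts = zone_counts,
    true_nc = spec$tf_nc_ratio, actin_class = spec$actin_class,
    well = list(cx = cx, cy = cy, R = R,
                control_inner = ring_in, control_outer = ring_out),
    spec = spec
  ), class = "well_ground_truth")

  out <- list(image = multichannel_image(noisy, px,
                meta = list(kind = "synthetic_well", seed = spec$seed)),
              truth = truth)
  if (return_clean)
    out$clean <- multichannel_image(clean, px, meta = list(kind = "clean"))
  out
}

#' Render a synthetic unconfined monolayer image with ground truth
#'
#' Nuclei are scattered uniformly over the field (count fixed or Poisson from
#' `cell_density`); all cells falling inside one of the `n_clusters` circular
#' aggregate regions, plus a sporadic `high_fraction` of the remainder, are
#' PDX1-high and carry `high_intensity_fold` elevated nuclear TF intensity.
#' Channels rendered: `dapi`, `actin`, `tf1`.
#'
#' @param spec a [synthetic_monolayer_spec()].
#' @param return_clean also return the noise-free stack.
#' @return list with `image` (a [multichannel_image]) and `truth` (class
#'   `monolayer_ground_truth`: per-cell table with high flags and cluster
#'   membership, cluster centres, the spec).
#' @export
render_monolayer_image <- function(spec, return_clean = FALSE) {
  stopifnot(inherits(spec, "synthetic_monolayer_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size
  W <- spec$field_size[1]; H <- spec$field_size[2]
  nc_px <- as.integer(ceiling(W / px)); nr_px <- as.integer(ceiling(H / px))

  rc <- spec$cluster_diameter / 2
  if (spec$n_clusters > 0 && (W < 2 * rc || H < 2 * rc))
    stop("clusters of the requested diameter do not fit in the field")
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(spec$n_clusters)) {
    placed <- FALSE
    for (try in seq_len(spec$max_retries)) {
      p <- c(stats::runif(1, rc, W - rc), stats::runif(1, rc, H - rc))
      ok <- nrow(centers) == 0 ||
        all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >=
              (2 * rc)^2)
      if (ok) { centers <- rbind(centers, p); placed <- TRUE; break }
    }
    if (!placed) stop("clusters of the requested diameter do not fit in the field")
  }

  area_mm2 <- W * H / 1e6
  n <- switch(spec$sampling,
              fixed = round(spec$cell_density * area_mm2),
              poisson = stats::rpois(1, spec$cell_density * area_mm2))
  radii <- sample_radii(n, spec$nucleus_radius_mean, spec$nucleus_radius_sd)
  rmean <- spec$nucleus_radius_mean
  propose <- function(i) c(stats::runif(1, rmean, W - rmean),
                           stats::runif(1, rmean, H - rmean))
  pos <- if (n > 0)
    place_with_rejection(n, radii, propose, spec$min_separation_frac,
                         spec$max_retries,
                         sprintf("monolayer density=%g cells/mm2",
                                 spec$cell_density))
  else cbind(x = numeric(0), y = numeric(0))

  cluster_id <- rep(NA_integer_, n)
  if (nrow(centers) > 0 && n > 0) {
    for (k in seq_len(nrow(centers))) {
      d2 <- (pos[, 1] - centers[k, 1])^2 + (pos[, 2] - centers[k, 2])^2
      cluster_id[is.na(cluster_id) & d2 <= rc^2] <- k
    }
  }
  high <- !is.na(cluster_id)
  sporadic <- !high & stats::runif(n) < spec$high_fraction
  high <- high | sporadic

  zero <- matrix(0, nr_px, nc_px)
  clean <- list(dapi = zero, actin = zero, tf1 = zero)
  clean$dapi <- paint_gaussians(clean$dapi, pos[, 1], pos[, 2],
                                spec$dapi_peak, radii / 2, px)
  if (n > 0) {
    clean$actin <- clean$actin + spec$actin_base
    cyto <- if (spec$tf_nc_ratio > 0) spec$tf_nuclear_mean / spec$tf_nc_ratio else 0
    clean$tf1 <- clean$tf1 + cyto
    amps <- spec$tf_nuclear_mean * ifelse(high, spec$high_intensity_fold, 1)
    clean$tf1 <- paint_discs(clean$tf1, pos[, 1], pos[, 2], radii, amps, px)
  }
  clean <- lapply(clean, function(ch) ch + spec$background_level)
  noisy <- lapply(clean, function(ch) {
    if (spec$noise_sd > 0) ch + matrix(stats::rnorm(length(ch), 0, spec$noise_sd),
                                       nrow(ch), ncol(ch))
    else ch
  })

  cells <- data.frame(
    id = seq_len(n),
    x_um = pos[, 1], y_um = pos[, 2], radius_um = radii,
    high = high, cluster = cluster_id,
    tf1_nuclear = spec$tf_nuclear_mean *
      ifelse(high, spec$high_intensity_fold, 1)
  )
  truth <- structure(list(
    cells = cells,
    cluster_centers = if (nrow(centers)) data.frame(cluster = seq_len(nrow(centers)),
                                                    x_um = centers[, 1],
                                                    y_um = centers[, 2])
                      else data.frame(cluster = integer(0), x_um = numeric(0),
                                      y_um = numeric(0)),
    spec = spec
  ), class = "monolayer_ground_truth")

  out <- list(image = multichannel_image(noisy, px,
                meta = list(kind = "synthetic_monolayer", seed = spec$seed)),
              truth = truth)
  if (return_clean)
    out$clean <- multichannel_image(clean, px, meta = list(kind = "clean"))
  out
}

#' Render the same colony under two imaging modalities
#'
#' Models the confocal-versus-epifluorescence consistency control: the second
#' image is `gain` times the first image's noise-free signal plus fresh
#' Gaussian noise, so per-cell intensity ratios between the two modalities are
#' constant up to noise. Truth is shared.
#'
#' @param spec a [synthetic_well_spec()].
#' @param gain multiplicative detector gain of modality 2 relative to 1 (> 0).
#' @param extra_noise_sd read-noise sd of modality 2 (a.u.).
#' @return list with `image1`, `image2` ([multichannel_image]) and `truth`.
#' @export
render_modality_pair <- function(spec, gain = 1, extra_noise_sd = 0) {
  if (gain <= 0) stop("gain must be > 0")
  base <- render_microwell_image(spec, return_clean = TRUE)
  ch2 <- lapply(base$clean$channels, function(ch) {
    out <- gain * ch
    if (extra_noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, extra_noise_sd),
                          nrow(out), ncol(out))
    out
  })
  list(image1 = base$image,
       image2 = multichannel_image(ch2, spec$pixel_size,
                                   meta = list(kind = "modality2", gain = gain)),
       truth = base$truth)
}

#' Write a rendered synthetic image bundle to disk
#'
#' Emits the multi-page TIFF, a per-nucleus ground-truth CSV and a YAML echo
#' of the generating spec, so a rendered dataset is self-describing.
#'
#' @param rendered result of [render_microwell_image()] or
#'   [render_monolayer_image()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(rendered, dir, prefix = "well") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tiff = file.path(dir, paste0(prefix, ".tif")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    spec = file.path(dir, paste0(prefix, "_spec.yaml"))
  )
  write_image_tiff(rendered$image, paths[["tiff"]])
  tab <- if (!is.null(rendered$truth$nuclei)) rendered$truth$nuclei
         else rendered$truth$cells
  utils::write.csv(tab, paths[["truth"]], row.names = FALSE)
  spec <- rendered$truth$spec
  yaml::write_yaml(lapply(unclass(spec), function(v)
    if (is.numeric(v)) as.numeric(v) else v), paths[["spec"]])
  invisible(paths)
}
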