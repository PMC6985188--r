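#' Well geometry
#'
#' @param cx,cy well centre in µm (image coordinate convention of
#'   [multichannel_image]).
#' @param R well radius in µm.
#' @return object of class `well_geometry`.
#' @export
well_geometry <- function(cx, cy, R) {
  if (R <= 0) stop("well radius must be > 0")
  structure(list(cx = cx, cy = cy, R = R), class = "well_geometry")
}

#' Equal-area concentric zones of a circular well
#'
#' Partitions a disc of radius `R` into `K` concentric annuli of identical
#' area; the closed-form boundaries are `r_k = R * sqrt(k / K)`.
#'
#' @param R well radius, µm.
#' @param K number of zones (default 4).
#' @return object of class `zone_spec`: list with `R`, `K`, `boundaries`
#'   (increasing radii `r_1..r_K`, with `r_K = R`) and `area_um2`, the common
#'   annulus area.
#' @export
equal_area_zones <- function(R, K = 4) {
  if (R <= 0) stop("R must be > 0")
  if (K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  boundaries <- R * sqrt(seq_len(K) / K)
  structure(list(R = R, K = K, boundaries = boundaries,
                 area_um2 = pi * R^2 / K),
            class = "zone_spec")
}

#' Assign nuclei to concentric zones
#'
#' Computes each nucleus's radial position (Euclidean centroid distance to the
#' well centre, the "centre of mass" convention) and its zone. Zone `k` covers
#' the half-open annulus `[r_{k-1}, r_k)` with `r_0 = 0`; a radial position of
#' exactly `R` belongs to the outermost zone. Nuclei beyond `R` are flagged
#' `outside` and excluded from zone summaries.
#'
#' @param rois a `nucleus_rois` object (or any data.frame with `x_um`,
#'   `y_um`).
#' @param well a [well_geometry()].
#' @param zones a [equal_area_zones()] built for `well$R`.
#' @return data.frame: the ROI table plus `r_um`, `zone` (NA when outside)
#'   and `outside`.
#' @export
assign_zones <- function(rois, well, zones) {
  stopifnot(inherits(well, "well_geometry"), inherits(zones, "zone_spec"))
  if (abs(zones$R - well$R) > 1e-9 * well$R)
    stop("zone spec was built for a different well radius")
  tab <- if (inherits(rois, "nucleus_rois")) rois$table else as.data.frame(rois)
  r <- sqrt((tab$x_um - well$cx)^2 + (tab$y_um - well$cy)^2)
  zone <- findInterval(r, c(0, zones$boundaries))   # K+1 => beyond r_K
  at_edge <- r <= well$R & zone == zones$K + 1L     # r == R exactly
  zone[at_edge] <- zones$K
  outside <- r > well$R
  zone[outside] <- NA_integer_
  cbind(tab, data.frame(r_um = r, zone = zone, outside = outside))
}

#' Per-zone nuclei counts and densities
#'
#' @param records output of [assign_zones()].
#' @param zones the [equal_area_zones()] used.
#' @return data.frame with one row per zone: `zone`, `count`, `area_um2`,
#'   `density_cells_mm2` (count / annulus area, in cells/mm²).
#' @export
zone_densities <- function(records, zones) {
  stopifnot(inherits(zones, "zone_spec"))
  counts <- tabulate(records$zone[!is.na(records$zone)], nbins = zones$K)
  data.frame(
    zone = seq_len(zones$K),
    count = counts,
    area_um2 = rep(zones$area_um2, zones$K),
    density_cells_mm2 = counts / zones$area_um2 * 1e6
  )
}

#' Mean nuclear intensity per ROI
#'
#' Mean of the channel over each nucleus region — the standard readout of
#' nuclear transcription-factor concentration, with the nuclear
#' cross-sectional area standing in for nuclear volume. The channel is
#' expected to be background-subtracted by the caller.
#'
#' @param channel numeric matrix.
#' @param rois a `nucleus_rois` object with at least one ROI.
#' @return numeric vector of per-ROI means, named by ROI id.
#' @export
nuclear_intensities <- function(channel, rois) {
  stopifnot(inherits(rois, "nucleus_rois"))
  if (nrow(rois$table) == 0) stop("no ROIs to measure")
  if (!identical(dim(channel), dim(rois$labels)))
    stop("channel and label raster dimensions differ")
  sel <- rois$labels > 0L
  ids <- rois$labels[sel]
  sums <- tapply_sum(channel[sel], ids)
  n <- tabulate(ids)
  out <- sums[rois$table$id] / n[rois$table$id]
  names(out) <- rois$table$id
  out
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Implements the N:C definition used for nuclear transcription-factor
#' localization: the cytoplasmic total is the channel total over the tissue
#' mask minus the total over all nuclear regions; the cytoplasmic mean divides
#' that by the corresponding pixel count; each nucleus's N:C is its nuclear
#' mean divided by the (shared) cytoplasmic mean, and the colony-level N:C
#' uses the mean of the nuclear means.
#'
#' When segmentation-derived ROIs are tighter than the true nucleus, pass a
#' dilated copy via `exclusion` so the ambiguous perinuclear ring counts
#' neither as nucleus nor as cytoplasm; nuclear means are still taken over
#' `rois`.
#'
#' @param channel numeric matrix (background-subtracted).
#' @param rois `nucleus_rois` measured as nuclei.
#' @param tissue a `tissue_mask` (or logical matrix) defining the tissue.
#' @param exclusion optional `nucleus_rois` whose union is removed from the
#'   cytoplasmic region instead of `rois` (defaults to `rois`).
#' @return list: `per_nucleus` (named vector of N:C), `colony` (scalar N:C),
#'   `nuclear_means`, `cyto_mean`, `n_undefined` (count of nuclei dropped
#'   because the cytoplasmic mean was non-positive — always 0 or all).
#' @export
nc_ratio <- function(channel, rois, tissue, exclusion = NULL) {
  mask <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue
  stopifnot(is.logical(mask), identical(dim(mask), dim(channel)))
  if (is.null(exclusion)) exclusion <- rois
  excl_px <- exclusion$labels > 0L
  clipped <- excl_px & !mask
  n_clipped <- sum(clipped)
  if (n_clipped > 0) {
    # edge nuclei routinely overhang the mask by a few pixels; only a large
    # clipped fraction indicates a mask/ROI mismatch worth surfacing
    if (n_clipped > 0.05 * sum(excl_px))
      warning(sprintf("%d nuclear pixels (>5%%) fall outside the tissue mask; clipped",
                      n_clipped))
    excl_px <- excl_px & mask
  }
  cyto_px <- mask & !excl_px
  n_cyto <- sum(cyto_px)
  if (n_cyto <= 0) stop("no cytoplasmic region: tissue mask does not exceed nuclear area")
  cyto_total <- sum(channel[mask]) - sum(channel[excl_px])
  cyto_mean <- cyto_total / n_cyto
  nuc_means <- nuclear_intensities(channel, rois)
  if (cyto_mean <= 0) {
    warning("cytoplasmic mean <= 0 after background subtraction; N:C undefined")
    return(list(per_nucleus = rep(NA_real_, length(nuc_means)),
                colony = NA_real_, nuclear_means = nuc_means,
                cyto_mean = cyto_mean, n_undefined = length(nuc_means)))
  }
  list(per_nucleus = nuc_means / cyto_mean,
       colony = mean(nuc_means) / cyto_mean,
       nuclear_means = nuc_means,
       cyto_mean = cyto_mean,
       n_undefined = 0L)
}

#' Normalize well nuclear intensities to the unconfined control
#'
#' Divides the mean nuclear intensity inside a microwell by the mean nuclear
#' intensity of cells in the surrounding unconfined monolayer, after an
#' optional shared background offset is removed from both; a value of 1 means
#' "equal to unconfined". The result is invariant under any positive
#' multiplicative gain applied to both sets.
#'
#' @param well_nuclear_means per-nucleus means inside the well.
#' @param control_nuclear_means per-nucleus means in the control region.
#' @param background scalar background already common to both (default 0,
#'   i.e. inputs are background-subtracted).
#' @return list: `normalized` (scalar well/control ratio of means),
#'   `per_cell` (each well nucleus normalized to the control mean),
#'   `control_mean`.
#' @export
normalize_to_control <- function(well_nuclear_means, control_nuclear_means,
                                 background = 0) {
  if (length(control_nuclear_means) == 0) stop("control region is empty")
  w <- well_nuclear_means - background
  ctrl <- mean(control_nuclear_means) - background
  if (ctrl <= 0) stop("control mean <= 0; cannot normalize")
  list(normalized = mean(w) / ctrl, per_cell = w / ctrl, control_mean = ctrl)
}

#' Discretized zone areas in pixels
#'
#' Counts raster pixels per zone for a given geometry — used to verify that
#' pixel-level zone areas track the analytic equal-area construction.
#'
#' @param dim_px raster dimension `c(nr, nc)`.
#' @param well a [well_geometry()] (µm).
#' @param zones a [equal_area_zones()].
#' @param pixel_size µm/px.
#' @return integer vector of per-zone pixel counts.
#' @export
zone_pixel_areas <- function(dim_px, well, zones, pixel_size) {
  g <- pixel_grids(dim_px[1], dim_px[2], pixel_size)
  r <- sqrt((g$x - well$cx)^2 + (g$y - well$cy)^2)
  zone <- findInterval(r, c(0, zones$boundaries))
  zone[r <= well$R & zone == zones$K + 1L] <- zones$K
  zone[r > well$R] <- 0L
  tabulate(zone[zone > 0], nbins = zones$K)
}
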