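#' Background subtraction
#'
#' Two estimators of the additive background of a fluorescence channel:
#' `rolling_ball` computes a morphological background (grayscale opening with
#' a disc structuring element of the given pixel radius, the flat-kernel
#' analogue of the classical rolling-ball filter) and subtracts it pixelwise;
#' `flat_percentile` subtracts a single scalar, the given percentile of the
#' image. Output is clamped at zero.
#'
#' @param channel numeric matrix (intensity, a.u.).
#' @param method `"rolling_ball"` or `"flat_percentile"`.
#' @param radius_or_pct ball radius in pixels (> 0), or percentile in (0, 100).
#' @return background-subtracted matrix, same dimensions, all values >= 0.
#' @export
subtract_background <- function(channel,
                                method = c("rolling_ball", "flat_percentile"),
                                radius_or_pct = 50) {
  method <- match.arg(method)
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  if (method == "flat_percentile") {
    if (radius_or_pct <= 0 || radius_or_pct >= 100)
      stop("percentile must be in (0, 100)")
    bg <- stats::quantile(channel, radius_or_pct / 100, names = FALSE)
    return(pmax(channel - bg, 0))
  }
  if (radius_or_pct <= 0) stop("ball radius must be > 0 px")
  size <- 2L * as.integer(ceiling(radius_or_pct)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  lo <- min(channel); hi <- max(channel)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1))
    return(matrix(0, nrow(channel), ncol(channel)))
  norm <- (channel - lo) / (hi - lo)
  bg <- EBImage::imageData(EBImage::opening(norm, brush)) * (hi - lo) + lo
  out <- channel - bg
  out[out < 0] <- 0
  out
}

# Otsu threshold on the raw intensity range; NA if the image is flat.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) return(NA_real_)
  EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
}

#' Segment nuclei from the nuclear counterstain
#'
#' Threshold (Otsu by default, or a manual cutoff) followed by
#' distance-transform watershed to split touching nuclei, with a minimum-area
#' filter. Alternatively an externally produced label raster (e.g. manually
#' curated regions) can be injected via `labels` and is then only measured,
#' not recomputed.
#'
#' @param dapi numeric matrix, nuclear counterstain (ideally
#'   background-subtracted).
#' @param pixel_size µm/px.
#' @param threshold_method `"otsu"` or `"manual"`.
#' @param threshold manual intensity cutoff (required for `"manual"`).
#' @param min_area minimum nucleus area in µm² (smaller regions are dropped).
#' @param split_touching apply the watershed split (otherwise plain connected
#'   components).
#' @param tolerance watershed minimum object-separation depth (px of the
#'   distance map).
#' @param mask_frac the component mask is taken at this fraction of the
#'   detection threshold, so each ROI extends from the bright core out to the
#'   dimmer nuclear rim without crossing into background (default 0.5).
#' @param labels optional integer label matrix overriding segmentation.
#' @return object of class `nucleus_rois`: list with `labels` (integer label
#'   matrix, 0 = background) and `table` (data.frame: `id`, `x_um`, `y_um`
#'   centroid at pixel-centre convention, `area_um2`, `n_px`). A blank image
#'   yields zero ROIs, not an error.
#' @export
segment_nuclei <- function(dapi, pixel_size,
                           threshold_method = c("otsu", "manual"),
                           threshold = NULL,
                           min_area = 20,
                           split_touching = TRUE,
                           tolerance = 0.5,
                           mask_frac = 0.5,
                           labels = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(dapi), pixel_size > 0)
  if (is.null(labels)) {
    th <- if (threshold_method == "manual") {
      if (is.null(threshold)) stop("manual threshold_method requires `threshold`")
      threshold
    } else otsu_threshold(dapi)
    if (is.na(th)) return(empty_rois(dim(dapi)))
    if (threshold_method == "otsu") th <- th * mask_frac
    mask <- dapi > th
    if (!any(mask)) return(empty_rois(dim(dapi)))
    labels <- if (split_touching) {
      dm <- EBImage::distmap(EBImage::Image(mask * 1))
      EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
    } else {
      EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    }
  }
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  measure_labels(labels, pixel_size, min_area)
}

empty_rois <- function(d) {
  structure(list(
    labels = matrix(0L, d[1], d[2]),
    table = data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                       area_um2 = numeric(0), n_px = integer(0))
  ), class = "nucleus_rois")
}

# Centroids/areas from a label matrix; relabels sequentially after the
# min-area filter.
measure_labels <- function(labels, pixel_size, min_area) {
  if (max(labels) == 0L) return(empty_rois(dim(labels)))
  keep_px <- labels > 0L
  ids <- labels[keep_px]
  idx <- which(keep_px)
  nr <- nrow(labels)
  rows0 <- (idx - 1L) %% nr          # 0-based row = y
  cols0 <- (idx - 1L) %/% nr         # 0-based col = x
  n_px <- tabulate(ids)
  sum_x <- tapply_sum(cols0, ids)
  sum_y <- tapply_sum(rows0, ids)
  present <- which(n_px > 0)
  area <- n_px[present] * pixel_size^2
  keep <- area >= min_area
  present <- present[keep]
  if (!length(present)) return(empty_rois(dim(labels)))
  relab <- integer(max(labels))
  relab[present] <- seq_along(present)
  new_labels <- matrix(0L, nrow(labels), ncol(labels))
  new_labels[keep_px] <- relab[labels[keep_px]]
  tab <- data.frame(
    id = seq_along(present),
    x_um = (sum_x[present] / n_px[present]) * pixel_size,
    y_um = (sum_y[present] / n_px[present]) * pixel_size,
    area_um2 = n_px[present] * pixel_size^2,
    n_px = n_px[present]
  )
  structure(list(labels = new_labels, table = tab), class = "nucleus_rois")
}

tapply_sum <- function(v, by) {
  out <- numeric(max(by))
  tmp <- rowsum(v, by)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

#' @export
print.nucleus_rois <- function(x, ...) {
  cat(sprintf("<nucleus_rois> %d ROIs over %d x %d px\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Segment the tissue (colony) region from the F-actin channel
#'
#' Thresholds the phalloidin stain (Otsu by default), applies a morphological
#' closing and fills holes, yielding the binary mask of the actin-covered
#' tissue used as the cytoplasmic reference region.
#'
#' @param actin numeric matrix (ideally background-subtracted).
#' @param pixel_size µm/px.
#' @param threshold_method `"otsu"` or `"manual"`.
#' @param threshold manual cutoff for `"manual"`.
#' @param closing_radius closing structuring-element radius in px (0 skips).
#' @param fill_holes fill enclosed holes in the mask.
#' @return object of class `tissue_mask`: list with `mask` (logical matrix)
#'   and `area_um2`. An all-flat channel yields an empty mask.
#' @export
segment_tissue <- function(actin, pixel_size,
                           threshold_method = c("otsu", "manual"),
                           threshold = NULL,
                           closing_radius = 5,
                           fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(actin), pixel_size > 0)
  th <- if (threshold_method == "manual") {
    if (is.null(threshold)) stop("manual threshold_method requires `threshold`")
    threshold
  } else otsu_threshold(actin)
  mask <- if (is.na(th)) matrix(FALSE, nrow(actin), ncol(actin)) else actin > th
  if (any(mask) && closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0.5
  }
  if (any(mask) && fill_holes) {
    mask <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  }
  structure(list(mask = mask, area_um2 = sum(mask) * pixel_size^2),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> area %.1f um2 (%d px)\n", x$area_um2, sum(x$mask)))
  invisible(x)
}

#' Dilate nucleus ROIs
#'
#' Grows every labelled nucleus region by `radius_px` (disc structuring
#' element) while keeping regions disjoint (ties resolved by distance via
#' Voronoi propagation). Used to build the perinuclear exclusion region for
#' cytoplasmic measurements.
#'
#' @param rois a `nucleus_rois` object.
#' @param radius_px dilation radius in pixels.
#' @param pixel_size µm/px, used to refresh the area column.
#' @return a new `nucleus_rois` with the same ids over grown regions.
#' @export
dilate_rois <- function(rois, radius_px, pixel_size) {
  stopifnot(inherits(rois, "nucleus_rois"))
  if (radius_px <= 0 || nrow(rois$table) == 0) return(rois)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "disc")
  grown_mask <- EBImage::imageData(
    EBImage::dilate(EBImage::Image((rois$labels > 0) * 1), brush)) > 0.5
  grown <- EBImage::imageData(EBImage::propagate(
    x = EBImage::Image(matrix(0, nrow(grown_mask), ncol(grown_mask))),
    seeds = EBImage::Image(rois$labels),
    mask = EBImage::Image(grown_mask * 1)))
  measure_labels(matrix(as.integer(grown), nrow(grown), ncol(grown)),
                 pixel_size, min_area = 0)
}
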