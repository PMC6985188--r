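#' Multi-channel fluorescence image container
#'
#' Bundles one 2D raster per channel with the physical pixel size so that all
#' downstream geometry can be expressed in micrometres. Channels are stored as
#' plain numeric matrices indexed `[row, col]`; the coordinate convention is a
#' 0-based pixel grid with the origin at the centre of the top-left pixel,
#' x increasing with column (rightward) and y with row (downward). A pixel at
#' 0-based indices `(i, j)` therefore sits at `(x, y) = (j, i) * pixel_size` µm.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#'   Canonical channel roles are `dapi` (nuclear counterstain), `actin`
#'   (F-actin / phalloidin), `tf1` (PDX1) and `tf2` (NKX6.1), but any names
#'   are accepted.
#' @param pixel_size pixel edge length in µm/px (scalar, > 0).
#' @param meta optional list of acquisition metadata carried through unchanged.
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size, meta = list()) {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must have the same dimensions")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/px)")
  structure(
    list(channels = channels, pixel_size = pixel_size, meta = meta),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<multichannel_image> %d x %d px (%.3g um/px), channels: %s\n",
    d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Extract one channel raster by role
#'
#' @param img a [multichannel_image].
#' @param role channel name, e.g. `"dapi"`.
#' @return numeric matrix.
#' @export
get_channel <- function(img, role) {
  stopifnot(inherits(img, "multichannel_image"))
  if (!role %in% names(img$channels))
    stop(sprintf("channel role '%s' not present (have: %s)",
                 role, paste(names(img$channels), collapse = ", ")))
  img$channels[[role]]
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' One 32-bit float page per channel, in the stored channel order. Channel
#' names and pixel size go into a small sidecar file (`<path>.meta.yaml`)
#' because baseline TIFF carries no standard channel-role metadata.
#'
#' @param img a [multichannel_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  lo <- min(vapply(img$channels, min, numeric(1)))
  hi <- max(vapply(img$channels, max, numeric(1)))
  scale <- max(hi - lo, .Machine$double.eps)
  pages <- lapply(unname(img$channels), function(m) (m - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(pixel_size_um = img$pixel_size,
                        channels = names(img$channels),
                        value_offset = lo, value_scale = scale),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' Channel names and pixel size are recovered from the sidecar
#' `<path>.meta.yaml` when present; otherwise they must be supplied.
#'
#' @param path TIFF file path.
#' @param channel_names optional character vector overriding stored names.
#' @param pixel_size optional µm/px overriding the stored value.
#' @return a [multichannel_image].
#' @export
read_image_tiff <- function(path, channel_names = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.yaml")
  offset <- 0; scale <- 1
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(channel_names)) channel_names <- meta$channels
    if (!is.null(meta$value_scale)) { offset <- meta$value_offset
                                      scale <- meta$value_scale }
  }
  if (is.null(pixel_size))
    stop("pixel_size not stored with the TIFF; supply it explicitly")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  chans <- lapply(pages, function(p) {
    m <- as.matrix(p)
    attributes(m) <- list(dim = dim(m))
    m * scale + offset
  })
  names(chans) <- channel_names[seq_along(chans)]
  multichannel_image(chans, pixel_size)
}

# Pixel-centre coordinate grids in um for an nr x nc raster (0-based centres).
pixel_grids <- function(nr, nc, pixel_size) {
  x <- matrix(rep((seq_len(nc) - 1) * pixel_size, each = nr), nr, nc)
  y <- matrix(rep((seq_len(nr) - 1) * pixel_size, times = nc), nr, nc)
  list(x = x, y = y)
}

# Bilinear interpolation of matrix m at fractional 0-based pixel coordinates
# (px = column, py = row). Points outside the grid are clamped to the border.
bilinear_sample <- function(m, px, py) {
  nr <- nrow(m); nc <- ncol(m)
  px <- pmin(pmax(px, 0), nc - 1)
  py <- pmin(pmax(py, 0), nr - 1)
  x0 <- pmin(floor(px), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(py), nr - 2); y1 <- y0 + 1
  if (nc == 1) { x0 <- x1 <- px * 0 }
  if (nr == 1) { y0 <- y1 <- py * 0 }
  fx <- px - x0; fy <- py - y0
  idx <- function(r, c) m[cbind(r + 1, c + 1)]
  idx(y0, x0) * (1 - fx) * (1 - fy) +
    idx(y0, x1) * fx * (1 - fy) +
    idx(y1, x0) * (1 - fx) * fy +
    idx(y1, x1) * fx * fy
}
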