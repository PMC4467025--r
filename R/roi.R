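#' Build a region-of-interest mask
#'
#' Analysis regions are represented as binary occupancy rasters.  Pixels are
#' half-open: pixel (i, j) covers x in \[x0+(j-1)p, x0+jp) and y in
#' \[y0+(i-1)p, y0+ip), so a point on a pixel's right/top edge belongs to
#' the next pixel.  The raster grid is indexed \[row = y, col = x\] with the
#' origin at the mask's lower-left corner.
#'
#' @param shape One of:
#'   * `list(type = "rectangle", bounds = c(xmin, xmax, ymin, ymax))`,
#'   * `list(type = "polygon", vertices = <n x 2 matrix of x, y in nm>)`,
#'   * a logical/0-1 matrix used directly as the raster
#'     (`list(type = "raster", grid = , origin = )` also accepted).
#' @param pixel_size Raster pixel edge in nm (> 0).
#' @param origin For raster input, the (x0, y0) of the grid's lower-left
#'   corner in nm; default `c(0, 0)`.
#' @return An `roi_mask`: list with `grid` (logical matrix), `pixel_size`,
#'   `origin`, `area` (nm^2, number of TRUE pixels times pixel area) and,
#'   for vector shapes, the original `shape` so the mask can be
#'   re-rasterized at other resolutions.
#' @examples
#' roi <- make_roi_mask(list(type = "rectangle",
#'                           bounds = c(0, 1e4, 0, 1e4)), pixel_size = 100)
#' roi$area / 1e6  # area in um^2
#' @export
make_roi_mask <- function(shape, pixel_size = 25) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (is.matrix(shape)) shape <- list(type = "raster", grid = shape)
  if (is.null(shape$type)) stop("shape must have a 'type' field or be a matrix")
  if (shape$type == "raster") {
    grid <- shape$grid
    storage.mode(grid) <- "logical"
    origin <- if (is.null(shape$origin)) c(0, 0) else as.numeric(shape$origin)
    if (!any(grid)) stop("raster mask has zero area")
    out <- list(grid = grid, pixel_size = pixel_size, origin = origin,
                area = sum(grid) * pixel_size^2, shape = NULL)
  } else {
    out <- .rasterize_shape(shape, pixel_size)
    out$shape <- shape
    if (out$area <= 0) stop("shape rasterizes to zero area")
  }
  class(out) <- "roi_mask"
  out
}

# rasterize a rectangle/polygon: pixel centers tested against the shape
.rasterize_shape <- function(shape, pixel_size) {
  if (shape$type == "rectangle") {
    b <- as.numeric(shape$bounds)
    if (length(b) != 4 || b[2] <= b[1] || b[4] <= b[3])
      stop("rectangle bounds must be c(xmin, xmax, ymin, ymax) with positive extent")
    vx <- c(b[1], b[2], b[2], b[1]); vy <- c(b[3], b[3], b[4], b[4])
  } else if (shape$type == "polygon") {
    v <- shape$vertices
    if (is.null(dim(v)) || nrow(v) < 3) stop("polygon needs >= 3 vertices")
    vx <- v[, 1]; vy <- v[, 2]
  } else stop("unknown shape type: ", shape$type)
  x0 <- floor(min(vx) / pixel_size) * pixel_size
  y0 <- floor(min(vy) / pixel_size) * pixel_size
  nc <- max(1L, ceiling((max(vx) - x0) / pixel_size))
  nr <- max(1L, ceiling((max(vy) - y0) / pixel_size))
  cx <- x0 + (seq_len(nc) - 0.5) * pixel_size
  cy <- y0 + (seq_len(nr) - 0.5) * pixel_size
  px <- rep(cx, each = nr); py <- rep(cy, times = nc)
  inside <- .point_in_polygon(px, py, vx, vy)
  grid <- matrix(inside, nrow = nr, ncol = nc)
  list(grid = grid, pixel_size = pixel_size, origin = c(x0, y0),
       area = sum(grid) * pixel_size^2)
}

# vectorized even-odd ray casting; boundary points resolved by the crossing
# rule (consistent, area-preserving for rasterization purposes)
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %dx%d raster @ %g nm/px, area %.4g nm^2 (%.4g um^2)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, x$area, x$area / 1e6))
  invisible(x)
}

#' Read an ROI definition from JSON
#'
#' Accepts `{"type": "rectangle", "bounds": [...], "pixel_size_nm": p}` or
#' `{"type": "polygon", "vertices": [[x, y], ...], "pixel_size_nm": p}`.
#'
#' @param path JSON file path.
#' @param pixel_size Override for the file's `pixel_size_nm` (optional).
#' @return An [make_roi_mask()] result.
#' @export
roi_from_json <- function(path, pixel_size = NULL) {
  js <- jsonlite::fromJSON(path)
  p <- if (!is.null(pixel_size)) pixel_size else js$pixel_size_nm
  if (is.null(p)) p <- 25
  shape <- if (identical(js$type, "rectangle")) {
    list(type = "rectangle", bounds = as.numeric(js$bounds))
  } else if (identical(js$type, "polygon")) {
    list(type = "polygon", vertices = matrix(as.numeric(js$vertices), ncol = 2))
  } else stop("unsupported ROI type in JSON: ", js$type)
  make_roi_mask(shape, pixel_size = p)
}

# logical index of table rows whose coordinates fall on a TRUE mask pixel
.in_roi <- function(table, roi) {
  p <- roi$pixel_size
  col <- floor((table$x - roi$origin[1]) / p) + 1L
  row <- floor((table$y - roi$origin[2]) / p) + 1L
  ok <- col >= 1L & col <= ncol(roi$grid) & row >= 1L & row <= nrow(roi$grid)
  ins <- logical(nrow(table))
  ins[ok] <- roi$grid[cbind(row[ok], col[ok])]
  ins
}

#' Subset a localization table to an ROI
#' @param table A [loc_table()].
#' @param roi An [make_roi_mask()] result.
#' @return A `loc_table` containing only in-ROI records.
#' @export
crop_to_roi <- function(table, roi) .loc_subset(table, .in_roi(table, roi))

#' Define uniform radial bins
#'
#' Bins are half-open, `[center - dr/2, center + dr/2)`, with the first
#' center at `dr/2` so that zero separations are representable.  The stored
#' ring areas `2*pi*r*dr` are the exact annulus areas for centered bins.
#'
#' @param dr Bin width in nm (default 25 nm, matching the reconstruction
#'   pixel size).
#' @param r_max Largest radius covered; rounded up to a whole number of bins.
#' @return A `radial_binning`: list with `centers`, `breaks`, `dr`,
#'   `ring_areas`.
#' @export
radial_binning <- function(dr = 25, r_max = 1000) {
  if (dr <= 0 || r_max <= 0) stop("dr and r_max must be > 0")
  nb <- ceiling(r_max / dr - 1e-9)
  breaks <- seq(0, by = dr, length.out = nb + 1L)
  centers <- breaks[-1L] - dr / 2
  structure(list(centers = centers, breaks = breaks, dr = dr,
                 ring_areas = 2 * pi * centers * dr),
            class = "radial_binning")
}

#' @export
print.radial_binning <- function(x, ...) {
  cat(sprintf("<radial_binning> %d bins of %g nm up to %g nm\n",
              length(x$centers), x$dr, max(x$breaks)))
  invisible(x)
}

# bin euclidean distances into a radial binning; distances >= max break drop
.bin_distances <- function(d, binning) {
  nb <- length(binning$centers)
  idx <- floor(d / binning$dr) + 1
  idx[idx > nb] <- NA
  tabulate(idx, nbins = nb)
}
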