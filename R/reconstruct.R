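#' Reconstruct per-channel count images from localizations
#'
#' Each localization increments the pixel it falls into (default 25 nm
#' pixels), per emission channel, over the ROI's bounding raster.
#' Localizations outside the raster or off the mask are dropped and
#' counted.
#'
#' @param table A [loc_table()].
#' @param pixel_size Reconstruction pixel in nm (default 25).
#' @param roi An [make_roi_mask()] result; its shape (or raster) is
#'   re-sampled onto the reconstruction grid.
#' @return A `recon_image`: list with count matrices `I1`, `I2`
#'   (\[row = y, col = x\]), logical `mask` on the same grid, `pixel_size`,
#'   `origin`, per-channel mean counts per mask pixel `rho` (`rho1`,
#'   `rho2`), in-mask totals `n`, and `dropped` counts.
#' @export
reconstruct_image <- function(table, pixel_size = 25, roi) {
  stopifnot(inherits(table, "loc_table"), inherits(roi, "roi_mask"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  mask <- .mask_on_grid(roi, pixel_size)
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  col <- floor((table$x - mask$origin[1]) / pixel_size) + 1L
  row <- floor((table$y - mask$origin[2]) / pixel_size) + 1L
  on_raster <- col >= 1L & col <= nc & row >= 1L & row <= nr
  on_mask <- logical(nrow(table))
  on_mask[on_raster] <- mask$grid[cbind(row[on_raster], col[on_raster])]
  imgs <- lapply(1:2, function(ch) {
    keep <- on_mask & table$channel == ch
    m <- matrix(0L, nr, nc)
    if (any(keep)) {
      idx <- (col[keep] - 1L) * nr + row[keep]
      cnt <- tabulate(idx, nbins = nr * nc)
      m[] <- cnt
    }
    m
  })
  npx <- sum(mask$grid)
  n <- c(sum(imgs[[1]]), sum(imgs[[2]]))
  structure(list(I1 = imgs[[1]], I2 = imgs[[2]], mask = mask$grid,
                 pixel_size = pixel_size, origin = mask$origin,
                 rho = n / npx, n = n,
                 dropped = nrow(table) - sum(on_mask)),
            class = "recon_image")
}

# resample an roi_mask onto a raster with the requested pixel size
.mask_on_grid <- function(roi, pixel_size) {
  if (!is.null(roi$shape))
    return(.rasterize_shape(roi$shape, pixel_size))
  if (isTRUE(all.equal(pixel_size, roi$pixel_size)))
    return(list(grid = roi$grid, origin = roi$origin))
  # nearest-neighbour resample of a raster mask at pixel centers
  nc <- max(1L, ceiling(ncol(roi$grid) * roi$pixel_size / pixel_size))
  nr <- max(1L, ceiling(nrow(roi$grid) * roi$pixel_size / pixel_size))
  cx <- roi$origin[1] + (seq_len(nc) - 0.5) * pixel_size
  cy <- roi$origin[2] + (seq_len(nr) - 0.5) * pixel_size
  scol <- pmin(pmax(floor((cx - roi$origin[1]) / roi$pixel_size) + 1L, 1L),
               ncol(roi$grid))
  srow <- pmin(pmax(floor((cy - roi$origin[2]) / roi$pixel_size) + 1L, 1L),
               nrow(roi$grid))
  list(grid = roi$grid[srow, scol, drop = FALSE], origin = roi$origin)
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf(
    "<recon_image> %dx%d px @ %g nm, counts ch1=%d ch2=%d, rho=(%.4g, %.4g)/px, %d dropped\n",
    nrow(x$I1), ncol(x$I1), x$pixel_size, x$n[1], x$n[2],
    x$rho[1], x$rho[2], x$dropped))
  invisible(x)
}

#' Export a reconstructed channel image as 16-bit TIFF
#'
#' @param img A [reconstruct_image()] result.
#' @param path Output file.
#' @param channel 1 or 2.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, channel = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  m <- if (channel == 1) img$I1 else img$I2
  m <- pmin(m, 65535L)
  # TIFF rows run top-down; our rasters are y-up
  tiff::writeTIFF(m[rev(seq_len(nrow(m))), , drop = FALSE] / 65535,
                  path, bits.per.sample = 16L)
  invisible(path)
}
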