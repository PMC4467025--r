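## Stage-drift correction and two-channel registration, applied to
## localization tables before correlation analysis.

# 2-D count histogram of points on a fixed raster
.count_grid <- function(x, y, origin, pixel, nr, nc) {
  col <- floor((x - origin[1]) / pixel) + 1L
  row <- floor((y - origin[2]) / pixel) + 1L
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  m <- matrix(0, nr, nc)
  if (any(ok)) {
    idx <- (col[ok] - 1L) * nr + row[ok]
    m[] <- tabulate(idx, nbins = nr * nc)
  }
  m
}

# sub-pixel peak refinement: separable fit through the three pixels around
# the integer peak.  Correlation peaks of localization rasters are close to
# Gaussian, so the fit is quadratic in log intensity (exact for a Gaussian);
# it falls back to a plain parabola when a neighbour is non-positive.
.subpixel_peak <- function(X, pk) {
  shift <- c(0, 0)
  for (ax in 1:2) {
    i <- pk[ax]
    n <- dim(X)[ax]
    im <- if (i == 1) n else i - 1   # the FFT displacement grid is circular
    ip <- if (i == n) 1L else i + 1
    y0 <- if (ax == 1) X[im, pk[2]] else X[pk[1], im]
    y1 <- X[pk[1], pk[2]]
    y2 <- if (ax == 1) X[ip, pk[2]] else X[pk[1], ip]
    if (y0 > 0 && y2 > 0 && y1 > 0) {
      l0 <- log(y0); l1 <- log(y1); l2 <- log(y2)
      den <- l0 - 2 * l1 + l2
      if (den < 0) shift[ax] <- 0.5 * (l0 - l2) / den
    } else {
      den <- y0 - 2 * y1 + y2
      if (den < 0) shift[ax] <- 0.5 * (y0 - y2) / den
    }
    if (!is.finite(shift[ax]) || abs(shift[ax]) > 1) shift[ax] <- 0
  }
  shift
}

#' Estimate stage drift from grouped localizations
#'
#' Splits the acquisition into consecutive groups of `group_size` frames
#' (default 500), reconstructs a 2-D count image per group, and finds the
#' displacement between successive groups as the maximum of their FFT
#' cross-correlation, refined to sub-pixel accuracy by a quadratic fit
#' around the peak.  Per-group offsets accumulate into a drift track
#' relative to the first group.
#'
#' @param table A [loc_table()] (all channels are pooled for drift).
#' @param group_size Frames per group (default 500).
#' @param pixel_size Raster pixel for the group reconstructions in nm
#'   (default 50).
#' @return A `drift_track`: data frame with columns `group`, `frame_start`,
#'   `dx`, `dy` (cumulative offsets in nm, first group at 0, 0), plus
#'   `group_size` attribute.
#' @export
estimate_drift <- function(table, group_size = 500, pixel_size = 50) {
  stopifnot(inherits(table, "loc_table"))
  if (!nrow(table)) stop("empty table")
  f0 <- min(table$frame)
  grp <- (table$frame - f0) %/% group_size
  ngrp <- max(grp) + 1L
  if (ngrp < 2) stop("need at least 2 frame groups with localizations")
  origin <- c(min(table$x), min(table$y))
  nc <- max(2L, ceiling((max(table$x) - origin[1]) / pixel_size) + 1L)
  nr <- max(2L, ceiling((max(table$y) - origin[2]) / pixel_size) + 1L)
  imgs <- lapply(0:(ngrp - 1L), function(g) {
    k <- grp == g
    .count_grid(table$x[k], table$y[k], origin, pixel_size, nr, nc)
  })
  dx <- dy <- numeric(ngrp)
  for (g in 2:ngrp) {
    if (sum(imgs[[g]]) == 0 || sum(imgs[[g - 1]]) == 0) {
      warning(sprintf("empty frame group %d: drift offset carried forward", g - 1))
      dx[g] <- dx[g - 1]; dy[g] <- dy[g - 1]
      next
    }
    xc <- .fft_xcorr(imgs[[g - 1]], imgs[[g]])
    pk <- which(xc$X == max(xc$X), arr.ind = TRUE)[1, ]
    sub <- .subpixel_peak(xc$X, pk)
    step_row <- (xc$drow[pk[1]] + sub[1]) * pixel_size
    step_col <- (xc$dcol[pk[2]] + sub[2]) * pixel_size
    # X(d) peaks at d = displacement of group g relative to group g-1
    dy[g] <- dy[g - 1] + step_row
    dx[g] <- dx[g - 1] + step_col
  }
  structure(data.frame(group = seq_len(ngrp) - 1L,
                       frame_start = f0 + (seq_len(ngrp) - 1L) * group_size,
                       dx = dx, dy = dy),
            group_size = group_size, frame0 = f0, pixel_size = pixel_size,
            class = c("drift_track", "data.frame"))
}

#' Apply a drift track to a localization table
#'
#' Subtracts each group's cumulative offset (block-constant within the
#' group), aligning all groups to the first.  Counts are unchanged.
#'
#' @param table A [loc_table()].
#' @param track An [estimate_drift()] result.
#' @return The corrected `loc_table`.
#' @export
apply_drift <- function(table, track) {
  stopifnot(inherits(table, "loc_table"), inherits(track, "drift_track"))
  gs <- attr(track, "group_size")
  f0 <- attr(track, "frame0")
  g <- pmin((table$frame - f0) %/% gs, nrow(track) - 1L) + 1L
  if (any(g < 1L)) stop("drift track does not cover the table's frame range")
  out <- table
  out$x <- table$x - track$dx[g]
  out$y <- table$y - track$dy[g]
  attr(out, "frame_interval") <- frame_interval(table)
  class(out) <- class(table)
  out
}

# bivariate monomial design matrix up to total degree d
.poly_design <- function(x, y, degree) {
  cols <- list()
  nm <- character()
  for (i in 0:degree) for (j in 0:(degree - i)) {
    cols[[length(cols) + 1]] <- x^i * y^j
    nm <- c(nm, sprintf("x%dy%d", i, j))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Fit a polynomial channel registration from bead control points
#'
#' Least-squares bivariate polynomial mapping near-channel bead
#' coordinates onto far-channel coordinates, as produced from fiducial
#' beads imaged in both emission channels.
#'
#' @param beads_near,beads_far Matrices/data frames of matched (x, y) bead
#'   coordinates in nm, one row per bead observation.
#' @param degree Total polynomial degree (default 2, standard for
#'   chromatic warps without overfitting a few tens of beads).
#' @return A `channel_transform`: list with `degree`, coefficient vectors
#'   `coef_x`, `coef_y`, and `rms_residual` (nm).
#' @export
fit_registration <- function(beads_near, beads_far, degree = 2) {
  near <- as.matrix(beads_near)[, 1:2, drop = FALSE]
  far <- as.matrix(beads_far)[, 1:2, drop = FALSE]
  if (nrow(near) != nrow(far)) stop("bead sets must pair up row by row")
  p <- (degree + 1) * (degree + 2) / 2
  if (nrow(near) < p)
    stop(sprintf("degree-%d transform needs >= %d bead pairs; have %d",
                 degree, p, nrow(near)))
  X <- .poly_design(near[, 1], near[, 2], degree)
  cx <- qr.coef(qr(X), far[, 1])
  cy <- qr.coef(qr(X), far[, 2])
  res <- cbind(far[, 1] - X %*% cx, far[, 2] - X %*% cy)
  structure(list(degree = degree, coef_x = cx, coef_y = cy,
                 rms_residual = sqrt(mean(res^2) * 2)),
            class = "channel_transform")
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf("<channel_transform> degree %d, rms residual %.3g nm\n",
              x$degree, x$rms_residual))
  invisible(x)
}

#' Apply a channel transform to one channel of a localization table
#'
#' @param table A [loc_table()].
#' @param transform A [fit_registration()] result.
#' @param channel The channel whose coordinates are mapped (the other
#'   channel is untouched).
#' @return The registered `loc_table`.
#' @export
apply_registration <- function(table, transform, channel) {
  stopifnot(inherits(table, "loc_table"),
            inherits(transform, "channel_transform"))
  k <- table$channel == channel
  out <- table
  if (any(k)) {
    X <- .poly_design(table$x[k], table$y[k], transform$degree)
    out$x[k] <- as.numeric(X %*% transform$coef_x)
    out$y[k] <- as.numeric(X %*% transform$coef_y)
  }
  attr(out, "frame_interval") <- frame_interval(table)
  class(out) <- class(table)
  out
}
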