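## Core estimator: edge-corrected pair cross-correlation C(r, tau).
##
## For a radial bin centered at r, C = M / (dA * rho0 * W) where M is the
## histogram of cross-channel pair distances, dA = 2*pi*r*dr the annulus
## area, rho0 = N / A_ROI the mean pair density (N the number of pair
## comparisons made), and W the radially averaged normalized
## autocorrelation of the ROI mask, which corrects for pairs lost across
## the ROI boundary.

# full 2-D cross-correlation X(d) = sum_x A(x) B(x+d) via zero-padded FFTs.
# Returns the wrapped correlation matrix plus the displacement value
# (in pixels) that each row/column index represents.
.fft_xcorr <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  nr2 <- 2L * nr; nc2 <- 2L * nc
  Ap <- matrix(0, nr2, nc2); Bp <- matrix(0, nr2, nc2)
  Ap[1:nr, 1:nc] <- A; Bp[1:nr, 1:nc] <- B
  X <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) /
    (nr2 * nc2)
  dr_ <- c(0:(nr2 / 2 - 1), -(nr2 / 2):-1)
  dc_ <- c(0:(nc2 / 2 - 1), -(nc2 / 2):-1)
  list(X = X, drow = dr_, dcol = dc_)
}

#' Edge factor W(r) of an ROI mask
#'
#' Computes the radially averaged, normalized autocorrelation of the ROI
#' mask by zero-padded FFT.  W(r) is the fraction of an annulus of radius r
#' around a uniformly placed point that falls inside the ROI, averaged over
#' points: it corrects pair counts for the finite, possibly irregular,
#' analysis region.  W(0) = 1 and W decays to 0 beyond the ROI diameter.
#'
#' @param roi An [make_roi_mask()] result.
#' @param binning A [radial_binning()].
#' @param pixel_size Raster pixel used for the mask autocorrelation;
#'   defaults to `min(binning$dr, 25)` nm.  Vector-shape ROIs are
#'   re-rasterized at this resolution.
#' @return An `edge_curve`: list with `r` (bin centers), `W`, `binning`,
#'   `pixel_size`.
#' @export
edge_factor <- function(roi, binning, pixel_size = NULL) {
  stopifnot(inherits(roi, "roi_mask"), inherits(binning, "radial_binning"))
  if (is.null(pixel_size)) pixel_size <- min(binning$dr, 25)
  mask <- .mask_on_grid(roi, pixel_size)
  M <- mask$grid * 1
  if (max(binning$breaks) > pixel_size * (min(dim(M)) + 1))
    stop("binning extends beyond the edge-factor support; ",
         "enlarge the ROI raster or reduce r_max")
  xc <- .fft_xcorr(M, M)
  omega <- xc$X                      # overlap pixel counts per displacement
  npx <- sum(M)
  d <- sqrt(outer(xc$drow^2, xc$dcol^2, "+")) * pixel_size
  nb <- length(binning$centers)
  idx <- floor(d / binning$dr) + 1
  idx[idx > nb] <- NA
  keep <- !is.na(idx)
  Wsum <- rep(0, nb); cnt <- rep(0, nb)
  t1 <- tapply(omega[keep], idx[keep], sum)
  t2 <- table(idx[keep])
  Wsum[as.integer(names(t1))] <- t1
  cnt[as.integer(names(t2))] <- t2
  if (any(cnt == 0))
    stop("binning finer than the edge-factor raster; reduce pixel_size")
  W <- pmax(Wsum / cnt / npx, 0)
  W[W < 1e-9] <- 0   # FFT roundoff: the true overlap is an integer count
  structure(list(r = binning$centers, W = W, binning = binning,
                 pixel_size = pixel_size), class = "edge_curve")
}

# chunked cross-distance histogram to bound memory at n1*n2 >> 1e6
.cross_hist <- function(x1, y1, x2, y2, binning) {
  n1 <- length(x1); n2 <- length(x2)
  nb <- length(binning$centers)
  if (n1 == 0L || n2 == 0L) return(rep(0L, nb))
  M <- rep(0L, nb)
  step <- max(1L, floor(4e6 / n2))
  for (s in seq(1L, n1, by = step)) {
    e <- min(n1, s + step - 1L)
    dx <- outer(x1[s:e], x2, "-")
    dy <- outer(y1[s:e], y2, "-")
    M <- M + .bin_distances(sqrt(dx * dx + dy * dy), binning)
  }
  M
}

#' Tabulate the time-lagged pair-distance histogram M(r)
#'
#' For each frame i in the steady-state window, distances between
#' channel-1 localizations in frame i and channel-2 localizations in frame
#' i + tau are binned; the number of pair comparisons is
#' N = sum_i n1_i * n2_(i+tau).  With `tau = "all"`, all cross-channel
#' pairs are tabulated irrespective of time and N = n1 * n2 (the
#' time-averaged mode, meaningful for immobile systems).
#'
#' @param table A [loc_table()].
#' @param roi An [make_roi_mask()]; only in-ROI localizations are used.
#' @param binning A [radial_binning()].
#' @param tau Integer lag in frames (>= 0), or `"all"` for the
#'   time-averaged mode.
#' @param window Inclusive frame range `c(first, last)` defining the
#'   steady-state window; default the table's full range.  Both members of
#'   a lagged pair must fall inside the window.
#' @param channels Length-2 vector of channel labels to correlate; the
#'   default `c(1, 2)` is the cross-correlation, `c(k, k)` gives the
#'   same-channel displacement histogram used by [auto_correlation()].
#' @return A `pair_histogram`: list with `M` (counts per bin), `N`, `F`
#'   (frame pairs used), `rho0 = N / area`, `area`, `binning`, `tau`,
#'   `window`, `n_ch` (in-window totals of the two correlated channels).
#' @export
pair_histogram <- function(table, roi, binning, tau = 0, window = NULL,
                           channels = c(1, 2)) {
  stopifnot(inherits(table, "loc_table"))
  tab <- crop_to_roi(table, roi)
  if (is.null(window)) {
    if (!nrow(tab)) stop("no localizations inside the ROI")
    window <- range(tab$frame)
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be c(first_frame, last_frame)")
  tab <- .loc_subset(tab, tab$frame >= window[1] & tab$frame <= window[2])
  if (!nrow(tab)) stop("empty steady-state window")
  a <- tab[tab$channel == channels[1], , drop = FALSE]
  b <- tab[tab$channel == channels[2], , drop = FALSE]
  n_ch <- c(nrow(a), nrow(b))
  nb <- length(binning$centers)
  if (identical(tau, "all")) {
    M <- .cross_hist(a$x, a$y, b$x, b$y, binning)
    N <- as.numeric(n_ch[1]) * n_ch[2]
    Fn <- window[2] - window[1] + 1L
  } else {
    tau <- as.integer(tau)
    if (tau < 0) stop("tau must be >= 0 (frames)")
    same <- channels[1] == channels[2]
    if (same && tau == 0L)
      warning("same-channel lag 0 measures probe density, not displacement; ",
              "flagged non-interpretable")
    frames <- window[1]:window[2]
    sa <- split(seq_len(nrow(a)), factor(a$frame, levels = frames))
    sb <- if (same) sa else split(seq_len(nrow(b)), factor(b$frame, levels = frames))
    M <- rep(0L, nb); N <- 0; Fn <- 0L
    nf <- length(frames)
    for (k in seq_len(nf - tau)) {
      ia <- sa[[k]]; ib <- sb[[k + tau]]
      if (!length(ia) || !length(ib)) { Fn <- Fn + 1L; next }
      M <- M + .cross_hist(a$x[ia], a$y[ia],
                           if (same) a$x[ib] else b$x[ib],
                           if (same) a$y[ib] else b$y[ib], binning)
      N <- N + as.numeric(length(ia)) * length(ib)
      Fn <- Fn + 1L
    }
  }
  if (N == 0)
    warning("no pair comparisons in window (a channel is empty); N = 0")
  structure(list(M = M, N = N, F = Fn, rho0 = N / roi$area, area = roi$area,
                 binning = binning, tau = tau, window = window, n_ch = n_ch,
                 channels = channels,
                 frame_interval = frame_interval(table)),
            class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf(
    "<pair_histogram> tau=%s, %d bins, sum(M)=%d of N=%.6g pairs, %d frame pairs\n",
    format(x$tau), length(x$M), sum(x$M), x$N, x$F))
  invisible(x)
}

#' Normalize a pair histogram into a correlation curve
#'
#' C(r) = M(r) / mu(r) with mu(r) = dA(r) * rho0 * W(r): the relative
#' probability of finding a cross-channel pair at separation r compared
#' with uniformly distributed particles.  Bins where the edge factor
#' vanishes are marked undefined (`NA`) rather than propagated.
#'
#' @param hist A [pair_histogram()].
#' @param edge An [edge_factor()] on the same binning.
#' @param sparse Logical or `NULL`; see [correlation_variance()].
#' @return A `corr_curve`: list with per-bin `r`, `C`, `var_C`, `sd_C`,
#'   `M`, `W`, `mu`, plus scalars `N`, `F`, `tau`, `tau_s`, and provenance.
#' @export
correlation_from_histogram <- function(hist, edge, sparse = NULL) {
  stopifnot(inherits(hist, "pair_histogram"), inherits(edge, "edge_curve"))
  if (!isTRUE(all.equal(hist$binning$centers, edge$binning$centers)))
    stop("histogram and edge factor use different binnings")
  if (hist$N == 0) stop("no pairs: N = 0 in this window")
  mu <- hist$binning$ring_areas * hist$rho0 * edge$W
  C <- ifelse(mu > 0, hist$M / mu, NA_real_)
  tau_s <- if (identical(hist$tau, "all")) NA_real_ else
    hist$tau * hist$frame_interval
  curve <- structure(list(r = hist$binning$centers, C = C, var_C = NULL,
                          sd_C = NULL, M = hist$M, W = edge$W, mu = mu,
                          N = hist$N, F = hist$F, tau = hist$tau,
                          tau_s = tau_s, binning = hist$binning,
                          n_ch = hist$n_ch, area = hist$area,
                          window = hist$window, method = "pairwise"),
                     class = "corr_curve")
  correlation_variance(hist, curve, sparse = sparse)
}

#' Attach analytic Poisson-counting variance to a correlation curve
#'
#' M and N are independent counting variables, so error propagation gives
#' `sigma_C^2 = C^2 (sigma_M^2 / M^2 + sigma_N^2 / N^2)` with
#' `sigma_M^2 = M` and `sigma_N^2 = N`, i.e. `C^2 (1/M + 1/N)`.  In sparse
#' mode `sigma_M^2 = M + 1`, which keeps the error estimate finite for
#' empty bins; it is enabled automatically when `sum(M) < 100`.
#'
#' @param hist The [pair_histogram()] behind the curve.
#' @param curve The corresponding `corr_curve` (made by
#'   [correlation_from_histogram()], which calls this itself).
#' @param sparse `TRUE`, `FALSE`, or `NULL` (auto).
#' @return The curve with `var_C` and `sd_C` filled.
#' @export
correlation_variance <- function(hist, curve, sparse = NULL) {
  if (is.null(sparse)) sparse <- sum(hist$M) < 100
  s2M <- if (sparse) hist$M + 1 else hist$M
  # var formulated via mu to stay finite at M = 0: C^2/M^2 * s2M = s2M/mu^2
  var_C <- ifelse(curve$mu > 0,
                  s2M / curve$mu^2 + curve$C^2 / hist$N, NA_real_)
  curve$var_C <- var_C
  curve$sd_C <- sqrt(var_C)
  curve$sparse <- sparse
  curve
}

#' Relative error sigma_C / C per bin
#' @param curve A `corr_curve` with variance attached.
#' @return Numeric vector `sqrt(1/M + 1/N)` (adjusted in sparse mode).
#' @export
relative_error <- function(curve) {
  s2M <- if (isTRUE(curve$sparse)) curve$M + 1 else curve$M
  sqrt(s2M / pmax(curve$M, 1e-300)^2 + 1 / curve$N)
}

#' One-call steady-state cross-correlation
#'
#' Convenience pipeline: [pair_histogram()] + [edge_factor()] +
#' [correlation_from_histogram()].
#'
#' @inheritParams pair_histogram
#' @inheritParams correlation_from_histogram
#' @param edge Optional precomputed [edge_factor()] (reused across windows).
#' @return A `corr_curve`.
#' @examples
#' set.seed(1)
#' roi <- make_roi_mask(list(type = "rectangle", bounds = c(0, 2000, 0, 2000)),
#'                      pixel_size = 25)
#' tab <- loc_table(runif(400, 0, 2000), runif(400, 0, 2000),
#'                  frame = rep(0:3, each = 100), channel = rep(1:2, 200))
#' cross_correlation(tab, roi, radial_binning(50, 500), tau = 0)
#' @export
cross_correlation <- function(table, roi, binning, tau = 0, window = NULL,
                              sparse = NULL, edge = NULL, channels = c(1, 2)) {
  if (is.null(edge)) edge <- edge_factor(roi, binning)
  hist <- pair_histogram(table, roi, binning, tau = tau, window = window,
                         channels = channels)
  correlation_from_histogram(hist, edge, sparse = sparse)
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("<corr_curve> %s, tau=%s, N=%.6g pairs over %d frame pairs\n",
              x$method, format(x$tau), x$N, x$F))
  print(utils::head(as.data.frame(x), 8), digits = 4)
  if (length(x$r) > 8) cat("...", length(x$r), "bins total\n")
  invisible(x)
}

#' @export
as.data.frame.corr_curve <- function(x, ...) {
  data.frame(r_nm = x$r, C = x$C, sigma_C = x$sd_C, M = x$M, N = x$N,
             W = x$W, mu = x$mu)
}

#' @export
plot.corr_curve <- function(x, ..., ylab = "C(r)", xlab = "r (nm)") {
  ok <- !is.na(x$C)
  graphics::plot(x$r[ok], x$C[ok], type = "b", pch = 16, xlab = xlab,
                 ylab = ylab, ...)
  if (!is.null(x$sd_C))
    graphics::arrows(x$r[ok], x$C[ok] - x$sd_C[ok], x$r[ok],
                     x$C[ok] + x$sd_C[ok], angle = 90, code = 3,
                     length = 0.02, col = "grey40")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Validate the analytic variance by scrambled-frame resampling
#'
#' Randomly permutes the time ordering of frames (removing bleaching or
#' other temporal correlations), splits the scrambled acquisition into
#' consecutive windows of equal frame count, tabulates C(r, tau = 0) in
#' each, and returns the empirical per-bin spread next to the analytic
#' prediction.
#'
#' @inheritParams pair_histogram
#' @param n_windows Number of resampled steady-state windows.
#' @param window_frames Frames per window (F).
#' @param seed Optional RNG seed for the permutation.
#' @return A `resample_set`: list with `curves`, per-bin `emp_mean`,
#'   `emp_sd`, `pred_sd` (root-mean analytic variance), `ratio`
#'   (`emp_sd / pred_sd`), and the binning.
#' @export
scrambled_resample <- function(table, roi, binning, n_windows, window_frames,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- crop_to_roi(table, roi)
  if (!nrow(tab)) stop("no localizations inside the ROI")
  frames <- seq(min(tab$frame), max(tab$frame))
  need <- n_windows * window_frames
  if (length(frames) < need)
    stop(sprintf("need %d frames for %d windows of %d; have %d",
                 need, n_windows, window_frames, length(frames)))
  perm <- sample(frames)
  newf <- match(tab$frame, perm) - 1L  # scrambled 0-based frame index
  tab$frame <- newf
  edge <- edge_factor(roi, binning)
  curves <- lapply(seq_len(n_windows) - 1L, function(w) {
    cross_correlation(tab, roi, binning, tau = 0,
                      window = c(w * window_frames, (w + 1L) * window_frames - 1L),
                      sparse = FALSE, edge = edge)
  })
  Cmat <- do.call(rbind, lapply(curves, `[[`, "C"))
  Vmat <- do.call(rbind, lapply(curves, `[[`, "var_C"))
  emp_sd <- if (n_windows > 1) apply(Cmat, 2, stats::sd) else
    rep(NA_real_, ncol(Cmat))
  if (n_windows == 1)
    warning("single window: empirical sd undefined")
  pred_sd <- sqrt(colMeans(Vmat))
  structure(list(curves = curves, emp_mean = colMeans(Cmat), emp_sd = emp_sd,
                 pred_sd = pred_sd, ratio = emp_sd / pred_sd,
                 r = binning$centers, binning = binning),
            class = "resample_set")
}

#' @export
print.resample_set <- function(x, ...) {
  cat(sprintf("<resample_set> %d windows; emp/pred sd ratio %.3g-%.3g\n",
              length(x$curves), min(x$ratio, na.rm = TRUE),
              max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Time-averaged cross-correlation by the FFT image method
#'
#' Computes C(r, <tau>) from reconstructed count images I1, I2 as the
#' radially averaged, density-normalized image cross-correlation
#' `Re{IFFT(FFT(I1) conj(FFT(I2)))}` divided by the mask autocorrelation
#' (which supplies both the area normalization and the edge factor).  The
#' result is equivalent to the pairwise `tau = "all"` mode up to pixel
#' discretization; the near-zero bins of a self-correlation (I1 = I2)
#' carry a density artifact and are excluded from interpretation.
#'
#' @param img A [reconstruct_image()] result.
#' @param binning A [radial_binning()]; bin width should be at least the
#'   image pixel size.
#' @return A `corr_curve` (method `"image"`), with M taken as the pair
#'   count recovered from the image product (integer up to FFT roundoff).
#' @export
correlation_image_method <- function(img, binning) {
  stopifnot(inherits(img, "recon_image"))
  if (img$n[1] == 0 || img$n[2] == 0) stop("empty channel image")
  p <- img$pixel_size
  I1 <- img$I1 * img$mask; I2 <- img$I2 * img$mask
  xc <- .fft_xcorr(I1, I2)
  om <- .fft_xcorr(img$mask * 1, img$mask * 1)
  d <- sqrt(outer(xc$drow^2, xc$dcol^2, "+")) * p
  nb <- length(binning$centers)
  idx <- floor(d / binning$dr) + 1
  idx[idx > nb] <- NA
  keep <- !is.na(idx) & om$X > 0.5
  f <- factor(idx[keep], levels = seq_len(nb))
  Xs <- as.numeric(tapply(xc$X[keep], f, sum, default = 0))
  Os <- as.numeric(tapply(om$X[keep], f, sum, default = 0))
  npx <- sum(img$mask)
  N <- as.numeric(img$n[1]) * img$n[2]
  mu <- N * Os / npx^2
  C <- ifelse(mu > 0, Xs / mu, NA_real_)
  M <- round(pmax(Xs, 0))
  var_C <- ifelse(mu > 0, M / mu^2 + C^2 / N, NA_real_)
  structure(list(r = binning$centers, C = C, var_C = var_C,
                 sd_C = sqrt(var_C), M = M,
                 W = Os * p^2 / (npx * binning$ring_areas), mu = mu, N = N,
                 F = NA_integer_, tau = "all", tau_s = NA_real_,
                 binning = binning, n_ch = img$n, area = npx * p^2,
                 window = NULL, method = "image", sparse = FALSE),
            class = "corr_curve")
}

#' Inverse-variance weighted average of correlation curves over tau
#'
#' Averages curves sharing a binning, typically C(r, tau) over
#' 0 < tau <= tau_max, to gain statistical significance when C(r, tau)
#' varies slowly with tau (e.g. clusters immobile over the averaged lags).
#' The attached uncertainty is the s.e. of the weighted average,
#' `1 / sqrt(sum(1 / sigma^2))`.
#'
#' @param curves List of `corr_curve`s on a common binning.
#' @return A `corr_curve` with `tau = "avg"`; bins undefined in every input
#'   stay undefined.
#' @export
average_over_tau <- function(curves) {
  if (!length(curves)) stop("no curves to average")
  r <- curves[[1]]$r
  for (cv in curves)
    if (!isTRUE(all.equal(cv$r, r))) stop("curves use different binnings")
  Cmat <- do.call(rbind, lapply(curves, `[[`, "C"))
  Vmat <- do.call(rbind, lapply(curves, `[[`, "var_C"))
  wmat <- 1 / Vmat
  wmat[!is.finite(wmat) | is.na(Cmat)] <- 0
  wsum <- colSums(wmat)
  C <- ifelse(wsum > 0, colSums(wmat * ifelse(is.na(Cmat), 0, Cmat)) / wsum,
              NA_real_)
  var_C <- ifelse(wsum > 0, 1 / wsum, NA_real_)
  tmpl <- curves[[1]]
  structure(list(r = r, C = C, var_C = var_C, sd_C = sqrt(var_C),
                 M = Reduce(`+`, lapply(curves, `[[`, "M")),
                 W = tmpl$W, mu = NA, N = sum(vapply(curves, `[[`, 0, "N")),
                 F = sum(vapply(curves, function(z) as.integer(z$F), 0L)),
                 tau = "avg",
                 tau_s = range(vapply(curves, `[[`, 0, "tau_s")),
                 binning = tmpl$binning, n_ch = tmpl$n_ch, area = tmpl$area,
                 window = tmpl$window, method = tmpl$method, sparse = FALSE),
            class = "corr_curve")
}

#' Extrapolate C(r, tau) to tau = 0, excluding bleed-through lags
#'
#' Spectral bleed-through creates spurious simultaneous pairs and inflates
#' C(r, tau = 0) only; when dynamics are slow compared with the lags used,
#' the bleed-free simultaneous correlation can be recovered by fitting
#' C versus tau per bin over lags not affected and evaluating at tau = 0.
#'
#' @param curves List of `corr_curve`s at integer lags (in frames).
#' @param exclude Integer lags to exclude from the fit (default 0).
#' @param mode `"constant"` (weighted mean) or `"linear"` (weighted
#'   least-squares line in tau, intercept reported).
#' @return A `corr_curve` at `tau = 0` with fit s.e. as `sd_C`.
#' @export
extrapolate_tau_zero <- function(curves, exclude = 0L,
                                 mode = c("constant", "linear")) {
  mode <- match.arg(mode)
  taus <- vapply(curves, function(z) as.numeric(z$tau), 0)
  use <- !(taus %in% exclude)
  if (sum(use) < 3)
    stop("need at least 3 non-excluded lags for the extrapolation")
  curves <- curves[use]; taus <- taus[use]
  r <- curves[[1]]$r
  Cmat <- do.call(rbind, lapply(curves, `[[`, "C"))
  Vmat <- do.call(rbind, lapply(curves, `[[`, "var_C"))
  nb <- length(r)
  C0 <- rep(NA_real_, nb); V0 <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    y <- Cmat[, b]; v <- Vmat[, b]
    ok <- is.finite(y) & is.finite(v) & v > 0
    if (sum(ok) < 3) next
    if (mode == "constant") {
      w <- 1 / v[ok]
      C0[b] <- sum(w * y[ok]) / sum(w)
      V0[b] <- 1 / sum(w)
    } else {
      fit <- stats::lm(y[ok] ~ taus[ok], weights = 1 / v[ok])
      C0[b] <- unname(stats::coef(fit)[1])
      V0[b] <- suppressWarnings(stats::vcov(fit)[1, 1])
    }
  }
  tmpl <- curves[[1]]
  structure(list(r = r, C = C0, var_C = V0, sd_C = sqrt(V0),
                 M = NA, W = tmpl$W, mu = NA, N = tmpl$N, F = tmpl$F,
                 tau = 0L, tau_s = 0, binning = tmpl$binning,
                 n_ch = tmpl$n_ch, area = tmpl$area, window = tmpl$window,
                 method = paste0("extrapolated-", mode), sparse = FALSE),
            class = "corr_curve")
}

#' Potential of mean force from a correlation curve
#'
#' Under equilibrium, the effective interaction between the labelled
#' components is `PMF(r) = -kT ln C(r)`, reported here in kT units.
#' Variance propagates as `var_pmf = var_C / C^2`.  Bins with C <= 0 or
#' undefined C are flagged `NA`, never +/-Inf.
#'
#' @param curve A `corr_curve`.
#' @return A `pmf_curve`: list with `r`, `pmf`, `var_pmf`, `sd_pmf`.
#' @examples
#' # C = 1 is non-interacting: PMF = 0; C = e gives PMF = -1 kT
#' @export
pmf_from_correlation <- function(curve) {
  ok <- is.finite(curve$C) & curve$C > 0
  pmf <- ifelse(ok, -log(curve$C), NA_real_)
  var_pmf <- ifelse(ok, curve$var_C / curve$C^2, NA_real_)
  structure(list(r = curve$r, pmf = pmf, var_pmf = var_pmf,
                 sd_pmf = sqrt(var_pmf), tau = curve$tau,
                 binning = curve$binning), class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  i <- which.min(x$pmf)
  cat(sprintf("<pmf_curve> %d bins; min %.3g kT at r = %g nm\n",
              length(x$r), x$pmf[i], x$r[i]))
  invisible(x)
}

#' @export
plot.pmf_curve <- function(x, ..., ylab = "PMF (kT)", xlab = "r (nm)") {
  ok <- !is.na(x$pmf)
  graphics::plot(x$r[ok], x$pmf[ok], type = "b", pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Convert a correlation curve to partner density and excess counts
#'
#' `rho(r) = C(r) * mean_density` is the density of one labelled species
#' at distance r from the average molecule of the other; integrating the
#' excess `(C - 1) * mean_density` over area gives the expected number of
#' excess partners within r.
#'
#' @param curve A `corr_curve`.
#' @param mean_density Mean density of the partner species in molecules
#'   per nm^2.
#' @return A `density_curve`: list with `r`, `rho` (nm^-2),
#'   `cumulative_excess` (counts within r), `mean_density`.
#' @export
density_from_correlation <- function(curve, mean_density) {
  if (!is.numeric(mean_density) || mean_density <= 0)
    stop("mean_density must be > 0")
  rho <- curve$C * mean_density
  exc <- (curve$C - 1) * mean_density * curve$binning$ring_areas
  structure(list(r = curve$r, rho = rho,
                 cumulative_excess = cumsum(ifelse(is.na(exc), 0, exc)),
                 mean_density = mean_density, binning = curve$binning),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "<density_curve> mean density %.4g nm^-2; excess partners within %g nm: %.3g\n",
    x$mean_density, max(x$binning$breaks), utils::tail(x$cumulative_excess, 1)))
  invisible(x)
}
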