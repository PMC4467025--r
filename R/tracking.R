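## Single-particle trajectory linking and MSD analysis.

#' Link localizations into single-particle trajectories
#'
#' Frame-to-frame linking with ambiguity termination: a link between a
#' localization in frame i and one in frame i + 1 is made only when each is
#' the other's unique candidate within `radius`; any localization with two
#' or more candidates in either direction stays unlinked, terminating the
#' trajectory at that frame.  The rule is global per frame pair, so the
#' result does not depend on input row order.
#'
#' @param table A [loc_table()].
#' @param channel Channel to track (1 or 2).
#' @param radius Search radius in nm (default 500).
#' @return A `trajectory_set`: data frame with columns `traj_id`, `frame`,
#'   `x`, `y`, ordered by trajectory then frame; consecutive rows of one
#'   trajectory differ by exactly one frame.  Carries the table's
#'   `frame_interval` and `radius` as attributes.
#' @export
link_trajectories <- function(table, channel, radius = 500) {
  stopifnot(inherits(table, "loc_table"))
  if (radius <= 0) stop("radius must be > 0")
  pts <- table[table$channel == channel, c("x", "y", "frame")]
  pts <- pts[order(pts$frame), , drop = FALSE]
  rownames(pts) <- NULL
  n <- nrow(pts)
  traj <- integer(n)
  if (n > 0) {
    frames <- sort(unique(pts$frame))
    byf <- split(seq_len(n), factor(pts$frame, levels = frames))
    next_id <- 0L
    for (k in seq_along(frames)) {
      ia <- byf[[k]]
      new <- ia[traj[ia] == 0L]
      if (length(new)) {
        traj[new] <- next_id + seq_along(new)
        next_id <- next_id + length(new)
      }
      if (k == length(frames) || frames[k + 1L] != frames[k] + 1L) next
      ib <- byf[[k + 1L]]
      if (!length(ib)) next
      dx <- outer(pts$x[ia], pts$x[ib], "-")
      dy <- outer(pts$y[ia], pts$y[ib], "-")
      within <- (dx * dx + dy * dy) <= radius^2
      dim(within) <- c(length(ia), length(ib))
      rc <- rowSums(within); cc <- colSums(within)
      link <- which(within & rc == 1L & rep(cc == 1L, each = length(ia)),
                    arr.ind = TRUE)
      if (nrow(link)) traj[ib[link[, 2]]] <- traj[ia[link[, 1]]]
    }
  }
  out <- data.frame(traj_id = traj, frame = pts$frame, x = pts$x, y = pts$y)
  out <- out[order(out$traj_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frame_interval = frame_interval(table), radius = radius,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  len <- table(x$traj_id)
  cat(sprintf("<trajectory_set> %d trajectories (%d with >= 2 points), %d localizations\n",
              length(len), sum(len >= 2), nrow(x)))
  invisible(x)
}

# squared displacements at a given frame lag within each trajectory
.traj_sqdisp <- function(trajs, lag) {
  byt <- split(seq_len(nrow(trajs)), trajs$traj_id)
  unlist(lapply(byt, function(idx) {
    m <- length(idx)
    if (m <= lag) return(numeric())
    i <- idx[seq_len(m - lag)]; j <- idx[seq_len(m - lag) + lag]
    (trajs$x[j] - trajs$x[i])^2 + (trajs$y[j] - trajs$y[i])^2
  }), use.names = FALSE)
}

#' Diffusion coefficients from trajectory mean squared displacements
#'
#' Tabulates the ensemble MSD(tau) pooled over all trajectories and
#' extracts D from a linear fit to the second through fourth MSD points
#' (slope / 4, with s.e. from the fit).  Trajectories with more than
#' `min_length` displacement segments also receive individual D estimates
#' by the same rule.
#'
#' @param trajs A [link_trajectories()] result.
#' @param min_length Minimum number of segments for a single-trajectory D
#'   (default 10).
#' @param max_lag Largest lag (frames) tabulated for the ensemble MSD
#'   (default 4, the largest the fit uses).
#' @return A `trajectory_diffusion`: list with `msd` (data frame `lag`,
#'   `tau_s`, `msd`, `n`), ensemble `D` and `D_se` (nm^2/s), per-trajectory
#'   data frame `per_traj`, and the number of excluded short trajectories.
#' @export
trajectory_diffusion <- function(trajs, min_length = 10, max_lag = 4) {
  stopifnot(inherits(trajs, "trajectory_set"))
  fi <- attr(trajs, "frame_interval")
  lags <- seq_len(max_lag)
  sq <- lapply(lags, function(l) .traj_sqdisp(trajs, l))
  msd <- data.frame(lag = lags, tau_s = lags * fi,
                    msd = vapply(sq, function(z)
                      if (length(z)) mean(z) else NA_real_, 0),
                    n = vapply(sq, length, 0L))
  fit_D <- function(m) {
    pts <- 2:4
    if (any(is.na(m$msd[pts]))) return(c(NA_real_, NA_real_))
    f <- stats::lm(msd ~ tau_s, data = m[pts, ])
    c(unname(stats::coef(f)[2]) / 4,
      sqrt(stats::vcov(f)[2, 2]) / 4)
  }
  ens <- fit_D(msd)
  # single-trajectory D for long trajectories
  len <- table(trajs$traj_id)
  long_ids <- as.integer(names(len)[len - 1 > min_length])
  per <- lapply(long_ids, function(id) {
    sub <- trajs[trajs$traj_id == id, , drop = FALSE]
    class(sub) <- class(trajs)
    attr(sub, "frame_interval") <- fi
    m <- data.frame(lag = lags, tau_s = lags * fi,
                    msd = vapply(lags, function(l) {
                      z <- .traj_sqdisp(sub, l)
                      if (length(z)) mean(z) else NA_real_
                    }, 0))
    d <- fit_D(m)
    data.frame(traj_id = id, n_points = nrow(sub), D = d[1], D_se = d[2])
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(traj_id = integer(), n_points = integer(), D = numeric(),
               D_se = numeric())
  n_excluded <- sum(len - 1 <= min_length)
  structure(list(msd = msd, D = ens[1], D_se = ens[2], per_traj = per,
                 n_excluded = n_excluded, frame_interval = fi),
            class = "trajectory_diffusion")
}

#' @export
print.trajectory_diffusion <- function(x, ...) {
  cat(sprintf("<trajectory_diffusion> ensemble D = %.5g +/- %.2g nm^2/s; %d single-trajectory D (%d too short)\n",
              x$D, x$D_se, nrow(x$per_traj), x$n_excluded))
  invisible(x)
}

#' Channel-1 displacement steps adjacent to simultaneous channel-2 partners
#'
#' Links channel-1 trajectories, forms their consecutive-frame steps, and
#' flags the steps whose endpoint localizations have a same-frame channel-2
#' localization within `r_c` (either endpoint by default; `mode = "both"`
#' requires both).  This selects the steps of molecules that are
#' correlated with the other species at short range, e.g. to compare their
#' step-size distribution with that of all steps.
#'
#' @param table A [loc_table()] with both channels present.
#' @param r_c Correlation radius in nm (default 50).
#' @param radius Trajectory linking radius in nm (default 500).
#' @param mode `"either"` or `"both"` endpoint proximity rule.
#' @return A data frame of steps: `traj_id`, `frame` (start), `x0`, `y0`,
#'   `x1`, `y1`, `step` (nm) and logical `correlated`.
#' @export
correlated_steps <- function(table, r_c = 50, radius = 500,
                             mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (r_c <= 0) stop("r_c must be > 0")
  trajs <- link_trajectories(table, channel = 1, radius = radius)
  ch2 <- table[table$channel == 2L, c("x", "y", "frame")]
  # flag each channel-1 localization with a simultaneous nearby partner
  near <- logical(nrow(trajs))
  if (nrow(ch2)) {
    byf2 <- split(seq_len(nrow(ch2)), ch2$frame)
    byf1 <- split(seq_len(nrow(trajs)), trajs$frame)
    for (f in intersect(names(byf1), names(byf2))) {
      i1 <- byf1[[f]]; i2 <- byf2[[f]]
      dx <- outer(trajs$x[i1], ch2$x[i2], "-")
      dy <- outer(trajs$y[i1], ch2$y[i2], "-")
      near[i1] <- rowSums((dx * dx + dy * dy) <= r_c^2) > 0
    }
  }
  i <- seq_len(nrow(trajs) - 1L)
  same <- trajs$traj_id[i] == trajs$traj_id[i + 1L] &
    trajs$frame[i + 1L] == trajs$frame[i] + 1L
  i <- i[same]
  corr <- if (mode == "either") near[i] | near[i + 1L] else
    near[i] & near[i + 1L]
  data.frame(traj_id = trajs$traj_id[i], frame = trajs$frame[i],
             x0 = trajs$x[i], y0 = trajs$y[i],
             x1 = trajs$x[i + 1L], y1 = trajs$y[i + 1L],
             step = sqrt((trajs$x[i + 1L] - trajs$x[i])^2 +
                           (trajs$y[i + 1L] - trajs$y[i])^2),
             correlated = corr)
}
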