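# shared fixtures: all test data is generated in code

rect_roi <- function(L = 4000, pixel = 25)
  make_roi_mask(list(type = "rectangle", bounds = c(0, L, 0, L)),
                pixel_size = pixel)

# uniform two-channel table: n points split over frames and channels
uniform_table <- function(n, L = 4000, n_frames = 10, seed = NULL,
                          frame_interval = 0.03) {
  if (!is.null(seed)) set.seed(seed)
  loc_table(runif(n, 0, L), runif(n, 0, L),
            frame = sample(0:(n_frames - 1), n, replace = TRUE),
            channel = sample(1:2, n, replace = TRUE),
            frame_interval = frame_interval)
}

# ground-truth random walks for a two-population (slow/fast) mixture,
# reflecting box, one channel; returns an observe_smlm()-compatible truth
mixture_truth <- function(n = 300, alpha = 0.25, d1 = 2e4, d2 = 2e5,
                          frames = 600, box = 2e4, dt = 0.03, seed = 1) {
  set.seed(seed)
  nslow <- round(alpha * n)
  D <- c(rep(d1, nslow), rep(d2, n - nslow))
  pos <- array(0, c(frames, n, 2))
  for (k in 1:2) {
    start <- runif(n, 0, box)
    steps <- matrix(rnorm(frames * n, 0, rep(sqrt(2 * D * dt), each = frames)),
                    frames, n)
    z <- apply(rbind(start, steps[-1, , drop = FALSE]), 2, cumsum)
    z <- z %% (2 * box)
    pos[, , k] <- ifelse(z > box, 2 * box - z, z)
  }
  list(positions = pos, channel = rep(1L, n), frame_interval = dt,
       n_slow = nslow)
}

# two uniform channels in one frame with a co-clustered fraction:
# every channel-1 point gets a channel-2 partner jittered by `sigma`
paired_table <- function(n_per_channel = 5000, L = 5000, sigma = 75,
                         seed = 1) {
  set.seed(seed)
  x1 <- runif(n_per_channel, 0, L); y1 <- runif(n_per_channel, 0, L)
  x2 <- (x1 + rnorm(n_per_channel, 0, sigma)) %% L
  y2 <- (y1 + rnorm(n_per_channel, 0, sigma)) %% L
  loc_table(c(x1, x2), c(y1, y2), frame = rep(0L, 2 * n_per_channel),
            channel = rep(1:2, each = n_per_channel))
}
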