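# clustered structure re-sampled with localization noise per group, as a
# blinking acquisition would produce, then rigidly shifted by the drift
make_drifting <- function(n = 600, L = 5000, groups = 4, group_size = 500,
                          shift = c(0, 0), per_group = NULL, seed = 1,
                          n_clusters = 60, jitter = 40) {
  set.seed(seed)
  cx <- runif(n_clusters, 500, L - 500); cy <- runif(n_clusters, 500, L - 500)
  xs <- c(); ys <- c(); fr <- c()
  for (g in seq_len(groups) - 1) {
    off <- if (is.null(per_group)) shift * g else per_group[[g + 1]]
    pick <- sample(n_clusters, n, replace = TRUE)
    xs <- c(xs, cx[pick] + rnorm(n, 0, jitter) + off[1])
    ys <- c(ys, cy[pick] + rnorm(n, 0, jitter) + off[2])
    fr <- c(fr, sample(g * group_size + 0:(group_size - 1), n, TRUE))
  }
  loc_table(xs, ys, fr, rep(1L, length(xs)))
}

test_that("a static cloud duplicated across groups yields zero drift", {
  set.seed(1)
  x <- runif(400, 500, 4500); y <- runif(400, 500, 4500)
  tab <- loc_table(rep(x, 3), rep(y, 3),
                   frame = rep(c(0L, 500L, 1000L), each = 400),
                   channel = rep(1L, 1200))
  track <- estimate_drift(tab, group_size = 500, pixel_size = 50)
  expect_equal(track$dx, rep(0, 3), tolerance = 1e-8)
  expect_equal(track$dy, rep(0, 3), tolerance = 1e-8)
  fixed <- apply_drift(tab, track)
  expect_equal(fixed$x, tab$x)
  expect_equal(fixed$y, tab$y)
})

test_that("a known (+80, -40) nm shift is recovered within half a pixel", {
  tab <- make_drifting(groups = 2, per_group = list(c(0, 0), c(80, -40)))
  track <- estimate_drift(tab, group_size = 500, pixel_size = 50)
  expect_lt(abs(track$dx[2] - 80), 25)
  expect_lt(abs(track$dy[2] - (-40)), 25)
})

test_that("linear drift of 10 nm/group accumulates linearly; correction is a fixpoint", {
  tab <- make_drifting(n = 800, groups = 10, shift = c(10, 10), seed = 3)
  track <- estimate_drift(tab, group_size = 500, pixel_size = 50)
  slope <- coef(lm(track$dx ~ track$group))[2]
  expect_lt(abs(slope - 10) / 10, 0.2)
  fixed <- apply_drift(tab, track)
  # mean position moves by exactly the mean applied offset
  grp <- tab$frame %/% 500 + 1
  expect_equal(mean(tab$x) - mean(fixed$x), mean(track$dx[grp]))
  # re-estimation on corrected data finds sub-pixel residuals
  track2 <- estimate_drift(fixed, group_size = 500, pixel_size = 50)
  expect_lt(max(abs(track2$dx)), 25)
  expect_lt(max(abs(track2$dy)), 25)
})

test_that("drift estimation is equivariant under a constant global shift", {
  tab <- make_drifting(n = 700, groups = 5, shift = c(12, -7), seed = 4)
  track <- estimate_drift(tab, group_size = 500, pixel_size = 50)
  shifted <- tab
  shifted$x <- tab$x + 1000; shifted$y <- tab$y + 500
  track_s <- estimate_drift(shifted, group_size = 500, pixel_size = 50)
  # offsets are relative: a common translation leaves them unchanged
  expect_equal(track_s$dx, track$dx, tolerance = 1e-6)
  expect_equal(track_s$dy, track$dy, tolerance = 1e-6)
})

test_that("identical bead sets give the identity with ~zero residual", {
  set.seed(6)
  beads <- cbind(runif(30, 0, 4e4), runif(30, 0, 4e4))
  tr <- fit_registration(beads, beads, degree = 2)
  expect_lt(tr$rms_residual, 1e-6)
  tab <- uniform_table(200, L = 4e4, seed = 7)
  out <- apply_registration(tab, tr, channel = 1)
  expect_equal(out$x, tab$x, tolerance = 1e-9)
  expect_equal(out$y, tab$y, tolerance = 1e-9)
})

test_that("a known 2nd-order warp with 5 nm noise is recovered with rms ~ 5 nm", {
  set.seed(8)
  nb <- 40
  near <- cbind(runif(nb, 0, 4e4), runif(nb, 0, 4e4))
  warp <- function(x, y) cbind(
    20 + 1.001 * x + 2e-4 * y + 1e-8 * x^2 - 5e-9 * x * y,
    -15 + 0.999 * y + 1e-4 * x + 8e-9 * y^2)
  far <- warp(near[, 1], near[, 2]) + rnorm(2 * nb, 0, 5)
  tr <- fit_registration(near, far, degree = 2)
  expect_lt(abs(tr$rms_residual - 5 * sqrt(2)), 4)
  # apply to fresh points: residual to the true warp stays small
  set.seed(9)
  test_pts <- cbind(runif(100, 2000, 38000), runif(100, 2000, 38000))
  tab <- loc_table(test_pts[, 1], test_pts[, 2], rep(0L, 100), rep(1L, 100))
  mapped <- apply_registration(tab, tr, channel = 1)
  truth <- warp(test_pts[, 1], test_pts[, 2])
  err <- sqrt((mapped$x - truth[, 1])^2 + (mapped$y - truth[, 2])^2)
  expect_lt(mean(err), 10)
})

test_that("pure translation is fitted exactly at any degree; channels stay separate", {
  set.seed(10)
  near <- cbind(runif(25, 0, 1e4), runif(25, 0, 1e4))
  far <- near + matrix(rep(c(120, -60), each = 25), ncol = 2)
  for (deg in 1:3) {
    tr <- fit_registration(near, far, degree = deg)
    expect_lt(tr$rms_residual, 1e-6)
  }
  tr <- fit_registration(near, far, degree = 1)
  tab <- loc_table(c(0, 0), c(0, 0), c(0, 0), c(1, 2))
  out <- apply_registration(tab, tr, channel = 1)
  expect_equal(out$x, c(120, 0), tolerance = 1e-9)
  expect_equal(out$y, c(-60, 0), tolerance = 1e-9)
})

test_that("forward plus inverse-fitted registration restores coordinates", {
  set.seed(11)
  near <- cbind(runif(35, 0, 2e4), runif(35, 0, 2e4))
  far <- cbind(10 + 1.002 * near[, 1] + 2e-8 * near[, 1]^2,
               -5 + 0.998 * near[, 2] + 1e-8 * near[, 2] * near[, 1])
  fwd <- fit_registration(near, far, degree = 2)
  inv <- fit_registration(far, near, degree = 2)
  tab <- loc_table(near[, 1], near[, 2], rep(0L, 35), rep(1L, 35))
  back <- apply_registration(apply_registration(tab, fwd, 1), inv, 1)
  err <- sqrt((back$x - near[, 1])^2 + (back$y - near[, 2])^2)
  expect_lt(max(err), max(1, 2 * (fwd$rms_residual + inv$rms_residual)))
})

test_that("underdetermined registration is rejected with the minimum count", {
  near <- cbind(runif(4), runif(4))
  expect_error(fit_registration(near, near, degree = 2), ">= 6")
})

test_that("registration residuals are invariant under common rigid motion", {
  set.seed(12)
  near <- cbind(runif(30, 0, 2e4), runif(30, 0, 2e4))
  far <- near + cbind(rnorm(30, 0, 8), rnorm(30, 0, 8))
  r0 <- fit_registration(near, far, degree = 2)$rms_residual
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  r1 <- fit_registration(near %*% R + 500, far %*% R + 500,
                         degree = 2)$rms_residual
  expect_equal(r0, r1, tolerance = 0.05)
})
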