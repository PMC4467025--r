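test_that("simultaneous pair bookkeeping follows N = sum n1_i * n2_i", {
  # frames with n1 = (2, 3), n2 = (4, 1): N = 2*4 + 3*1 = 11
  roi <- rect_roi(L = 100, pixel = 10)
  tab <- loc_table(runif(10, 0, 100), runif(10, 0, 100),
                   frame = c(0, 0, 1, 1, 1, 0, 0, 0, 0, 1),
                   channel = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  h <- pair_histogram(tab, roi, radial_binning(10, 150), tau = 0)
  expect_equal(h$N, 11)
  expect_equal(sum(h$M), 11)    # max radius >= ROI diagonal: all pairs binned
  # lag 1: N = n1_0 * n2_1 = 2*1
  h1 <- pair_histogram(tab, roi, radial_binning(10, 150), tau = 1)
  expect_equal(h1$N, 2)
  # time-averaged mode: N = n1 * n2
  ha <- pair_histogram(tab, roi, radial_binning(10, 150), tau = "all")
  expect_equal(ha$N, 25)
  expect_equal(sum(ha$M), 25)
})

test_that("a single 3 nm pair lands in the half-open bin [3, 4)", {
  roi <- make_roi_mask(list(type = "rectangle", bounds = c(-5, 10, -5, 5)),
                       pixel_size = 1)
  tab <- loc_table(c(0, 3), c(0, 0), c(0, 0), c(1, 2))
  h <- pair_histogram(tab, roi, radial_binning(1, 4), tau = 0)
  expect_equal(h$M, c(0, 0, 0, 1))
  expect_equal(h$N, 1)
})

test_that("direct evaluation: C = M / (dA rho0 W)", {
  # M = 63 pairs at r = 1 um, dr = 0.1 um, N = 1000, A = 100 um^2, W = 1
  mu <- 2 * pi * 1000 * 100 * (1000 / 1e8)
  expect_equal(63 / mu, 10.03, tolerance = 1e-3)
  # and through the code path with a synthetic histogram
  bn <- radial_binning(100, 1100)
  h <- structure(list(M = ifelse(bn$centers == 1050, 63L, 0L) * 0 +
                        ifelse(abs(bn$centers - 950) < 1, 63L, 0L),
                      N = 1000, F = 1, rho0 = 1000 / 1e8, area = 1e8,
                      binning = bn, tau = 0L, window = c(0L, 0L),
                      n_ch = c(100L, 10L), channels = c(1, 2),
                      frame_interval = 0.03),
                 class = "pair_histogram")
  edge <- structure(list(r = bn$centers, W = rep(1, length(bn$centers)),
                         binning = bn, pixel_size = 25),
                    class = "edge_curve")
  cv <- correlation_from_histogram(h, edge, sparse = FALSE)
  i <- which(abs(bn$centers - 950) < 1)  # bin [900, 1000): center 950
  expect_equal(cv$C[i], 63 / (2 * pi * 950 * 100 * 1e-5), tolerance = 1e-12)
})

test_that("independent uniform channels give C compatible with 1", {
  roi <- rect_roi()
  bn <- radial_binning(50, 600)
  bad <- 0; tot <- 0
  for (s in 1:5) {
    tab <- uniform_table(6000, seed = 100 + s)
    cv <- cross_correlation(tab, roi, bn, tau = 0)
    z <- abs(cv$C - 1) / cv$sd_C
    bad <- bad + sum(z > 3); tot <- tot + length(z)
  }
  expect_gte(1 - bad / tot, 0.99)
})

test_that("co-localized channels reproduce the brute-force first-bin limit", {
  set.seed(9)
  L <- 4000; n <- 400
  roi <- rect_roi(L = L)
  x <- runif(n, 0, L); y <- runif(n, 0, L)
  tab <- loc_table(c(x, x), c(y, y), rep(0L, 2 * n), rep(1:2, each = n))
  bn <- radial_binning(25, 500)
  cv <- cross_correlation(tab, roi, bn, tau = 0)
  # brute force: self pairs all fall at distance 0 plus uniform background
  d <- as.matrix(dist(cbind(x, y)))
  m1_bg <- sum(d > 0 & d < 25)  # ordered cross pairs excluding self
  mu1 <- bn$ring_areas[1] * (n^2 / roi$area) * cv$W[1]
  expect_equal(cv$M[1], n + m1_bg)
  expect_equal(cv$C[1], (n + m1_bg) / mu1)
  expect_gt(cv$C[1], 10)  # ~ A / (dA * n): far above random coincidence
})

test_that("error propagation follows sigma_C^2 = C^2 (1/M + 1/N)", {
  # C = 2, M = 100, N = 1e4 -> sigma_C^2 = 4 (1/100 + 1/1e4) = 0.0404
  bn <- radial_binning(10, 20)
  h <- structure(list(M = c(100L, 0L), N = 1e4, F = 1, rho0 = 1,
                      area = 1e4, binning = bn, tau = 0L,
                      window = c(0L, 0L), n_ch = c(100L, 100L),
                      channels = c(1, 2), frame_interval = 0.03),
                 class = "pair_histogram")
  edge <- structure(list(r = bn$centers, W = c(1, 1), binning = bn,
                         pixel_size = 10), class = "edge_curve")
  cv <- correlation_from_histogram(h, edge, sparse = FALSE)
  scaled <- cv
  scaled$mu <- c(50, 50)          # force C = 2 in the first bin
  scaled$C <- scaled$M / scaled$mu
  scaled <- correlation_variance(h, scaled, sparse = FALSE)
  expect_equal(scaled$var_C[1], 0.0404, tolerance = 1e-12)
  expect_equal(sqrt(scaled$var_C[1]), 0.201, tolerance = 1e-3)
  # sparse mode keeps empty bins with finite uncertainty
  sp <- correlation_variance(h, scaled, sparse = TRUE)
  expect_true(is.finite(sp$var_C[2]) && sp$var_C[2] > 0)
  expect_equal(sp$var_C[2], 1 / 50^2 + 0, tolerance = 1e-12)
  expect_equal(relative_error(scaled)[1], sqrt(1 / 100 + 1 / 1e4))
})

test_that("channel swap leaves the simultaneous correlation unchanged", {
  tab <- uniform_table(3000, seed = 42)
  roi <- rect_roi()
  bn <- radial_binning(50, 500)
  cv12 <- cross_correlation(tab, roi, bn, tau = 0)
  cv21 <- cross_correlation(tab, roi, bn, tau = 0, channels = c(2, 1))
  expect_equal(cv12$C, cv21$C)
  expect_equal(cv12$N, cv21$N)
})

test_that("lagged correlation is asymmetric under directed motion", {
  # channel 1 static; channel 2 sits on channel 1 at t = 0 and has moved
  # +300 nm by t = 1: the forward lag sees 300 nm, the reverse lag sees 0
  set.seed(5)
  L <- 4000; n <- 50   # sparse: the planted peak dominates the background
  x <- runif(n, 500, L - 800); y <- runif(n, 500, L - 500)
  tab <- loc_table(c(x, x, x, x + 300), c(y, y, y, y),
                   frame = rep(c(0L, 1L, 0L, 1L), each = n),
                   channel = rep(c(1L, 1L, 2L, 2L), each = n))
  roi <- rect_roi(L = L)
  bn <- radial_binning(25, 600)
  fwd <- cross_correlation(tab, roi, bn, tau = 1)   # ch1 at t, ch2 at t+1
  rev <- cross_correlation(tab, roi, bn, tau = 1, channels = c(2, 1))
  i300 <- floor(300 / 25) + 1   # half-open bin holding a 300 nm separation
  expect_gt(fwd$C[i300] / max(fwd$C[1], 1), 5)  # mass concentrated at 300 nm
  expect_gt(rev$C[1] / max(rev$C[i300], 1), 5)  # reverse lag peaks at zero
})

test_that("weighted tau-averaging reproduces the closed-form mean and K-fold variance", {
  bn <- radial_binning(10, 20)
  mk <- function(C, v, tau) structure(
    list(r = bn$centers, C = C, var_C = v, sd_C = sqrt(v), M = c(1, 1),
         W = c(1, 1), mu = c(1, 1), N = 10, F = 1, tau = tau,
         tau_s = tau * 0.03, binning = bn, n_ch = c(1, 1), area = 1,
         window = NULL, method = "pairwise", sparse = FALSE),
    class = "corr_curve")
  # bins with (C, sigma) = (1.0, 0.1) and (2.0, 0.2) -> weighted mean 1.2
  avg <- average_over_tau(list(mk(c(1, 1), c(0.01, 0.01), 1),
                               mk(c(2, 2), c(0.04, 0.04), 2)))
  expect_equal(avg$C[1], 1.2)
  expect_equal(avg$var_C[1], 1 / (1 / 0.01 + 1 / 0.04))
  # K identical curves: same mean, variance / K
  K <- 4
  avgK <- average_over_tau(replicate(K, mk(c(1.5, 1.5), c(0.02, 0.02), 1),
                                     simplify = FALSE))
  expect_equal(avgK$C, c(1.5, 1.5))
  expect_equal(avgK$var_C, c(0.02, 0.02) / K)
})

test_that("tau->0 extrapolation recovers constants and linear intercepts exactly", {
  bn <- radial_binning(10, 20)
  mk <- function(C, tau) structure(
    list(r = bn$centers, C = C, var_C = c(0.01, 0.01), sd_C = c(0.1, 0.1),
         M = c(1, 1), W = c(1, 1), mu = c(1, 1), N = 10, F = 1, tau = tau,
         tau_s = tau * 0.03, binning = bn, n_ch = c(1, 1), area = 1,
         window = NULL, method = "pairwise", sparse = FALSE),
    class = "corr_curve")
  taus <- 1:6
  const <- lapply(taus, function(t) mk(c(1.7, 0.4), t))
  e1 <- extrapolate_tau_zero(const, exclude = 0L)
  expect_equal(e1$C, c(1.7, 0.4))
  lin <- lapply(taus, function(t) mk(c(2 - 0.1 * t, 1 + 0.05 * t), t))
  e2 <- extrapolate_tau_zero(lin, exclude = c(0L, 1L), mode = "linear")
  expect_equal(e2$C, c(2, 1), tolerance = 1e-9)
  expect_error(extrapolate_tau_zero(const[1:3], exclude = c(1L, 2L)),
               "at least 3")
})

test_that("PMF obeys the log identities and propagates variance", {
  bn <- radial_binning(10, 30)
  cv <- structure(list(r = bn$centers, C = c(1, exp(1), exp(-1)),
                       var_C = c(0.04, 0.04, 0.04), sd_C = rep(0.2, 3),
                       binning = bn), class = "corr_curve")
  p <- pmf_from_correlation(cv)
  expect_equal(p$pmf, c(0, -1, 1))
  expect_equal(p$var_pmf, c(0.04, 0.04 / exp(2), 0.04 * exp(2)))
  cv$C[2] <- 0
  p0 <- pmf_from_correlation(cv)
  expect_true(is.na(p0$pmf[2]))            # flagged, not -Inf
})

test_that("density conversion: C = 1 gives flat density and zero excess", {
  bn <- radial_binning(25, 500)
  cv <- structure(list(r = bn$centers, C = rep(1, 20),
                       var_C = rep(0.01, 20), binning = bn),
                  class = "corr_curve")
  d <- density_from_correlation(cv, 5e-6)   # 5 per um^2
  expect_equal(d$rho, rep(5e-6, 20))
  expect_equal(d$cumulative_excess, rep(0, 20))
  # prefix-sum additivity
  cv$C <- seq(2, 0.5, length.out = 20)
  d2 <- density_from_correlation(cv, 5e-6)
  expect_equal(diff(d2$cumulative_excess),
               ((cv$C - 1) * 5e-6 * bn$ring_areas)[-1])
})

test_that("constructed clusters yield the planted excess partner count", {
  # k = 3 extra channel-2 partners within 100 nm of every channel-1 point
  set.seed(12)
  L <- 16000; n1 <- 100; k <- 3
  x1 <- runif(n1, 300, L - 300); y1 <- runif(n1, 300, L - 300)
  th <- runif(n1 * k, 0, 2 * pi); rad <- 100 * sqrt(runif(n1 * k))
  n2bg <- 3000
  x2 <- c(runif(n2bg, 0, L), rep(x1, each = k) + rad * cos(th))
  y2 <- c(runif(n2bg, 0, L), rep(y1, each = k) + rad * sin(th))
  tab <- loc_table(c(x1, x2), c(y1, y2),
                   frame = rep(0L, n1 + length(x2)),
                   channel = rep(c(1L, 2L), c(n1, length(x2))))
  roi <- rect_roi(L = L)
  bn <- radial_binning(25, 1000)
  cv <- cross_correlation(tab, roi, bn, tau = 0)
  d <- density_from_correlation(cv, length(x2) / roi$area)
  got <- d$cumulative_excess[max(which(bn$centers < 100 + 12.5))]
  expect_equal(got, k, tolerance = 0.15)
})

test_that("scrambling frames leaves the time-averaged statistic invariant", {
  tab <- uniform_table(2000, n_frames = 40, seed = 77)
  roi <- rect_roi()
  bn <- radial_binning(50, 500)
  before <- cross_correlation(tab, roi, bn, tau = "all")
  perm <- sample(0:39)
  tab2 <- tab
  tab2$frame <- perm[tab$frame + 1L]
  after <- cross_correlation(tab2, roi, bn, tau = "all")
  expect_equal(before$C, after$C)
  expect_warning(rs1 <- scrambled_resample(tab, roi, bn, 1, 40, seed = 1),
                 "single window")
  expect_true(all(is.na(rs1$emp_sd)))
  expect_error(scrambled_resample(tab, roi, bn, 5, 40), "have 40")
})
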