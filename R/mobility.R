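## Same-channel displacement analysis: G(r, tau) normalized into a
## step-length probability density, one/two-population Gaussian fits, and
## the decay of the slow fraction alpha with lag time.

#' Time-lagged same-channel correlation G(r, tau)
#'
#' Tabulates the correlation between localizations of one fluorophore type
#' observed with a lag of `tau` frames, using the same histogram/edge
#' normalization machinery as the cross-correlation.  For mobile probes the
#' short-r part of G is dominated by self-pairs (the same molecule seen
#' twice) and, once normalized, measures the displacement probability
#' density.  `G(r, tau = 0)` measures probe density, not motion, and is
#' flagged non-interpretable.
#'
#' @inheritParams pair_histogram
#' @param channel Which channel to autocorrelate (1 or 2).
#' @param tau Lag in frames (>= 1 for displacement analysis).
#' @param edge Optional precomputed [edge_factor()].
#' @return A `displacement_pdf` with the `G` part filled (`pdf` is `NULL`
#'   until [pdf_from_G()]).
#' @export
auto_correlation <- function(table, channel, roi, binning, tau = 1,
                             window = NULL, edge = NULL) {
  if (is.null(edge)) edge <- edge_factor(roi, binning)
  hist <- pair_histogram(table, roi, binning, tau = tau, window = window,
                         channels = c(channel, channel))
  # sparse-mode errors keep empty bins informative in the PDF fits
  cv <- correlation_from_histogram(hist, edge, sparse = TRUE)
  structure(list(r = cv$r, G = cv$C, var_G = cv$var_C, pdf = NULL,
                 var_pdf = NULL, tau = tau,
                 tau_s = tau * frame_interval(table), channel = channel,
                 binning = binning, M = cv$M, N = cv$N),
            class = "displacement_pdf")
}

#' Normalize G(r, tau) into a displacement probability density
#'
#' Sets the total two-dimensional area under the curve to one:
#' `pdf = G / sum(G * dA)`.  In the edge-corrected normalization,
#' uncorrelated pairs of *different* molecules contribute exactly G = 1 in
#' expectation, while self-pairs (the same molecule seen twice) carry the
#' displacement signal on top; by default that uniform background is
#' subtracted before normalizing, so the result estimates the step-length
#' density itself even at non-negligible labelling density.  With
#' `background = "none"` the raw curve is normalized, appropriate when
#' localizations are so sparse that cross-molecule pairs are negligible.
#'
#' @param g A `displacement_pdf` from [auto_correlation()].
#' @param background `"uniform"` (subtract the G = 1 cross-molecule
#'   baseline; default) or `"none"`.
#' @return `g` with `pdf` and `var_pdf` filled;
#'   `sum(pdf * ring_areas) == 1` to numerical tolerance.
#' @export
pdf_from_G <- function(g, background = c("uniform", "none")) {
  stopifnot(inherits(g, "displacement_pdf"))
  background <- match.arg(background)
  G <- if (background == "uniform") g$G - 1 else g$G
  ok <- is.finite(G)
  tot <- sum(G[ok] * g$binning$ring_areas[ok])
  if (!is.finite(tot) || tot <= 0)
    stop("G carries no correlated mass: cannot normalize")
  g$pdf <- G / tot
  g$var_pdf <- g$var_G / tot^2
  g$background <- background
  g
}

#' @export
print.displacement_pdf <- function(x, ...) {
  cat(sprintf("<displacement_pdf> channel %d, tau = %d frames (%.4g s), %s\n",
              x$channel, x$tau, x$tau_s,
              if (is.null(x$pdf)) "raw G" else "normalized"))
  invisible(x)
}

#' @export
plot.displacement_pdf <- function(x, ...) {
  y <- if (is.null(x$pdf)) x$G else x$pdf
  graphics::plot(x$r, y, type = "h", lwd = 3, col = "grey60",
                 xlab = "r (nm)",
                 ylab = if (is.null(x$pdf)) "G(r)" else "PDF (nm^-2)", ...)
  invisible(x)
}

# bin-averaged density of the 2-D Gaussian step model with width MSD:
# mass in [r1, r2) is exp(-r1^2/MSD) - exp(-r2^2/MSD); divide by ring area.
.gauss_bin <- function(binning, msd) {
  r1 <- binning$breaks[-length(binning$breaks)]
  r2 <- binning$breaks[-1]
  (exp(-r1^2 / msd) - exp(-r2^2 / msd)) / (pi * (r2^2 - r1^2))
}

# inverse-variance weights, optionally with a variance floor expressed as
# a fraction of the peak density.  Pure Poisson weights (floor 0) are
# statistically efficient when the two-Gaussian model is exact; the floor
# tames tail bins with vanishing counting error, which otherwise amplify
# small model mismatch (partially bound steps, residual cross-molecule
# structure) into degenerate optima.
.fit_weights <- function(g, floor_frac = 0) {
  vfloor <- (floor_frac * max(abs(g$pdf), na.rm = TRUE))^2
  w <- 1 / (g$var_pdf + vfloor)
  w[!is.finite(w) | is.na(g$pdf)] <- 0
  w
}

#' Fit a single-population diffusion model to a displacement PDF
#'
#' Weighted least-squares fit of the 2-D Brownian step model: a normalized
#' Gaussian centred at zero whose width is the mean squared displacement,
#' evaluated as exact bin averages.  `D = MSD / (4 tau)`.
#'
#' @param g A normalized `displacement_pdf` (see [pdf_from_G()]).
#' @param tau_s Lag in seconds; defaults to the value carried by `g`.
#' @param floor_frac Variance floor for the fit weights, as a fraction of
#'   the peak density (default 0: pure Poisson inverse-variance weights).
#' @return A `diffusion_fit`: list with `msd` (nm^2), `msd_se`, `D`
#'   (nm^2/s), `D_se`, `tau_s`, `fitted`.
#' @export
fit_single <- function(g, tau_s = NULL, floor_frac = 0) {
  stopifnot(inherits(g, "displacement_pdf"))
  if (is.null(g$pdf)) g <- pdf_from_G(g)
  if (is.null(tau_s)) tau_s <- g$tau_s
  w <- .fit_weights(g, floor_frac)
  ok <- w > 0
  msd0 <- sum(g$pdf[ok] * g$r[ok]^2 * g$binning$ring_areas[ok])
  df <- data.frame(y = g$pdf[ok], w = w[ok], bin = which(ok))
  bn <- g$binning
  fit <- minpack.lm::nlsLM(
    y ~ .gauss_bin(bn, msd)[bin], data = df, weights = df$w,
    start = list(msd = msd0), lower = 1e-6,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  msd <- unname(stats::coef(fit)["msd"])
  se <- sqrt(stats::vcov(fit)[1, 1])
  structure(list(msd = msd, msd_se = se, D = msd / (4 * tau_s),
                 D_se = se / (4 * tau_s), tau_s = tau_s,
                 fitted = .gauss_bin(bn, msd), r = g$r, fit = fit),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> MSD = %.5g +/- %.2g nm^2, D = %.5g +/- %.2g nm^2/s (tau = %.4g s)\n",
              x$msd, x$msd_se, x$D, x$D_se, x$tau_s))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(msd = object$msd, D = object$D)

#' Fit a two-population diffusion model to a displacement PDF
#'
#' Weighted fit of a mixture of two independent normalized Gaussian step
#' models with widths `msd1 <= msd2` (slow and fast populations) and slow
#' fraction `alpha` in \[0, 1\].  Starting widths come from mass-quantile
#' radii of the PDF with multiplicative restarts; among converged fits the
#' best weighted SSE wins, with interior solutions preferred over ones
#' pinned at the width bound.  A width ratio below 2 triggers an
#' identifiability warning.
#'
#' @param g A normalized `displacement_pdf`.
#' @param tau_s Lag in seconds (defaults to the value carried by `g`).
#' @param init Optional `c(alpha, msd1, msd2)` starting values.
#' @param n_restarts Number of jittered restarts (default 5).
#' @param floor_frac Variance floor for the fit weights, as a fraction of
#'   the peak density.  The default 0 keeps pure Poisson weights (well
#'   calibrated when the mixture model is exact); [mobility_analysis()]
#'   uses 0.005 to stay robust to model mismatch across lags.
#' @return A `diffusion_fit2`: list with `alpha`, `msd1`, `msd2`, their
#'   standard errors, `D1`, `D2`, the fit covariance `cov`
#'   (alpha, msd1, msd2 order), `identifiable`, `tau_s`, `fitted`.
#' @export
fit_two <- function(g, tau_s = NULL, init = NULL, n_restarts = 5,
                    floor_frac = 0) {
  stopifnot(inherits(g, "displacement_pdf"))
  if (is.null(g$pdf)) g <- pdf_from_G(g)
  if (is.null(tau_s)) tau_s <- g$tau_s
  w <- .fit_weights(g, floor_frac)
  ok <- w > 0
  df <- data.frame(y = g$pdf[ok], w = w[ok], bin = which(ok))
  bn <- g$binning
  # mass-quantile radii of the positive part seed the two widths; noisy
  # (possibly negative) tails make raw moments unreliable
  mass <- cumsum(pmax(g$pdf, 0) * bn$ring_areas)
  qr_ <- function(q) g$r[which.min(abs(mass - q * max(mass)))]
  m_lo <- max(qr_(0.25)^2, 4 * bn$dr^2)
  m_hi <- max(qr_(0.90)^2, 4 * m_lo)
  starts <- list()
  if (!is.null(init)) starts[[1]] <- list(alpha = init[1], msd1 = init[2],
                                          msd2 = init[3])
  jit <- c(1, 0.5, 2, 0.25, 4)[seq_len(min(n_restarts, 5))]
  for (j in jit)
    starts[[length(starts) + 1]] <- list(alpha = 0.5, msd1 = m_lo / j,
                                         msd2 = m_hi * j)
  model_pdf <- function(alpha, msd1, msd2)
    (alpha * .gauss_bin(bn, msd1) + (1 - alpha) * .gauss_bin(bn, msd2))[df$bin]
  # a component wider than the analysis window degenerates into a flat
  # background; both widths are bounded so most of their mass stays inside
  ub <- (0.75 * max(bn$breaks))^2
  starts <- lapply(starts, function(s) {
    s$msd1 <- min(s$msd1, ub / 4); s$msd2 <- min(s$msd2, ub / 2); s
  })
  # interior solutions are preferred over ones pinned at the width bound:
  # a bound-hitting "fast" component is the degenerate background mode
  best <- NULL; best_sse <- Inf; best_interior <- FALSE
  for (s in starts) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ alpha * .gauss_bin(bn, msd1)[bin] +
        (1 - alpha) * .gauss_bin(bn, msd2)[bin],
      data = df, weights = df$w, start = s,
      lower = c(alpha = 0, msd1 = 1e-6, msd2 = 1e-6),
      upper = c(alpha = 1, msd1 = ub, msd2 = ub),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(df$w * stats::residuals(fit)^2)
    interior <- max(stats::coef(fit)[c("msd1", "msd2")]) < 0.95 * ub
    take <- if (interior == best_interior) sse < best_sse else interior
    if (take) { best <- fit; best_sse <- sse; best_interior <- interior }
  }
  if (!is.null(best)) {
    cf <- stats::coef(best)
    V <- tryCatch(stats::vcov(best), error = function(e) matrix(NA, 3, 3))
  } else {
    # Levenberg-Marquardt rejected every start: Nelder-Mead on transformed
    # parameters, with Gauss-Newton covariance at the optimum
    obj <- function(p) {
      a <- stats::plogis(p[1])
      m1 <- min(exp(p[2]), ub); m2 <- min(exp(p[3]), ub)
      sum(df$w * (df$y - model_pdf(a, m1, m2))^2)
    }
    p0 <- c(0, log(min(m_lo, ub / 4)), log(min(m_hi, ub / 2)))
    op <- stats::optim(p0, obj, control = list(maxit = 2000))
    if (op$convergence != 0) stop("two-population fit failed to converge")
    cf <- c(alpha = stats::plogis(op$par[1]),
            msd1 = min(exp(op$par[2]), ub),
            msd2 = min(exp(op$par[3]), ub))
    best_sse <- op$value
    eps <- pmax(abs(cf) * 1e-5, 1e-8)
    J <- sapply(1:3, function(k) {
      hi <- cf; lo <- cf
      hi[k] <- hi[k] + eps[k]; lo[k] <- lo[k] - eps[k]
      (model_pdf(hi[1], hi[2], hi[3]) - model_pdf(lo[1], lo[2], lo[3])) /
        (2 * eps[k])
    })
    JtWJ <- crossprod(J * sqrt(df$w))
    chi2red <- best_sse / max(nrow(df) - 3, 1)
    V <- tryCatch(solve(JtWJ) * chi2red,
                  error = function(e) matrix(NA, 3, 3))
    best <- NULL
  }
  rownames(V) <- colnames(V) <- c("alpha", "msd1", "msd2")
  alpha <- unname(cf["alpha"]); msd1 <- unname(cf["msd1"])
  msd2 <- unname(cf["msd2"])
  if (msd1 > msd2) {  # enforce slow/fast ordering
    tmp <- msd1; msd1 <- msd2; msd2 <- tmp
    alpha <- 1 - alpha
    V <- V[c("alpha", "msd2", "msd1"), c("alpha", "msd2", "msd1")]
  }
  if (msd2 > 0.95 * ub)
    warning("fast component reaches the analysis window; increase r_max")
  identifiable <- msd2 >= 2 * msd1
  if (!identifiable)
    warning(sprintf("msd2/msd1 = %.2f < 2: populations not identifiable",
                    msd2 / max(msd1, 1e-12)))
  se <- sqrt(pmax(diag(V), 0))
  structure(list(alpha = alpha, msd1 = msd1, msd2 = msd2,
                 alpha_se = se[1], msd1_se = se[2], msd2_se = se[3],
                 D1 = msd1 / (4 * tau_s), D2 = msd2 / (4 * tau_s),
                 cov = V, identifiable = identifiable, tau_s = tau_s,
                 fitted = alpha * .gauss_bin(bn, msd1) +
                   (1 - alpha) * .gauss_bin(bn, msd2),
                 r = g$r, fit = best, sse = best_sse),
            class = "diffusion_fit2")
}

#' @export
print.diffusion_fit2 <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit2> alpha = %.3f +/- %.3f, MSD1 = %.5g +/- %.2g, MSD2 = %.5g +/- %.2g nm^2 (tau = %.4g s)%s\n",
    x$alpha, x$alpha_se, x$msd1, x$msd1_se, x$msd2, x$msd2_se, x$tau_s,
    if (x$identifiable) "" else " [unidentifiable]"))
  invisible(x)
}

#' @export
coef.diffusion_fit2 <- function(object, ...)
  c(alpha = object$alpha, msd1 = object$msd1, msd2 = object$msd2)

#' Fit the exponential decay of the slow fraction alpha(tau)
#'
#' Weighted fit of `alpha(tau) = alpha0 * exp(-tau / tau0)`.  `tau0`
#' estimates the off-rate (1 / tau0) of the slow state: a step spanning a
#' lag tau is slow only if the molecule stays bound throughout, so alpha
#' decays exponentially with the unbinding rate.
#'
#' @param tau_s Numeric vector of lags in seconds (>= 3 points).
#' @param alpha Slow-fraction estimates at each lag.
#' @param se Standard errors of `alpha` (used as 1/se^2 weights); optional.
#' @return An `alpha_decay_fit`: list with `alpha0`, `tau0`, their standard
#'   errors, and `non_decaying` flag (`TRUE` when the series does not
#'   decrease; `tau0` then has an s.e. spanning infinity).
#' @export
fit_alpha_decay <- function(tau_s, alpha, se = NULL) {
  if (length(tau_s) < 3) stop("need at least 3 lag points")
  w <- if (is.null(se)) rep(1, length(alpha)) else 1 / se^2
  ok <- is.finite(alpha) & alpha > 0 & is.finite(w) & w > 0
  if (sum(ok) < 3) stop("fewer than 3 usable alpha points")
  df <- data.frame(t = tau_s[ok], a = alpha[ok], w = w[ok])
  # slope check on log scale for the non-decaying flag
  lf <- stats::lm(log(a) ~ t, data = df, weights = w)
  slope <- unname(stats::coef(lf)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ a0 * exp(-t / t0), data = df, weights = df$w,
                      start = list(a0 = df$a[1],
                                   t0 = if (slope < 0) -1 / slope else
                                     10 * max(df$t)),
                      lower = c(a0 = 0, t0 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (slope >= 0) {
      # flat or rising series: report the weighted mean with tau0 unbounded
      warning("alpha(tau) does not decay over the fitted range")
      a0 <- sum(df$w * df$a) / sum(df$w)
      return(structure(list(alpha0 = a0, tau0 = Inf,
                            alpha0_se = sqrt(1 / sum(df$w)), tau0_se = Inf,
                            non_decaying = TRUE, fit = NULL, data = df),
                       class = "alpha_decay_fit"))
    }
    stop("alpha(tau) exponential fit failed: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  se_cf <- sqrt(diag(stats::vcov(fit)))
  non_dec <- slope >= 0 || cf["t0"] > 100 * max(df$t) ||
    !is.finite(se_cf["t0"]) || se_cf["t0"] >= cf["t0"]
  if (non_dec) warning("alpha(tau) does not decay over the fitted range")
  structure(list(alpha0 = unname(cf["a0"]), tau0 = unname(cf["t0"]),
                 alpha0_se = unname(se_cf["a0"]), tau0_se = unname(se_cf["t0"]),
                 non_decaying = non_dec, fit = fit,
                 data = df), class = "alpha_decay_fit")
}

#' @export
print.alpha_decay_fit <- function(x, ...) {
  cat(sprintf("<alpha_decay_fit> alpha0 = %.3f +/- %.3f, tau0 = %.4g +/- %.2g s%s\n",
              x$alpha0, x$alpha0_se, x$tau0, x$tau0_se,
              if (x$non_decaying) " [non-decaying]" else ""))
  invisible(x)
}

#' @export
coef.alpha_decay_fit <- function(object, ...)
  c(alpha0 = object$alpha0, tau0 = object$tau0)

#' Full single-channel mobility analysis over a range of lags
#'
#' For each lag `tau = 1 .. tau_max` frames: tabulate G(r, tau), normalize
#' to a PDF, fit the two-population model, and collect `alpha(tau)`;
#' finally fit the exponential decay of alpha.
#'
#' @inheritParams auto_correlation
#' @param tau_max Largest lag in frames (default 30, about 1 s at
#'   0.03 s/frame).
#' @return A `mobility_fits`: list with per-lag data frame `fits`
#'   (tau_s, alpha, alpha_se, msd1, msd2, ...), the `decay`
#'   ([fit_alpha_decay()] result), and the per-lag fit objects.
#' @export
mobility_analysis <- function(table, channel, roi, binning, tau_max = 30,
                              window = NULL) {
  edge <- edge_factor(roi, binning)
  per_tau <- vector("list", tau_max)
  for (tau in seq_len(tau_max)) {
    g <- pdf_from_G(auto_correlation(table, channel, roi, binning, tau = tau,
                                     window = window, edge = edge))
    # robust (floored) weights: across many lags the two-Gaussian model is
    # only approximate, and exact Poisson weights over-trust the tails
    per_tau[[tau]] <- fit_two(g, floor_frac = 0.005)
  }
  fits <- do.call(rbind, lapply(per_tau, function(f)
    data.frame(tau_s = f$tau_s, alpha = f$alpha, alpha_se = f$alpha_se,
               msd1 = f$msd1, msd1_se = f$msd1_se, msd2 = f$msd2,
               msd2_se = f$msd2_se, identifiable = f$identifiable)))
  decay <- tryCatch(fit_alpha_decay(fits$tau_s, fits$alpha, fits$alpha_se),
                    error = function(e) NULL)
  structure(list(fits = fits, decay = decay, per_tau = per_tau,
                 channel = channel), class = "mobility_fits")
}

#' @export
print.mobility_fits <- function(x, ...) {
  cat(sprintf("<mobility_fits> channel %d, %d lags\n", x$channel,
              nrow(x$fits)))
  if (!is.null(x$decay)) print(x$decay)
  invisible(x)
}
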