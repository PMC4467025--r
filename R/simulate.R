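## Ground-truth generators: a 2-D Lennard-Jones molecular-dynamics
## integrator, Brownian/two-state binding dynamics, and the stochastic
## single-molecule observation model (blinking, localization noise,
## spectral bleed-through).

#' Configuration for the 2-D Lennard-Jones simulation
#'
#' Reduced units throughout: particle diameter sigma, well depth epsilon
#' and mass are 1.  The box side follows from the particle count and
#' reduced density, `sqrt(n_atoms / reduced_density)` (about 35.8 sigma at
#' the defaults, i.e. close to 36).
#'
#' @param n_atoms Number of atoms (default 64).
#' @param reduced_density Atoms per unit area (default 0.05).
#' @param dt Integration time step in reduced time (default 0.005).
#' @param n_steps Production steps (default 200000).
#' @param equil_steps Equilibration steps before saving (default 40000).
#' @param save_every Save positions every this many production steps
#'   (default 5; the defaults give 40000 snapshots).
#' @param temperature Target reduced temperature for the initial/equilibrated
#'   velocities (default 1.0).  Production is plain NVE.
#' @param cutoff Interaction cutoff in sigma (default 2.5), with the
#'   potential shifted to zero at the cutoff; must not exceed half the box.
#' @param seed Optional RNG seed.
#' @return An `lj_config` list with `box_side` and `n_snapshots` derived.
#' @export
lj_config <- function(n_atoms = 64, reduced_density = 0.05, dt = 0.005,
                      n_steps = 200000, equil_steps = 40000, save_every = 5,
                      temperature = 1.0, cutoff = 2.5, seed = NULL) {
  box_side <- sqrt(n_atoms / reduced_density)
  if (cutoff > box_side / 2)
    stop("cutoff exceeds half the box side; reduce density or cutoff")
  structure(list(n_atoms = as.integer(n_atoms),
                 reduced_density = reduced_density, dt = dt,
                 n_steps = as.integer(n_steps),
                 equil_steps = as.integer(equil_steps),
                 save_every = as.integer(save_every),
                 temperature = temperature, cutoff = cutoff, seed = seed,
                 box_side = box_side,
                 n_snapshots = as.integer(n_steps / save_every)),
            class = "lj_config")
}

# forces and shifted potential energy of a 2-D L-J configuration
# (minimum-image convention)
.lj_forces <- function(px, py, L, rc2, ushift) {
  dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
  dx <- dx - L * round(dx / L); dy <- dy - L * round(dy / L)
  r2 <- dx * dx + dy * dy
  diag(r2) <- Inf
  ok <- r2 < rc2
  inv2 <- ok / r2
  inv6 <- inv2 * inv2 * inv2
  inv12 <- inv6 * inv6
  fr <- 24 * (2 * inv12 - inv6) * inv2       # F/r
  pe <- sum(4 * (inv12 - inv6) - ushift * ok) / 2
  list(fx = rowSums(fr * dx), fy = rowSums(fr * dy), pe = pe)
}

#' Run the 2-D Lennard-Jones molecular dynamics simulation
#'
#' Atoms start on a square lattice (maximizing spacing), receive Gaussian
#' velocities at the target temperature with zero net momentum, are
#' equilibrated (with periodic velocity rescaling to the target
#' temperature), and then propagated with the velocity-Verlet integrator
#' under periodic boundary conditions with no thermostat.  Positions are
#' saved every `save_every` production steps and the atoms are randomly
#' split into two equal colour groups.
#'
#' @param config An [lj_config()].
#' @return An `lj_sim`: list with `positions` (array snapshots x atoms x 2,
#'   wrapped into the box), `colors` (1/2 per atom), `energy` (data frame
#'   per snapshot: `ke`, `pe`, `e`, `temperature`), `config`.
#' @export
lj_simulate <- function(config) {
  stopifnot(inherits(config, "lj_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_atoms; L <- config$box_side; dt <- config$dt
  rc2 <- config$cutoff^2
  ushift <- 4 * (config$cutoff^-12 - config$cutoff^-6)
  side <- ceiling(sqrt(n))
  g <- (seq_len(n) - 1)
  px <- ((g %% side) + 0.5) * L / side
  py <- ((g %/% side) + 0.5) * L / side
  vx <- stats::rnorm(n); vy <- stats::rnorm(n)
  vx <- vx - mean(vx); vy <- vy - mean(vy)
  rescale <- function() {
    t_now <- 0.5 * sum(vx^2 + vy^2) / (n - 1)
    s <- sqrt(config$temperature / t_now)
    vx <<- vx * s; vy <<- vy * s
  }
  rescale()
  f <- .lj_forces(px, py, L, rc2, ushift)
  step <- function() {
    vx <<- vx + 0.5 * dt * f$fx; vy <<- vy + 0.5 * dt * f$fy
    px <<- (px + dt * vx) %% L; py <<- (py + dt * vy) %% L
    f <<- .lj_forces(px, py, L, rc2, ushift)
    vx <<- vx + 0.5 * dt * f$fx; vy <<- vy + 0.5 * dt * f$fy
  }
  for (i in seq_len(config$equil_steps)) {
    step()
    if (i %% 100 == 0) rescale()
  }
  n_snap <- config$n_snapshots
  pos <- array(NA_real_, c(n_snap, n, 2))
  en <- data.frame(ke = numeric(n_snap), pe = numeric(n_snap))
  k <- 0L
  for (i in seq_len(config$n_steps)) {
    step()
    if (i %% config$save_every == 0) {
      k <- k + 1L
      pos[k, , 1] <- px; pos[k, , 2] <- py
      en$ke[k] <- 0.5 * sum(vx^2 + vy^2)
      en$pe[k] <- f$pe
    }
  }
  en$e <- en$ke + en$pe
  en$temperature <- en$ke / (n - 1)
  colors <- sample(rep(1:2, length.out = n))
  structure(list(positions = pos, colors = colors, energy = en,
                 config = config,
                 momentum = c(sum(vx), sum(vy))),
            class = "lj_sim")
}

#' @export
print.lj_sim <- function(x, ...) {
  cat(sprintf(
    "<lj_sim> %d atoms, box %.4g sigma, %d snapshots; <T*> = %.3f, |dE/E| = %.2g\n",
    x$config$n_atoms, x$config$box_side, dim(x$positions)[1],
    mean(x$energy$temperature),
    abs(diff(range(x$energy$e))) / abs(mean(x$energy$e))))
  invisible(x)
}

#' Brownian / two-state binding dynamics
#'
#' Channel-2 particles diffuse at `d_slow` (immobile by default) and act
#' as binding sites.  Channel-1 particles alternate between a free state
#' diffusing at `d_free` and a bound state co-moving with the captured
#' site, with exponential waiting times: binding at rate `k_on` when
#' within `capture_radius` of a site, unbinding at rate `k_off`.
#' Boundaries reflect.
#'
#' @param n Channel-1 particles.
#' @param n_sites Channel-2 particles (binding sites).
#' @param d_free,d_slow Diffusion coefficients in nm^2/s.
#' @param k_on,k_off Binding/unbinding rates in 1/s.
#' @param frames Number of frames simulated.
#' @param frame_interval Seconds per frame.
#' @param box Box size `c(width, height)` in nm.
#' @param capture_radius Binding capture radius in nm (default 50).
#' @param seed Optional RNG seed.
#' @return A `brownian_sim`: list with `positions` (frames x particles x 2;
#'   channel-1 particles first), `channel`, `bound` (frames x n logical),
#'   `params`, `frame_interval`, `box`.
#' @export
brownian_simulate <- function(n, n_sites = 0, d_free = 2e5, d_slow = 0,
                              k_on = 0, k_off = 0, frames = 1000,
                              frame_interval = 0.03, box = c(2e4, 2e4),
                              capture_radius = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(d_free, d_slow, k_on, k_off) < 0)) stop("rates must be >= 0")
  dt <- frame_interval
  ntot <- n + n_sites
  p <- cbind(stats::runif(ntot, 0, box[1]), stats::runif(ntot, 0, box[2]))
  sd_free <- sqrt(2 * d_free * dt); sd_slow <- sqrt(2 * d_slow * dt)
  p_bind <- 1 - exp(-k_on * dt); p_unbind <- 1 - exp(-k_off * dt)
  reflect <- function(z, lim) {
    z <- z %% (2 * lim)
    ifelse(z > lim, 2 * lim - z, z)
  }
  pos <- array(NA_real_, c(frames, ntot, 2))
  bound <- matrix(FALSE, frames, max(n, 1L))
  site_of <- integer(n)          # 0 = free, else site index (1..n_sites)
  for (f in seq_len(frames)) {
    pos[f, , 1] <- p[, 1]; pos[f, , 2] <- p[, 2]
    if (n > 0) bound[f, seq_len(n)] <- site_of > 0
    if (f == frames) break
    # move sites
    if (n_sites > 0) {
      si <- n + seq_len(n_sites)
      p[si, 1] <- reflect(p[si, 1] + stats::rnorm(n_sites, 0, sd_slow), box[1])
      p[si, 2] <- reflect(p[si, 2] + stats::rnorm(n_sites, 0, sd_slow), box[2])
    }
    if (n > 0) {
      free <- which(site_of == 0L)
      bnd <- which(site_of > 0L)
      p[free, 1] <- reflect(p[free, 1] + stats::rnorm(length(free), 0, sd_free),
                            box[1])
      p[free, 2] <- reflect(p[free, 2] + stats::rnorm(length(free), 0, sd_free),
                            box[2])
      if (length(bnd))  # co-move with the captured site
        p[bnd, ] <- p[n + site_of[bnd], , drop = FALSE]
      # state switches
      if (length(bnd) && p_unbind > 0) {
        rel <- bnd[stats::runif(length(bnd)) < p_unbind]
        site_of[rel] <- 0L
      }
      if (length(free) && p_bind > 0 && n_sites > 0) {
        try_bind <- free[stats::runif(length(free)) < p_bind]
        if (length(try_bind)) {
          sx <- p[n + seq_len(n_sites), 1]; sy <- p[n + seq_len(n_sites), 2]
          for (i in try_bind) {
            d2 <- (sx - p[i, 1])^2 + (sy - p[i, 2])^2
            jmin <- which.min(d2)
            if (d2[jmin] <= capture_radius^2) {
              site_of[i] <- jmin
              p[i, ] <- c(sx[jmin], sy[jmin])
            }
          }
        }
      }
    }
  }
  structure(list(positions = pos,
                 channel = c(rep(1L, n), rep(2L, n_sites)),
                 bound = bound[, seq_len(max(n, 1L)), drop = FALSE],
                 params = list(n = n, n_sites = n_sites, d_free = d_free,
                               d_slow = d_slow, k_on = k_on, k_off = k_off,
                               capture_radius = capture_radius),
                 frame_interval = frame_interval, box = box),
            class = "brownian_sim")
}

#' @export
print.brownian_sim <- function(x, ...) {
  cat(sprintf("<brownian_sim> %d + %d particles, %d frames @ %g s; bound fraction %.3f\n",
              x$params$n, x$params$n_sites, dim(x$positions)[1],
              x$frame_interval,
              if (x$params$n > 0) mean(x$bound) else NA))
  invisible(x)
}

#' Stochastic blinking observation model
#'
#' @param p_on Per-frame probability that a particle is on (detected).
#' @param loc_noise Localization precision in nm (Gaussian s.d. per axis).
#' @param bleed_prob Probability that a channel-1 emission is additionally
#'   localized in channel 2 (spectral bleed-through): the spurious record
#'   is simultaneous and position-correlated.
#' @param bleed_noise Extra jitter of the bleed-through record in nm
#'   (defaults to `loc_noise`).
#' @param seed Optional RNG seed.
#' @return A `blink_model` list.
#' @export
blink_model <- function(p_on = 1, loc_noise = 0, bleed_prob = 0,
                        bleed_noise = loc_noise, seed = NULL) {
  stopifnot(p_on >= 0, p_on <= 1, bleed_prob >= 0, bleed_prob <= 1)
  structure(list(p_on = p_on, loc_noise = loc_noise,
                 bleed_prob = bleed_prob, bleed_noise = bleed_noise,
                 seed = seed), class = "blink_model")
}

# normalize a ground-truth object to (positions array, channel, dt)
.truth_frames <- function(truth, scale = 1, frame_interval = NULL) {
  if (inherits(truth, "lj_sim")) {
    list(pos = truth$positions * scale, channel = truth$colors,
         dt = if (is.null(frame_interval)) 0.03 else frame_interval)
  } else if (inherits(truth, "brownian_sim")) {
    list(pos = truth$positions * scale, channel = truth$channel,
         dt = if (is.null(frame_interval)) truth$frame_interval else
           frame_interval)
  } else if (is.list(truth) && !is.null(truth$positions)) {
    list(pos = truth$positions * scale, channel = truth$channel,
         dt = if (is.null(frame_interval)) truth$frame_interval else
           frame_interval)
  } else stop("unsupported ground-truth object")
}

#' Apply the single-molecule observation model to ground-truth dynamics
#'
#' Each particle is localized independently in each frame with probability
#' `p_on`, its position jittered by the localization noise; channel-1
#' localizations additionally spawn a simultaneous channel-2 record with
#' probability `bleed_prob` (bleed-through).  The result is a standard
#' localization table.
#'
#' @param truth An [lj_simulate()] or [brownian_simulate()] result, or a
#'   list with `positions` (frames x particles x 2), `channel`,
#'   `frame_interval`.
#' @param model A [blink_model()].
#' @param scale Length units per ground-truth unit (use e.g. nm per sigma
#'   for Lennard-Jones output; default 1).
#' @param frame_interval Override seconds per frame.
#' @return A [loc_table()].
#' @export
observe_smlm <- function(truth, model, scale = 1, frame_interval = NULL) {
  stopifnot(inherits(model, "blink_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  tf <- .truth_frames(truth, scale = scale, frame_interval = frame_interval)
  nf <- dim(tf$pos)[1]; np <- dim(tf$pos)[2]
  on <- matrix(stats::runif(nf * np) < model$p_on, nf, np)
  idx <- which(on, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(loc_table(numeric(), numeric(), integer(), integer(),
                     frame_interval = tf$dt))
  m <- nrow(idx)
  x <- tf$pos[cbind(idx[, 1], idx[, 2], 1L)] +
    stats::rnorm(m, 0, model$loc_noise)
  y <- tf$pos[cbind(idx[, 1], idx[, 2], 2L)] +
    stats::rnorm(m, 0, model$loc_noise)
  fr <- idx[, 1] - 1L
  ch <- tf$channel[idx[, 2]]
  if (model$bleed_prob > 0) {
    cand <- which(ch == 1L)
    bl <- cand[stats::runif(length(cand)) < model$bleed_prob]
    if (length(bl)) {
      x <- c(x, x[bl] + stats::rnorm(length(bl), 0, model$bleed_noise))
      y <- c(y, y[bl] + stats::rnorm(length(bl), 0, model$bleed_noise))
      fr <- c(fr, fr[bl])
      ch <- c(ch, rep(2L, length(bl)))
    }
  }
  o <- order(fr)
  loc_table(x[o], y[o], fr[o], ch[o], frame_interval = tf$dt)
}
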