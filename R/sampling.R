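## Synthetic-data engine standing in for explicit-solvent MD: analytic
## free-energy landscapes with the qualitative shape of the tubulin bending
## profile, an overdamped-Langevin umbrella sampler in CV space, umbrella
## window layouts, and synthetic dimer structures with prescribed rotations.

#' Thermal energy at 300 K, kcal/mol
#' @export
KT_DEFAULT <- 0.596

## ---- analytic landscapes ----------------------------------------------

.gauss <- function(x, mu, sigma) {
  exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
}
.dgauss <- function(x, mu, sigma) {
  -(x - mu) / sigma^2 * .gauss(x, mu, sigma)
}

#' Construct an analytic toy free-energy landscape
#'
#' Returns a callable potential (kcal/mol) with analytic gradient and known
#' bounds, suitable for umbrella sampling and for exact quadrature oracles.
#'
#' Kinds:
#' \describe{
#'   \item{`harmonic`}{`U = 0.5 * k * (x - x0)^2`; params `k`, `x0`.}
#'   \item{`flat`}{`U = 0` on `bounds`.}
#'   \item{`double_well`}{`U = h * ((x/a)^2 - 1)^2 + tilt * x`; params `a`,
#'     `h`, `tilt`.}
#'   \item{`tubulin_like`}{a 1D profile in the intradimer rotation angle
#'     theta (degrees): a narrow "straight" well (default centre 1.5
#'     degrees, sd 0.6), a broad "bent" well (centre 7, sd 2.5) spanning
#'     roughly 4-13 degrees, separated by a barrier (default 2 kcal/mol)
#'     near 3.5 degrees.  The well weights are solved numerically so that
#'     the free-energy difference between the bent and straight basins
#'     (split at `split` = 3.5 degrees, at temperature `kT`) equals
#'     `delta_g` exactly, with the bent basin lower for `delta_g > 0`.}
#' }
#'
#' With `dimensions = 2` the landscape becomes `U(x) + 0.5 * k_z * y^2`,
#' emulating a harmonic confinement transverse to the path.
#'
#' @param shape landscape family (the "kind" of potential).
#' @param ... shape-specific parameters (see Details).
#' @param dimensions 1 or 2.
#' @param k_z transverse force constant for `dimensions = 2`.
#' @return a `toy_potential`: list with `U`, `grad` (functions of `x` or
#'   `(x, y)`), `dim`, `bounds` (dim x 2 matrix), `params`, `kT_ref`.
#' @examples
#' pot <- make_toy_landscape("harmonic", k = 1, x0 = 0)
#' pot$U(2)     # 2 kcal/mol
#' @export
make_toy_landscape <- function(shape = c("double_well", "tubulin_like",
                                         "harmonic", "flat"), ...,
                               dimensions = 1L, k_z = 10) {
  kind <- match.arg(shape)
  dots <- list(...)
  prm <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  base <- switch(kind,
    harmonic = {
      k <- prm("k", 1); x0 <- prm("x0", 0)
      stopifnot(k > 0)
      list(U = function(x) 0.5 * k * (x - x0)^2,
           grad = function(x) k * (x - x0),
           bounds = c(x0 - 10, x0 + 10),
           params = list(k = k, x0 = x0))
    },
    flat = {
      b <- prm("bounds", c(0, 1))
      list(U = function(x) rep(0, length(x)),
           grad = function(x) rep(0, length(x)),
           bounds = b, params = list())
    },
    double_well = {
      a <- prm("a", 1); h <- prm("h", 2); tilt <- prm("tilt", 0)
      stopifnot(a > 0, h > 0)
      list(U = function(x) h * ((x / a)^2 - 1)^2 + tilt * x,
           grad = function(x) 4 * h * x * ((x / a)^2 - 1) / a^2 + tilt,
           bounds = c(-2.5 * a, 2.5 * a),
           params = list(a = a, h = h, tilt = tilt))
    },
    tubulin_like = .tubulin_like_landscape(
      delta_g = prm("delta_g", 1.0),
      theta_straight = prm("theta_straight", 1.5),
      sigma_straight = prm("sigma_straight", 0.6),
      theta_bent = prm("theta_bent", 7.0),
      sigma_bent = prm("sigma_bent", 2.5),
      barrier = prm("barrier", 2.0),
      split = prm("split", 3.5),
      kT = prm("kT", KT_DEFAULT),
      bounds = prm("bounds", c(-2, 15))))

  if (dimensions == 1L) {
    pot <- c(base, list(dim = 1L, kind = kind, kT_ref = KT_DEFAULT))
    pot$bounds <- matrix(base$bounds, 1L, 2L, byrow = TRUE)
  } else if (dimensions == 2L) {
    stopifnot(k_z > 0)
    u1 <- base$U; g1 <- base$grad
    zmax <- 6 * sqrt(KT_DEFAULT / k_z)
    pot <- list(U = function(x, y) u1(x) + 0.5 * k_z * y^2,
                grad = function(x, y) cbind(g1(x), k_z * y),
                bounds = rbind(base$bounds, c(-zmax, zmax)),
                params = c(base$params, list(k_z = k_z)),
                dim = 2L, kind = kind, kT_ref = KT_DEFAULT)
  } else stop("dimensions must be 1 or 2")
  class(pot) <- "toy_potential"
  pot
}

## Two Gaussian wells in energy space on a common baseline (the barrier
## level): U(x) = -A_s g_s(x) - A_b g_b(x) with unit-height Gaussian bumps
## g.  The bent-well depth A_b is solved so that the bent/straight basin
## free-energy gap (split at `split`, temperature kT) equals delta_g
## exactly, and the straight-well depth A_s so that the highest point of U
## between the two well centres sits `barrier` kcal/mol above the straight
## minimum.  The two one-dimensional root solves are alternated to joint
## convergence.
.tubulin_like_landscape <- function(delta_g, theta_straight, sigma_straight,
                                    theta_bent, sigma_bent, barrier, split,
                                    kT, bounds) {
  stopifnot(sigma_straight > 0, sigma_bent > 0, barrier > 0,
            bounds[1] < theta_straight, theta_straight < split,
            split < theta_bent, theta_bent < bounds[2])
  bump <- function(x, mu, sigma) exp(-0.5 * ((x - mu) / sigma)^2)
  u_of <- function(x, a_s, a_b)
    -a_s * bump(x, theta_straight, sigma_straight) -
    a_b * bump(x, theta_bent, sigma_bent)
  ratio <- function(a_s, a_b) {
    lo <- stats::integrate(function(x) exp(-u_of(x, a_s, a_b) / kT),
                           bounds[1], split, rel.tol = 1e-10)$value
    hi <- stats::integrate(function(x) exp(-u_of(x, a_s, a_b) / kT),
                           split, bounds[2], rel.tol = 1e-10)$value
    hi / lo
  }
  xg <- seq(theta_straight, theta_bent, length.out = 4001)
  xs <- seq(bounds[1], split, length.out = 2001)
  barfun <- function(a_s, a_b) {
    u <- u_of(xg, a_s, a_b)
    max(u) - min(u_of(xs, a_s, a_b))
  }
  target <- exp(delta_g / kT)
  a_s <- barrier; a_b <- barrier
  for (it in 1:8) {
    a_b <- stats::uniroot(function(a) ratio(a_s, a) - target,
                          c(1e-6, 60), tol = 1e-12)$root
    a_s <- stats::uniroot(function(a) barfun(a, a_b) - barrier,
                          c(1e-3, 60), tol = 1e-12)$root
  }
  u_fun <- function(x) u_of(x, a_s, a_b)
  g_fun <- function(x)
    a_s * (x - theta_straight) / sigma_straight^2 *
      bump(x, theta_straight, sigma_straight) +
    a_b * (x - theta_bent) / sigma_bent^2 * bump(x, theta_bent, sigma_bent)
  list(U = u_fun, grad = g_fun, bounds = bounds,
       params = list(delta_g = delta_g, theta_straight = theta_straight,
                     sigma_straight = sigma_straight,
                     theta_bent = theta_bent, sigma_bent = sigma_bent,
                     barrier = barrier, split = split, kT = kT,
                     depth_straight = a_s, depth_bent = a_b))
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("toy_potential '%s' (%dD), bounds %s\n", x$kind, x$dim,
              paste(apply(x$bounds, 1, function(b)
                sprintf("[%.3g, %.3g]", b[1], b[2])), collapse = " x ")))
  invisible(x)
}

#' Boltzmann weight of an interval by quadrature
#'
#' `integral exp(-U/kT) dx` over `[lower, upper]` for a 1D potential; the
#' exact-oracle counterpart of histogram populations.
#'
#' @param potential a 1D `toy_potential`.
#' @param lower,upper integration limits (default: the potential bounds).
#' @param kT thermal energy, kcal/mol.
#' @return numeric weight.
#' @export
basin_weight <- function(potential, lower = potential$bounds[1, 1],
                         upper = potential$bounds[1, 2], kT = KT_DEFAULT) {
  stopifnot(inherits(potential, "toy_potential"), potential$dim == 1L)
  stats::integrate(function(x) exp(-potential$U(x) / kT), lower, upper,
                   rel.tol = 1e-10)$value
}

## ---- umbrella windows -------------------------------------------------

#' Equidistant umbrella-window layout
#'
#' @param range length-2 numeric, `[s_min, s_max]`.
#' @param count number of windows (>= 2); centres span the range inclusive.
#' @param k_s force constant along s (kcal/mol per squared CV unit),
#'   default 10.
#' @param k_z,z_center transverse restraint (2D sampling only).
#' @return data.frame with one row per window: `center_s`, `k_s`,
#'   `center_z`, `k_z`.
#' @examples
#' generate_window_set(c(1, 15), 15)
#' @export
generate_window_set <- function(range, count, k_s = 10, k_z = 0,
                                z_center = 0) {
  stopifnot(length(range) == 2L, count >= 2L, k_s >= 0, k_z >= 0)
  if (!(range[2] > range[1])) stop("degenerate range")
  data.frame(center_s = seq(range[1], range[2], length.out = count),
             k_s = k_s, center_z = z_center, k_z = k_z)
}

#' Overdamped-Langevin umbrella sampling of a toy landscape
#'
#' Euler-Maruyama integration of `dx = -grad(U_total)/friction dt +
#' sqrt(2 kT dt / friction) dW` with `U_total = U + 0.5 k_s (x - s0)^2`
#' (plus `0.5 k_z (y - z0)^2` in 2D), run simultaneously for all windows.
#' The first `discard_frac` of recorded steps (equilibration) is dropped.
#' Deterministic for a fixed seed.
#'
#' @param potential a `toy_potential`.
#' @param windows data.frame from [generate_window_set()] (or one row).
#' @param n_steps integration steps per window.
#' @param dt time step (reduced units).
#' @param friction friction coefficient.
#' @param kT thermal energy, kcal/mol.
#' @param seed integer RNG seed.
#' @param discard_frac fraction of initial steps dropped as equilibration.
#' @param stride record every `stride`-th step.
#' @return an `umbrella_run`: list with `samples` (matrix, retained steps x
#'   windows), `samples_z` (2D only), `windows`, `kT`, `n_steps`, `seed`.
#' @export
sample_umbrella <- function(potential, windows, n_steps = 20000L, dt = 0.005,
                            friction = 1, kT = KT_DEFAULT, seed = 1L,
                            discard_frac = 0.25, stride = 1L) {
  stopifnot(inherits(potential, "toy_potential"), dt > 0, friction > 0,
            kT > 0, n_steps >= 10L, discard_frac >= 0, discard_frac < 1)
  w <- as.data.frame(windows)
  nw <- nrow(w)
  two_d <- potential$dim == 2L
  set.seed(seed)
  x <- w$center_s
  y <- if (two_d) {
    if (is.null(w$center_z)) rep(0, nw) else w$center_z
  } else NULL
  lo <- potential$bounds[1, 1]; hi <- potential$bounds[1, 2]
  mid <- (lo + hi) / 2; halfspan <- (hi - lo) / 2
  n_rec <- n_steps %/% stride
  xs <- matrix(NA_real_, n_rec, nw)
  ys <- if (two_d) matrix(NA_real_, n_rec, nw) else NULL
  noise <- sqrt(2 * kT * dt / friction)
  r <- 0L
  for (step in seq_len(n_steps)) {
    if (two_d) {
      g <- potential$grad(x, y)
      fx <- g[, 1L] + w$k_s * (x - w$center_s)
      fy <- g[, 2L] + w$k_z * (y - w$center_z)
      x <- x - fx * dt / friction + noise * stats::rnorm(nw)
      y <- y - fy * dt / friction + noise * stats::rnorm(nw)
    } else {
      fx <- potential$grad(x) + w$k_s * (x - w$center_s)
      x <- x - fx * dt / friction + noise * stats::rnorm(nw)
    }
    if (any(abs(x - mid) > 10 * halfspan))
      stop("trajectory diverged (left the potential bounds by 10x); ",
           "try a smaller dt")
    if (step %% stride == 0L) {
      r <- r + 1L
      xs[r, ] <- x
      if (two_d) ys[r, ] <- y
    }
  }
  keep <- seq.int(floor(n_rec * discard_frac) + 1L, n_rec)
  structure(list(samples = xs[keep, , drop = FALSE],
                 samples_z = if (two_d) ys[keep, , drop = FALSE],
                 windows = w, kT = kT, n_steps = n_steps, dt = dt,
                 friction = friction, seed = seed,
                 discard_frac = discard_frac),
            class = "umbrella_run")
}

#' @export
print.umbrella_run <- function(x, ...) {
  cat(sprintf("umbrella_run: %d windows x %d retained samples (kT = %.3g)\n",
              ncol(x$samples), nrow(x$samples), x$kT))
  invisible(x)
}

## ---- synthetic dimer structures ---------------------------------------

## ideal-helix backbone: deterministic parametric alpha-helix along +x
.helix_atoms <- function(resno, x0, y0, z0, chain, resid = "ALA") {
  offs <- list(N  = c(1.60, -30, -0.60),
               CA = c(2.30,   0,  0.00),
               C  = c(1.70,  30,  0.60),
               O  = c(2.10,  47,  1.00),
               CB = c(3.30, -40,  0.20))
  rows <- lapply(seq_along(resno), function(i) {
    a0 <- (i - 1) * 100 * pi / 180
    x <- x0 + (i - 1) * 1.5
    do.call(rbind, lapply(names(offs), function(nm) {
      o <- offs[[nm]]
      ang <- a0 + o[2] * pi / 180
      data.frame(elety = nm,
                 elesy = substr(nm, 1, 1),
                 resid = resid, resno = resno[i],
                 chain = chain,
                 x = x + o[3], y = y0 + o[1] * cos(ang),
                 z = z0 + o[1] * sin(ang))
    }))
  })
  do.call(rbind, rows)
}

## symmetric jittered blob of CA atoms whose mean is exactly `center`
.blob_atoms <- function(resno, center, chain, n_pairs = 7L, sd = 2.5) {
  d <- matrix(stats::rnorm(3 * n_pairs, sd = sd), n_pairs, 3)
  xyz <- sweep(rbind(d, -d), 2L, center, "+")
  k <- nrow(xyz)
  data.frame(elety = "CA", elesy = "C", resid = "GLY",
             resno = rep(resno, length.out = k), chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Synthetic dimer pair with a prescribed intersubunit rotation
#'
#' Builds an idealised "straight" two-chain structure (chain A = alpha,
#' chain B = beta) and a "bent" copy in which every beta-subunit atom is
#' rigidly rotated by `intersubunit_angle` about the x axis through the
#' origin (the interface axis, parallel to both H7 helices and lying in
#' their common plane).  Each subunit carries an H7 helix (full backbone
#' plus CB) and three CA-blob domains whose mass centers are stacked along
#' z, so that the same rotation is recovered both by the H7-plane
#' intradimer metric and by the domain-center bending angle.
#'
#' @param intersubunit_angle rotation in degrees, in `[0, 90]`.
#' @param helix_length residues per H7 helix (default 23).
#' @param seed RNG seed for the (symmetrised) domain-blob jitter.
#' @return list with `straight`, `bent` (`structure_model`),
#'   `straight_dimer`, `bent_dimer` (`tubulin_dimer`), `axis`, `angle`,
#'   `domains`.
#' @export
make_synthetic_dimer <- function(intersubunit_angle, helix_length = 23L,
                                 seed = 1L) {
  if (intersubunit_angle < 0 || intersubunit_angle > 90)
    stop("intersubunit_angle must be in [0, 90] degrees")
  stopifnot(helix_length >= 5L)
  set.seed(seed)
  h7 <- 60L:(60L + helix_length - 1L)
  span <- 1.5 * (helix_length - 1)
  build_subunit <- function(chain, x_sign, y0) {
    x_start <- if (x_sign < 0) -2 - span else 2
    rbind(
      .blob_atoms(1:15, c(x_sign * 18, y0, -14), chain),
      .blob_atoms(20:34, c(x_sign * 18, y0, 0), chain),
      .blob_atoms(40:54, c(x_sign * 18, y0, 14), chain),
      .helix_atoms(h7, x_start, y0, 0, chain))
  }
  at <- rbind(build_subunit("A", -1, 0), build_subunit("B", +1, 8))
  straight <- structure_model(at, identifier = "synthetic_straight")
  r <- rotation_about_axis(c(1, 0, 0), intersubunit_angle)
  at_b <- at
  bsel <- at_b$chain == "B"
  at_b[bsel, c("x", "y", "z")] <-
    as.matrix(at_b[bsel, c("x", "y", "z")]) %*% r
  bent <- structure_model(at_b, identifier = "synthetic_bent")
  dom <- domain_config(n_terminal = c(1L, 15L), intermediate = c(20L, 34L),
                       c_terminal = c(40L, 54L),
                       h7_alpha = range(h7), h7_beta = range(h7))
  cm <- list(alpha = "A", beta = "B")
  list(straight = straight, bent = bent,
       straight_dimer = annotate_dimer(straight, cm, dom, quiet = TRUE),
       bent_dimer = annotate_dimer(bent, cm, dom, quiet = TRUE),
       axis = c(1, 0, 0), angle = intersubunit_angle, domains = dom)
}
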