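## Thermodynamic post-processing of PMF profiles: basin populations, free
## energy differences between regions, extrema/barriers, and the mapping
## from path progress s to intradimer rotation angle.

## bin edges for a profile, inferred from centres when not stored
.profile_edges <- function(profile) {
  if (!is.null(profile$edges)) return(profile$edges)
  x <- profile$xi
  mid <- (x[-1L] + x[-length(x)]) / 2
  c(2 * x[1L] - mid[1L], mid, 2 * x[length(x)] - mid[length(mid)])
}

## Boltzmann weight of [lo, hi]: per-bin weights exp(-W/kT) times the
## fraction of each bin inside the interval.  Exact partition: weights over
## a partition of the support sum to the total.
.interval_weight <- function(profile, lo, hi, kT) {
  edges <- .profile_edges(profile)
  wdt <- diff(edges)
  cover <- pmax(0, pmin(edges[-1L], hi) - pmax(edges[-length(edges)], lo))
  w <- exp(-profile$W / kT)
  w[!is.finite(profile$W)] <- 0
  sum(w * cover)
}

#' Basin population from a PMF profile
#'
#' Fraction of the Boltzmann population inside a reaction-coordinate
#' interval: `integral_basin exp(-W/kT) / integral_support exp(-W/kT)`,
#' evaluated on the profile's bin grid (bins straddling a basin edge
#' contribute fractionally, so populations over a partition sum to one).
#' Bins with infinite `W` carry zero weight.
#'
#' @param profile a `pmf_profile`.
#' @param basin length-2 numeric interval on the xi axis.
#' @param kT thermal energy (defaults to the profile's).
#' @return population fraction in `[0, 1]`.
#' @examples
#' \dontrun{basin_population(pmf, c(-2, 3.5))}
#' @export
basin_population <- function(profile, basin, kT = NULL) {
  stopifnot(inherits(profile, "pmf_profile"), length(basin) == 2L,
            basin[1L] < basin[2L])
  kT <- if (!is.null(kT)) kT else profile$kT
  num <- .interval_weight(profile, basin[1L], basin[2L], kT)
  den <- .interval_weight(profile, -Inf, Inf, kT)
  if (num <= 0) stop("basin does not overlap the profile support")
  num / den
}

#' Free energy difference between two basins
#'
#' `delta G = -kT ln(pop_a / pop_b)`; negative when basin a is the more
#' populated (lower free energy).  Antisymmetric under swapping the
#' arguments, and invariant to the profile gauge.
#'
#' @param profile a `pmf_profile`.
#' @param basin_a,basin_b length-2 intervals.
#' @param kT thermal energy (defaults to the profile's).
#' @return free energy difference in kcal/mol.
#' @export
delta_g <- function(profile, basin_a, basin_b, kT = NULL) {
  kT <- if (!is.null(kT)) kT else profile$kT
  pa <- basin_population(profile, basin_a, kT)
  pb <- basin_population(profile, basin_b, kT)
  -kT * log(pa / pb)
}

#' Locate minima, maxima and the barrier of a profile
#'
#' Finds interior local extrema of `W(xi)` after optional moving-average
#' smoothing.  When at least two minima exist, the highest point between
#' the two deepest minima is additionally labelled `"barrier"`.  Monotone
#' or flat profiles yield no interior extrema (endpoints are not reported
#' as extrema).
#'
#' @param profile a `pmf_profile`.
#' @param smoothing odd moving-average window in bins (0 or 1 = none).
#' @return data.frame with columns `type` (`"min"`, `"max"`, `"barrier"`),
#'   `xi`, `W`.
#' @export
locate_extrema <- function(profile, smoothing = 0L) {
  stopifnot(inherits(profile, "pmf_profile"))
  fin <- is.finite(profile$W)
  x <- profile$xi[fin]
  w <- profile$W[fin]
  if (length(w) < 3L) stop("need at least 3 finite bins")
  if (smoothing > 1L) {
    k <- as.integer(smoothing)
    if (k %% 2L == 0L) k <- k + 1L
    w <- stats::filter(w, rep(1 / k, k), sides = 2L)
    keep <- !is.na(w)
    x <- x[keep]; w <- as.numeric(w[keep])
  }
  n <- length(w)
  d <- diff(w)
  out <- data.frame(type = character(), xi = numeric(), W = numeric())
  for (i in 2:(n - 1L)) {
    left <- d[i - 1L]; right <- d[i]
    if (left < 0 && right > 0)
      out <- rbind(out, data.frame(type = "min", xi = x[i], W = w[i]))
    else if (left > 0 && right < 0)
      out <- rbind(out, data.frame(type = "max", xi = x[i], W = w[i]))
  }
  mins <- out[out$type == "min", ]
  if (nrow(mins) >= 2L) {
    deepest <- mins[order(mins$W), ][1:2, ]
    lo <- min(deepest$xi); hi <- max(deepest$xi)
    seg <- which(x > lo & x < hi)
    if (length(seg)) {
      i_bar <- seg[which.max(w[seg])]
      out <- rbind(out, data.frame(type = "barrier", xi = x[i_bar],
                                   W = w[i_bar]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Map path progress s to intradimer rotation angle
#'
#' Computes the intradimer rotation of every path frame with respect to a
#' straight reference (by default the first frame), yielding the
#' s-to-angle table that turns a PMF over s into a PMF over intradimer
#' curvature.
#'
#' @param path a `reference_path` whose frames can be annotated as dimers.
#' @param chain_map,domains passed to [annotate_dimer()]; defaults cover
#'   the synthetic dimers from [make_synthetic_dimer()].
#' @param straight_ref optional `tubulin_dimer` used as the straight
#'   reference; default: frame 1 of the path.
#' @return an `s_angle_map`: data.frame with `s` (frame index) and `angle`
#'   (degrees); use [angle_at_s()] for interpolated lookup.
#' @export
map_s_to_angle <- function(path, chain_map = list(alpha = "A", beta = "B"),
                           domains = domain_config(), straight_ref = NULL) {
  stopifnot(inherits(path, "reference_path"))
  p <- length(path$frames)
  dimers <- lapply(seq_len(p), function(k)
    annotate_dimer(path_frame_structure(path, k), chain_map, domains,
                   quiet = TRUE))
  ref <- if (!is.null(straight_ref)) straight_ref else dimers[[1L]]
  ang <- vapply(dimers, function(d) intradimer_angle(d, ref)$mean,
                numeric(1))
  if (any(diff(ang) < -1e-6))
    warning("frame-wise angles are not monotone along the path")
  structure(data.frame(s = seq_len(p), angle = ang),
            class = c("s_angle_map", "data.frame"))
}

#' Interpolated angle lookup on an s-to-angle map
#' @param map an `s_angle_map`.
#' @param s path-progress values in `[1, P]`.
#' @return angles in degrees (linear interpolation between frames).
#' @export
angle_at_s <- function(map, s) {
  stats::approx(map$s, map$angle, xout = s, rule = 2L)$y
}
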