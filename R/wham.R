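## Weighted histogram analysis method: 1D and 2D unbiasing of umbrella
## trajectories, projection of a 2D surface onto the path at z = 0, and
## bootstrap uncertainty with profile alignment at xi = 0.

## ---- core self-consistent iteration -----------------------------------

## counts: bins x windows matrix; bias: bins x windows bias energies
## (kcal/mol).  Iterates
##   p_j  propto  sum_i h_ij / sum_i N_i exp((f_i - w_ij)/kT)
##   f_i = -kT ln sum_j p_j exp(-w_ij/kT)
## until max |delta f| < tol.  Returns p (normalised), f, iterations,
## final increment.
.wham_core <- function(counts, bias, kT, tol, max_iter, f_init = NULL) {
  h <- rowSums(counts)
  n_i <- colSums(counts)
  b <- exp(-bias / kT)
  f <- if (is.null(f_init)) numeric(ncol(counts)) else f_init
  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(b %*% (n_i * exp(f / kT)))
    p <- ifelse(denom > 0, h / denom, 0)
    s <- sum(p)
    if (s <= 0) stop("WHAM produced an empty distribution")
    p <- p / s
    f_new <- -kT * log(as.vector(crossprod(b, p)))
    f_new <- f_new - f_new[1L]           # gauge: f_1 = 0
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
  list(p = p, f = f, iterations = it, final_tol = delta)
}

## adjacent-window support connectivity (1D); errors when the sampled
## supports form disconnected segments
.check_overlap <- function(counts, centers) {
  if (ncol(counts) < 2L) return(invisible(TRUE))
  ord <- order(centers)
  for (k in seq_len(length(ord) - 1L)) {
    a <- counts[, ord[k]] > 0
    b <- counts[, ord[k + 1L]] > 0
    if (!any(a & b)) {
      warning("umbrella windows ", ord[k], " and ", ord[k + 1L],
              " share no occupied bins", call. = FALSE)
      stop("disconnected umbrella-window segments; add windows or samples",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.bin_centers <- function(edges) (edges[-1L] + edges[-length(edges)]) / 2

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin.max <- pmax(1L, pmin(i, length(edges) - 1L))
  pmin.max
}

## ---- PMF profile container --------------------------------------------

#' @keywords internal
pmf_profile <- function(xi, w, sigma = NULL, kT = KT_DEFAULT,
                        iterations = NA_integer_, final_tol = NA_real_,
                        f = NULL, edges = NULL) {
  finite <- is.finite(w)
  if (!any(finite)) stop("profile has no finite bins")
  w <- w - min(w[finite])                 # gauge: global minimum at 0
  structure(list(xi = xi, W = w, sigma = sigma, kT = kT,
                 iterations = iterations, final_tol = final_tol, f = f,
                 edges = edges),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$W)
  cat(sprintf(paste0("pmf_profile: %d bins on [%.3g, %.3g], max W %.3g ",
                     "kcal/mol%s\n"),
              length(x$xi), min(x$xi), max(x$xi), max(x$W[fin]),
              if (!is.null(x$sigma)) sprintf(", bootstrap sigma attached")
              else ""))
  if (!is.na(x$iterations))
    cat(sprintf("  converged in %d iterations (residual %.3g)\n",
                x$iterations, x$final_tol))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  d <- data.frame(xi = x$xi, W = x$W)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

## accept an umbrella_run or a bare list(samples, windows, kT)
.run_parts <- function(run, kT) {
  stopifnot(!is.null(run$samples), !is.null(run$windows))
  list(samples = as.matrix(run$samples),
       samples_z = if (!is.null(run$samples_z)) as.matrix(run$samples_z),
       windows = as.data.frame(run$windows),
       kT = if (!is.null(kT)) kT else if (!is.null(run$kT)) run$kT
       else KT_DEFAULT)
}

## ---- 1D WHAM ----------------------------------------------------------

#' One-dimensional WHAM
#'
#' Unbiases a set of umbrella trajectories along a single collective
#' variable into a free-energy profile `W(xi) = -kT ln p(xi)`, gauge-fixed
#' to zero at the global minimum.  Bin centres span the sampled range
#' inclusive; bins never visited get `W = +Inf`.
#'
#' @param run an `umbrella_run` (or any list with `samples` matrix,
#'   `windows` data.frame with `center_s`/`k_s`, optional `kT`).
#' @param n_bins histogram resolution (default 1000).
#' @param tol convergence tolerance on the per-window free-energy constants
#'   f_i, kcal/mol (default 1e-6).
#' @param max_iter iteration cap.
#' @param kT thermal energy; defaults to the run's.
#' @param range optional length-2 histogram range (default: sampled range).
#' @return a `pmf_profile`.
#' @export
wham_1d <- function(run, n_bins = 1000L, tol = 1e-6, max_iter = 200000L,
                    kT = NULL, range = NULL) {
  rp <- .run_parts(run, kT)
  if (is.null(range)) range <- base::range(rp$samples)
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  centers <- .bin_centers(edges)
  counts <- apply(rp$samples, 2L, function(x)
    tabulate(.bin_index(x, edges), nbins = n_bins))
  .check_overlap(counts, rp$windows$center_s)
  bias <- outer(centers, seq_len(nrow(rp$windows)), function(xi, i)
    0.5 * rp$windows$k_s[i] * (xi - rp$windows$center_s[i])^2)
  sol <- .wham_core(counts, bias, rp$kT, tol, max_iter)
  pmf_profile(centers, -rp$kT * log(sol$p), kT = rp$kT,
              iterations = sol$iterations, final_tol = sol$final_tol,
              f = sol$f, edges = edges)
}

## ---- 2D WHAM ----------------------------------------------------------

#' Two-dimensional WHAM over (s, z)
#'
#' As [wham_1d()] but on a 2D bin grid with biases
#' `w_i(s, z) = 0.5 k_s (s - s_i)^2 + 0.5 k_z (z - z_i)^2`.
#'
#' @param run an `umbrella_run` with `samples` and `samples_z`.
#' @param n_bins length-2 integer (s bins, z bins), or one integer for
#'   both.
#' @param tol convergence tolerance on f_i, kcal/mol (default 0.001).
#' @param max_iter iteration cap.
#' @param kT thermal energy.
#' @param range_s,range_z optional histogram ranges.
#' @return a `pmf_surface`: list with `s`, `z` (bin centres) and `W`
#'   (matrix, s by z), plus convergence metadata.
#' @export
wham_2d <- function(run, n_bins = c(200L, 60L), tol = 1e-3,
                    max_iter = 200000L, kT = NULL, range_s = NULL,
                    range_z = NULL) {
  rp <- .run_parts(run, kT)
  if (is.null(rp$samples_z)) stop("run has no z samples; use wham_1d")
  if (length(n_bins) == 1L) n_bins <- rep(n_bins, 2L)
  if (is.null(range_s)) range_s <- base::range(rp$samples)
  if (is.null(range_z)) range_z <- base::range(rp$samples_z)
  es <- seq(range_s[1L], range_s[2L], length.out = n_bins[1L] + 1L)
  ez <- seq(range_z[1L], range_z[2L], length.out = n_bins[2L] + 1L)
  cs <- .bin_centers(es); cz <- .bin_centers(ez)
  nw <- nrow(rp$windows)
  nb <- n_bins[1L] * n_bins[2L]
  counts <- matrix(0L, nb, nw)
  for (i in seq_len(nw)) {
    is_ <- .bin_index(rp$samples[, i], es)
    iz <- .bin_index(rp$samples_z[, i], ez)
    counts[, i] <- tabulate(is_ + (iz - 1L) * n_bins[1L], nbins = nb)
  }
  grid_s <- rep(cs, times = n_bins[2L])
  grid_z <- rep(cz, each = n_bins[1L])
  kz <- if (is.null(rp$windows$k_z)) rep(0, nw) else rp$windows$k_z
  zc <- if (is.null(rp$windows$center_z)) rep(0, nw)
  else rp$windows$center_z
  bias <- vapply(seq_len(nw), function(i)
    0.5 * rp$windows$k_s[i] * (grid_s - rp$windows$center_s[i])^2 +
      0.5 * kz[i] * (grid_z - zc[i])^2, numeric(nb))
  sol <- .wham_core(counts, bias, rp$kT, tol, max_iter)
  w <- matrix(-rp$kT * log(sol$p), n_bins[1L], n_bins[2L])
  fin <- is.finite(w)
  w <- w - min(w[fin])
  structure(list(s = cs, z = cz, W = w, kT = rp$kT,
                 iterations = sol$iterations, final_tol = sol$final_tol,
                 f = sol$f),
            class = "pmf_surface")
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat(sprintf("pmf_surface: %d x %d bins, converged in %d iterations\n",
              length(x$s), length(x$z), x$iterations))
  invisible(x)
}

#' Project a 2D free-energy surface onto the path
#'
#' Extracts the slice `W(s, z = z_star)` (linear interpolation between the
#' two bracketing z bins, per s column) and re-gauges it to minimum zero.
#'
#' @param surface a `pmf_surface`.
#' @param z_star slice position (default 0); must lie inside the z grid.
#' @return a `pmf_profile` over s.
#' @export
project_to_path <- function(surface, z_star = 0) {
  stopifnot(inherits(surface, "pmf_surface"))
  cz <- surface$z
  if (z_star < min(cz) || z_star > max(cz))
    stop(sprintf("z_star = %.3g outside the sampled z grid [%.3g, %.3g]",
                 z_star, min(cz), max(cz)))
  sliced <- apply(surface$W, 1L, function(wz) {
    fin <- which(is.finite(wz))
    if (length(fin) < 2L) return(NA_real_)
    if (z_star < cz[fin[1L]] || z_star > cz[fin[length(fin)]])
      return(NA_real_)
    stats::approx(cz[fin], wz[fin], xout = z_star)$y
  })
  ## s columns with no finite W anywhere are outside the sampled s support
  col_support <- apply(surface$W, 1L, function(wz) any(is.finite(wz)))
  bad <- which(col_support & is.na(sliced))
  if (length(bad))
    stop(sprintf("z = %.3g slice unsupported for s in [%.4g, %.4g]",
                 z_star, min(surface$s[bad]), max(surface$s[bad])))
  keep <- !is.na(sliced)
  if (!any(keep)) stop("slice has no supported bins")
  pmf_profile(surface$s[keep], sliced[keep], kT = surface$kT,
              iterations = surface$iterations,
              final_tol = surface$final_tol)
}

## ---- bootstrap uncertainty --------------------------------------------

#' Bootstrap uncertainty of a 1D PMF
#'
#' Resamples each window's trajectory with replacement (optionally in
#' blocks, for autocorrelated samples), recomputes the WHAM profile for
#' each of `n_boot` replicates on the same bin grid, aligns every replicate
#' so its value at the bin containing `align_at` is zero, and reports the
#' per-bin standard deviation across replicates (population form, 1/N_b).
#' By construction the uncertainty at the alignment position is exactly
#' zero.  Deterministic for a fixed seed.
#'
#' @param run an `umbrella_run` (raw per-window samples are required).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param align_at alignment position on the xi axis (default 0).
#' @param block_length resample in contiguous blocks of this length
#'   (default 1 = ordinary bootstrap).
#' @param n_bins,tol,max_iter,kT,range as in [wham_1d()].
#' @return a `pmf_profile` with `sigma` filled in (NA for bins that are
#'   empty in some replicate).
#' @export
bootstrap_uncertainty <- function(run, n_boot = 1000L, seed = 1L,
                                  align_at = 0, block_length = 1L,
                                  n_bins = 1000L, tol = 1e-6,
                                  max_iter = 200000L, kT = NULL,
                                  range = NULL) {
  rp <- .run_parts(run, kT)
  n <- nrow(rp$samples)
  if (n < 2L) stop("need raw per-window samples to bootstrap")
  if (is.null(range)) range <- base::range(rp$samples)
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  centers <- .bin_centers(edges)
  nw <- ncol(rp$samples)
  idx <- apply(rp$samples, 2L, .bin_index, edges = edges)  # n x nw
  counts <- apply(idx, 2L, tabulate, nbins = n_bins)
  .check_overlap(counts, rp$windows$center_s)
  bias <- outer(centers, seq_len(nw), function(xi, i)
    0.5 * rp$windows$k_s[i] * (xi - rp$windows$center_s[i])^2)
  full <- .wham_core(counts, bias, rp$kT, tol, max_iter)
  w_full <- -rp$kT * log(full$p)
  a_bin <- which.min(abs(centers - align_at))
  if (abs(centers[a_bin] - align_at) > diff(range))
    stop("align_at outside the profile range")

  set.seed(seed)
  resample <- function(col) {
    if (block_length <= 1L) col[sample.int(n, n, replace = TRUE)]
    else {
      nb <- ceiling(n / block_length)
      starts <- sample.int(n, nb, replace = TRUE)
      pos <- as.vector(outer(0:(block_length - 1L), starts, "+")) %% n + 1L
      col[pos[seq_len(n)]]
    }
  }
  acc <- matrix(0, n_bins, 2L)   # running sum, sum of squares
  n_fin <- integer(n_bins)
  for (b in seq_len(n_boot)) {
    cb <- vapply(seq_len(nw), function(i)
      tabulate(resample(idx[, i]), nbins = n_bins), integer(n_bins))
    sol <- .wham_core(cb, bias, rp$kT, tol, max_iter, f_init = full$f)
    wb <- -rp$kT * log(sol$p)
    if (!is.finite(wb[a_bin]))
      stop("alignment bin empty in a bootstrap replicate; use more samples")
    wb <- wb - wb[a_bin]
    fin <- is.finite(wb)
    acc[fin, 1L] <- acc[fin, 1L] + wb[fin]
    acc[fin, 2L] <- acc[fin, 2L] + wb[fin]^2
    n_fin <- n_fin + fin
  }
  sigma <- rep(NA_real_, n_bins)
  ok <- n_fin == n_boot
  mu <- acc[ok, 1L] / n_boot
  sigma[ok] <- sqrt(pmax(0, acc[ok, 2L] / n_boot - mu^2))
  pmf_profile(centers, w_full, sigma = sigma, kT = rp$kT,
              iterations = full$iterations, final_tol = full$final_tol,
              f = full$f, edges = edges)
}
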