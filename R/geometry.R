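## Structural metrics for tubulin curvature: least-squares superposition,
## plane fitting, intradimer and intramonomer rotations, domain-center
## bending angle, solvent-accessible and buried surface area, steric clashes.

## ---- rigid-body superposition -----------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets.  Reflections are disallowed.
#'
#' @param mobile,reference n x 3 coordinate matrices, paired row-by-row,
#'   n >= 3 and not all collinear.
#' @return a `superposition`: list with `rotation` (3 x 3, applied on the
#'   right of row vectors), `translation` (length 3), `rmsd` (angstrom).
#'   Transformed coordinates are `mobile %*% rotation` plus `translation`.
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' superpose(x, x)$rmsd
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mc <- sweep(mobile, 2L, cm); rc <- sweep(reference, 2L, cr)
  if (.is_collinear(mc) || .is_collinear(rc))
    stop("degenerate (collinear) coordinates: rotation is not determined")
  h <- crossprod(mc, rc)                 # 3 x 3
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- mc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  structure(list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd),
            class = "superposition")
}

.is_collinear <- function(centered, tol = 1e-8) {
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2L] <= tol * max(s[1L], 1e-300)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param sup a `superposition`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% sup$rotation, 2L, sup$translation, "+")
}

#' Rotation angle of a 3 x 3 rotation matrix, degrees
#' @param rotation proper rotation matrix.
#' @return angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(rotation) {
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

## rotation matrix for angle (deg) about unit axis, row-vector convention
#' Rotation matrix about an axis
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3 x 3 matrix to be applied on the right of row vectors.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  r_col <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  t(r_col)   # column-vector convention transposed for x %*% R use
}

## ---- plane fitting ----------------------------------------------------

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances to a
#' point set.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @return a `plane_fit`: list with `centroid`, `normal` (unit vector),
#'   `residual` (root-mean-square orthogonal distance, angstrom).
#' @examples
#' p <- cbind(runif(10), runif(10), 0)
#' fit_plane(p)$normal
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  if (.is_collinear(cen)) stop("collinear points: plane is not determined")
  sv <- svd(cen, nu = 0)
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  structure(list(centroid = ctr, normal = normal,
                 residual = sv$d[3L] / sqrt(nrow(points))),
            class = "plane_fit")
}

#' Intersection angle of two planes, degrees
#'
#' Plane normals carry a sign ambiguity, so the angle is folded to
#' `[0, 90]` degrees.
#' @param n1,n2 plane normals (any length-3 vectors).
#' @return angle in degrees.
#' @export
plane_angle <- function(n1, n2) {
  c1 <- n1 / sqrt(sum(n1^2)); c2 <- n2 / sqrt(sum(n2^2))
  acos(min(1, abs(sum(c1 * c2)))) * 180 / pi
}

## ---- per-variant angle aggregation ------------------------------------

#' @keywords internal
angle_result <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) stop("all atom-selection variants failed")
  structure(list(variants = angles, mean = mean(angles),
                 sd = if (length(angles) > 1L) stats::sd(angles) else 0),
            class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  cat(sprintf("angle: %.2f +/- %.2f deg  [%s]\n", x$mean, x$sd,
              paste(sprintf("%s=%.2f", names(x$variants), x$variants),
                    collapse = ", ")))
  invisible(x)
}

ANGLE_VARIANTS <- c("all", "backbone", "calpha")

## ---- intradimer rotation ----------------------------------------------

#' Intradimer rotation angle between a bent and a straight heterodimer
#'
#' The curvature metric based on the H7 central helices: the bent dimer is
#' superposed onto the straight one by its alpha-subunit H7 atoms; one
#' least-squares plane is then fitted through the combined alpha-H7 plus
#' beta-H7 atoms of the straight structure and one through those of the
#' transformed bent structure; the intradimer rotation is the intersection
#' angle of the two planes.  The measurement is repeated for three
#' atom-selection variants (all atoms, backbone N-CA-C-O, CA only) and
#' reported as their mean and standard deviation.
#'
#' @param bent,straight `tubulin_dimer` objects.
#' @param variants subset of `c("all", "backbone", "calpha")`.
#' @return an `angle_result` (degrees, folded to `[0, 90]`).
#' @export
intradimer_angle <- function(bent, straight, variants = ANGLE_VARIANTS) {
  variants <- match.arg(variants, ANGLE_VARIANTS, several.ok = TRUE)
  angles <- vapply(variants, function(v) {
    tryCatch({
      a_s <- select_atoms(straight, "alpha", "h7", v)
      a_b <- select_atoms(bent, "alpha", "h7", v)
      pr <- .pair_atoms(a_b, a_s)
      if (pr$n < 3L) stop("fewer than 3 paired alpha-H7 atoms")
      sup <- superpose(pr$a, pr$b)
      h7_s <- rbind(as.matrix(a_s[, c("x", "y", "z")]),
                    as.matrix(select_atoms(straight, "beta", "h7",
                                           v)[, c("x", "y", "z")]))
      h7_b <- rbind(as.matrix(a_b[, c("x", "y", "z")]),
                    as.matrix(select_atoms(bent, "beta", "h7",
                                           v)[, c("x", "y", "z")]))
      plane_angle(fit_plane(h7_s)$normal,
                  fit_plane(apply_superposition(h7_b, sup))$normal)
    }, error = function(e) {
      warning("variant '", v, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  angle_result(angles)
}

## ---- intramonomer rotation --------------------------------------------

#' Intramonomer rotation of the intermediate domain
#'
#' Quantifies the internal rearrangement of one subunit between a bent and a
#' straight structure: the two structures are first aligned on a reference
#' frame (by default the subunit's N-terminal-domain CA atoms), then the
#' residual rotation superposing the bent intermediate-domain selection onto
#' the straight one is extracted and converted to an angle via
#' `acos((trace - 1) / 2)`.  Three atom-selection variants are aggregated as
#' for [intradimer_angle()].
#'
#' @param bent,straight `tubulin_dimer` objects.
#' @param subunit `"alpha"` or `"beta"`.
#' @param frame_domain domain used for the reference alignment (CA atoms).
#' @param variants atom-selection variants for the intermediate domain.
#' @return an `angle_result` (degrees).
#' @export
intramonomer_rotation <- function(bent, straight,
                                  subunit = c("alpha", "beta"),
                                  frame_domain = "n_terminal",
                                  variants = ANGLE_VARIANTS) {
  subunit <- match.arg(subunit)
  variants <- match.arg(variants, ANGLE_VARIANTS, several.ok = TRUE)
  fr_s <- select_atoms(straight, subunit, frame_domain, "calpha")
  fr_b <- select_atoms(bent, subunit, frame_domain, "calpha")
  fr <- .pair_atoms(fr_b, fr_s)
  if (fr$n < 3L)
    stop("empty or degenerate frame selection for ", subunit, " ",
         frame_domain)
  frame_sup <- superpose(fr$a, fr$b)
  angles <- vapply(variants, function(v) {
    tryCatch({
      im_s <- select_atoms(straight, subunit, "intermediate", v)
      im_b <- select_atoms(bent, subunit, "intermediate", v)
      pr <- .pair_atoms(im_b, im_s)
      if (pr$n < 3L) stop("fewer than 3 paired intermediate-domain atoms")
      res <- superpose(apply_superposition(pr$a, frame_sup), pr$b)
      rotation_angle(res$rotation)
    }, error = function(e) {
      warning("variant '", v, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  angle_result(angles)
}

## ---- domain center-of-mass bending angle ------------------------------

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, Mg = 24.305, Zn = 65.38,
                   Fe = 55.845, Na = 22.99, K = 39.098, Cl = 35.45)

.center_of_mass <- function(atoms) {
  m <- ATOMIC_MASSES[atoms$elesy]
  m[is.na(m)] <- 12.011
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  colSums(xyz * m) / sum(m)
}

#' Intrinsic bending angle from domain mass centers
#'
#' The alternative curvature metric: for each subunit, a least-squares line
#' is fitted through the centers of mass of its N-terminal, intermediate and
#' C-terminal domains; the bending angle is the intersection angle of the
#' two subunit lines, folded to `[0, 90]` degrees.
#'
#' @param dimer a `tubulin_dimer`.
#' @return angle in degrees.
#' @export
voth_bending_angle <- function(dimer) {
  dirs <- lapply(c("alpha", "beta"), function(su) {
    centers <- t(vapply(c("n_terminal", "intermediate", "c_terminal"),
                        function(dom)
                          .center_of_mass(select_atoms(dimer, su, dom, "all")),
                        numeric(3)))
    cen <- sweep(centers, 2L, colMeans(centers))
    sv <- svd(cen, nu = 0)
    if (sv$d[1L] <= 1e-8)
      stop("degenerate domain centers (coincident) for ", su, "-subunit")
    sv$v[, 1L]
  })
  acos(min(1, abs(sum(dirs[[1]] * dirs[[2]])))) * 180 / pi
}

## ---- solvent-accessible and buried surface area ------------------------

#' Van der Waals radii (Bondi-style element table), angstrom
#' @keywords internal
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Mg = 1.73,
               Zn = 1.39, Na = 2.27, K = 2.75, Fe = 2.00, Se = 1.90)

#' Look up van der Waals radii for elements
#' @param elements character vector of element symbols.
#' @param radii named radius table (angstrom); defaults to the built-in
#'   Bondi-style table.
#' @param default fallback radius for unknown elements; if `NULL`
#'   (default), unknown elements are an error.
#' @return numeric vector of radii.
#' @export
vdw_radii <- function(elements, radii = VDW_RADII, default = NULL) {
  r <- radii[elements]
  if (anyNA(r)) {
    unknown <- unique(elements[is.na(r)])
    if (is.null(default))
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "))
    r[is.na(r)] <- default
  }
  unname(r)
}

## deterministic quasi-uniform sphere point set (Fibonacci lattice)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling of the solvent-accessible surface: each atom is
#' expanded by the probe radius and covered with a deterministic Fibonacci
#' lattice of test points; points falling inside any neighbour's expanded
#' sphere are buried.  Deterministic for a fixed `n_points`.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param radii per-atom van der Waals radii (angstrom), all positive.
#' @param probe_radius solvent probe radius, angstrom (default 1.2).
#' @param n_points test points per atom (default 960).
#' @return total area in square angstrom, with attribute `"per_atom"`.
#' @examples
#' sasa(matrix(0, 1, 3), 1.7)          # 4*pi*(1.7+1.2)^2
#' @export
sasa <- function(xyz, radii, probe_radius = 1.2, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("radii must be positive")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  rr <- radii + probe_radius
  pts <- .sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    p <- sweep(pts * rr[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc[acc] <- rowSums(sweep(p[acc, , drop = FALSE], 2L,
                                xyz[j, ])^2) >= rr[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_points
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Buried surface area of the intradimer interface
#'
#' `BSA = SASA(alpha alone) + SASA(beta alone) - SASA(alpha-beta complex)`,
#' all three terms computed with the same probe radius and point set.
#' Heteroatoms (ligands, ions, solvent) are stripped by default.
#'
#' @param dimer a `tubulin_dimer`.
#' @param probe_radius,n_points passed to [sasa()].
#' @param strip_het drop HETATM records (default `TRUE`).
#' @param radius_default fallback vdW radius for unknown elements.
#' @return buried area in square angstrom.
#' @export
buried_surface_area <- function(dimer, probe_radius = 1.2, n_points = 960L,
                                strip_het = TRUE, radius_default = NULL) {
  get_chain <- function(ch) {
    a <- dimer$structure$atoms
    a <- a[a$chain == ch, , drop = FALSE]
    if (strip_het) a <- a[a$type == "ATOM", , drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms in chain ", ch)
    a
  }
  aa <- get_chain(dimer$alpha)
  ab <- get_chain(dimer$beta)
  ra <- vdw_radii(aa$elesy, default = radius_default)
  rb <- vdw_radii(ab$elesy, default = radius_default)
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  as.numeric(sasa(xa, ra, probe_radius, n_points) +
               sasa(xb, rb, probe_radius, n_points) -
               sasa(rbind(xa, xb), c(ra, rb), probe_radius, n_points))
}

## ---- steric clashes ---------------------------------------------------

#' Steric clashes between two atom sets
#'
#' Flags every atom pair whose distance is below `scale` times the sum of
#' the two van der Waals radii (default 75 percent).  When both arguments
#' are the same set, an atom is never paired with itself and each pair is
#' reported once.
#'
#' @param set_a,set_b atom tables (data.frames with `x`, `y`, `z` and
#'   `elesy`) or n x 3 matrices (then `elements_a`/`elements_b` supply the
#'   element symbols).
#' @param elements_a,elements_b element symbols when matrices are given.
#' @param scale clash threshold as a fraction of the radius sum.
#' @param radii,default radius table and fallback, as in [vdw_radii()].
#' @return data.frame with `i`, `j`, `distance`, `threshold` (angstrom).
#' @export
steric_clashes <- function(set_a, set_b = set_a, elements_a = NULL,
                           elements_b = NULL, scale = 0.75,
                           radii = VDW_RADII, default = NULL) {
  unpack <- function(s, elems) {
    if (is.data.frame(s))
      list(xyz = as.matrix(s[, c("x", "y", "z")]), el = s$elesy)
    else list(xyz = as.matrix(s), el = elems)
  }
  same <- identical(set_a, set_b) &&
    (is.data.frame(set_a) || is.null(elements_b) ||
       identical(elements_a, elements_b))
  ua <- unpack(set_a, elements_a)
  ub <- unpack(set_b, if (same) elements_a else elements_b)
  if (is.null(ua$el) || is.null(ub$el))
    stop("element symbols required (elements_a/elements_b)")
  ra <- vdw_radii(ua$el, radii, default)
  rb <- vdw_radii(ub$el, radii, default)
  na <- nrow(ua$xyz); nb <- nrow(ub$xyz)
  out <- vector("list", na)
  for (i in seq_len(na)) {
    d <- sqrt(rowSums(sweep(ub$xyz, 2L, ua$xyz[i, ])^2))
    thr <- scale * (ra[i] + rb)
    hit <- which(d < thr)
    if (same) hit <- hit[hit > i]
    if (length(hit))
      out[[i]] <- data.frame(i = i, j = hit, distance = d[hit],
                             threshold = thr[hit])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(i = integer(), j = integer(), distance = numeric(),
                      threshold = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
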