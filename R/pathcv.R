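## Reference paths (linear morphs between endpoint structures) and the path
## collective variables s(R) / z(R).
##
## s(R) = sum_i i * exp(-lambda * M_i) / sum_i exp(-lambda * M_i)
## z(R) = -(1/lambda) * ln sum_i exp(-lambda * M_i)
## with M_i the mean squared displacement (angstrom^2) of the configured
## atom selection from path frame R_i, i = 1..P (1-based frame index).

#' Construct a reference path
#'
#' Low-level constructor; most users will call [linear_morph()].
#'
#' @param frames list of n x 3 coordinate matrices sharing atom order.
#' @param meta data.frame describing the shared atoms (`chain`, `resno`,
#'   `insert`, `elety`, `resid`).
#' @param cv_idx integer row indices of the collective-variable selection.
#' @param lambda smoothing prefactor (1/angstrom^2), or `NULL` to defer to
#'   [choose_lambda()].
#' @return a `reference_path`.
#' @export
reference_path <- function(frames, meta, cv_idx = seq_len(nrow(meta)),
                           lambda = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  n <- nrow(frames[[1L]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("all frames must share the same atom count and ordering")
  stopifnot(nrow(meta) == n, length(cv_idx) >= 1L,
            all(cv_idx >= 1L & cv_idx <= n))
  succ <- vapply(seq_len(length(frames) - 1L), function(k)
    mean(rowSums((frames[[k + 1L]][cv_idx, , drop = FALSE] -
                    frames[[k]][cv_idx, , drop = FALSE])^2)), numeric(1))
  if (any(succ <= 0))
    stop("successive frames must differ on the CV selection")
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be positive")
  structure(list(frames = frames, meta = meta, cv_idx = as.integer(cv_idx),
                 lambda = lambda),
            class = "reference_path")
}

#' @export
print.reference_path <- function(x, ...) {
  cat(sprintf("reference_path: P = %d frames, %d atoms (%d in CV selection)",
              length(x$frames), nrow(x$meta), length(x$cv_idx)),
      if (!is.null(x$lambda)) sprintf(", lambda = %.4g /A^2", x$lambda)
      else "", "\n", sep = "")
  invisible(x)
}

#' Linear morph between two endpoint structures
#'
#' Builds `n_intermediates + 2` equidistant frames along the straight line
#' (in coordinate space) between two structures: the end structure is first
#' rigidly superposed onto the start over the collective-variable selection,
#' then frame `k` is `start + (k-1)/(P-1) * (end - start)` over all atoms
#' common to both structures.  Endpoints are frames 1 and P.
#'
#' @param start,end `structure_model` objects.
#' @param n_intermediates number of interior frames (default 13, giving
#'   P = 15).
#' @param select_fun predicate on the common-atom table choosing the CV
#'   selection; default CA atoms.
#' @param lambda optional smoothing prefactor; if `NULL` it is filled in
#'   with [choose_lambda()].
#' @param lambda_c proportionality constant for [choose_lambda()].
#' @return a `reference_path`.
#' @export
linear_morph <- function(start, end, n_intermediates = 13L,
                         select_fun = function(meta) meta$elety == "CA",
                         lambda = NULL, lambda_c = 2.3) {
  stopifnot(inherits(start, "structure_model"),
            inherits(end, "structure_model"), n_intermediates >= 0L)
  sa <- start$atoms[start$atoms$type == "ATOM", , drop = FALSE]
  ea <- end$atoms[end$atoms$type == "ATOM", , drop = FALSE]
  key <- function(a) paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  common <- intersect(key(sa), key(ea))
  if (length(common) == 0L) stop("no atoms common to both structures")
  ia <- match(common, key(sa)); ie <- match(common, key(ea))
  meta <- sa[ia, c("chain", "resno", "insert", "elety", "resid")]
  rownames(meta) <- NULL
  xs <- as.matrix(sa[ia, c("x", "y", "z")])
  xe <- as.matrix(ea[ie, c("x", "y", "z")])
  cv_idx <- which(select_fun(meta))
  if (length(cv_idx) < 3L)
    stop("CV selection resolves to fewer than 3 common atoms")
  sup <- superpose(xe[cv_idx, , drop = FALSE], xs[cv_idx, , drop = FALSE])
  xe <- apply_superposition(xe, sup)
  p <- n_intermediates + 2L
  fr <- lapply(seq_len(p), function(k)
    xs + (k - 1) / (p - 1) * (xe - xs))
  path <- reference_path(fr, meta, cv_idx, lambda)
  if (is.null(path$lambda)) path$lambda <- choose_lambda(path, c = lambda_c)
  path
}

#' Materialise one path frame as a structure
#' @param path a `reference_path`.
#' @param k frame index (1..P).
#' @param identifier label for the new model.
#' @return a `structure_model`.
#' @export
path_frame_structure <- function(path, k, identifier = sprintf("frame%02d",
                                                               k)) {
  stopifnot(k >= 1L, k <= length(path$frames))
  at <- path$meta
  at$x <- path$frames[[k]][, 1L]
  at$y <- path$frames[[k]][, 2L]
  at$z <- path$frames[[k]][, 3L]
  structure_model(at, identifier = identifier)
}

#' Mean squared displacement between two conformations
#'
#' @param x,y n x 3 coordinate matrices over the same atoms.
#' @param align superpose `x` onto `y` first (default `TRUE`; rigid-body
#'   motion is not part of the conformational coordinate).
#' @return MSD in square angstrom.
#' @export
frame_msd <- function(x, y, align = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("coordinate sets must match in size")
  if (align) x <- apply_superposition(x, superpose(x, y))
  mean(rowSums((x - y)^2))
}

#' Smoothing prefactor from successive-frame displacements
#'
#' `lambda = c / mean(MSD(R_i, R_{i+1}))`, proportional to the inverse mean
#' square displacement between successive path frames.
#'
#' @param path a `reference_path`.
#' @param c proportionality constant (default 2.3).
#' @param align align successive frames before the MSD (default `TRUE`).
#' @return lambda in 1/angstrom^2.
#' @export
choose_lambda <- function(path, c = 2.3, align = TRUE) {
  stopifnot(inherits(path, "reference_path"), c > 0)
  p <- length(path$frames)
  msds <- vapply(seq_len(p - 1L), function(k)
    frame_msd(path$frames[[k]][path$cv_idx, , drop = FALSE],
              path$frames[[k + 1L]][path$cv_idx, , drop = FALSE],
              align = align), numeric(1))
  if (any(msds <= 0)) stop("zero successive-frame MSD")
  c / mean(msds)
}

#' Path collective variables s(R) and z(R)
#'
#' Progress along (`s`, dimensionless, range `[1, P]`) and squared-distance
#' deviation from (`z`, square angstrom) a reference path, computed with
#' overflow-safe exponent shifting.
#'
#' @param xyz coordinates of the query conformation: either over all path
#'   atoms (rows matching `path$meta`) or over the CV selection only.
#' @param path a `reference_path`.
#' @param lambda smoothing prefactor; defaults to `path$lambda`.
#' @param align superpose the query onto each frame before the MSD.
#' @return list with `s`, `z`, and the per-frame `msd` vector.
#' @export
path_cv <- function(xyz, path, lambda = NULL, align = TRUE) {
  stopifnot(inherits(path, "reference_path"))
  lambda <- if (!is.null(lambda)) lambda else path$lambda
  if (is.null(lambda)) stop("no lambda: set path$lambda or pass lambda")
  xyz <- as.matrix(xyz)
  n_all <- nrow(path$meta)
  xq <- if (nrow(xyz) == n_all) xyz[path$cv_idx, , drop = FALSE]
  else if (nrow(xyz) == length(path$cv_idx)) xyz
  else stop("xyz must cover all path atoms or exactly the CV selection")
  m <- vapply(path$frames, function(fr)
    frame_msd(xq, fr[path$cv_idx, , drop = FALSE], align = align),
    numeric(1))
  if (all(!is.finite(m))) stop("all frame MSDs are non-finite")
  e <- -lambda * m
  shift <- max(e)
  w <- exp(e - shift)
  sw <- sum(w)
  list(s = sum(seq_along(m) * w) / sw,
       z = -(log(sw) + shift) / lambda,
       msd = m)
}
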