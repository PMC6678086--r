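#' Geometric center of a coordinate set
#'
#' Unweighted arithmetic mean of the coordinates — deliberately not a
#' center of mass: all inter-domain distances here are defined on
#' geometric centers of C-alpha atoms.
#'
#' @param points n x 3 numeric matrix (nm).
#' @return Length-3 numeric vector (nm).
#' @export
geometric_center <- function(points) {
  points <- as_coord_matrix(points)
  colMeans(points)
}

as_coord_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) == 3L) points <- matrix(points, nrow = 1L)
    else stop("expected an n x 3 coordinate matrix")
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("expected an n x 3 coordinate matrix")
  if (nrow(points) < 1L) stop("empty coordinate set")
  if (anyNA(points) || any(!is.finite(points)))
    stop("non-finite coordinates")
  points
}

#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum_i || R x_i + t - y_i ||^2` for paired point sets, via SVD of the
#' 3x3 cross-covariance with a determinant correction that excludes
#' reflections.
#'
#' @param mobile n x 3 matrix to be fitted (nm).
#' @param reference n x 3 matrix of target coordinates (nm).
#' @return A `rigid_transform`: list with `rotation` (3x3, det +1) and
#'   `translation` (length-3, nm), applied as `x %*% t(R) + t`.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  n <- nrow(mobile)
  if (nrow(reference) != n)
    stop("kabsch_fit: point counts differ (", n, " vs ", nrow(reference), ")")
  if (n < 3L)
    stop("kabsch_fit: need at least 3 points, got ", n)
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2L, mc)
  Y <- sweep(reference, 2L, rc)
  # rank of the mobile cloud: collinear points leave the rotation about
  # the line undetermined
  sx <- svd(X, nu = 0, nv = 0)$d
  if (sx[2] <= 1e-10 * max(sx[1], 1e-300))
    stop("kabsch_fit: degenerate (collinear or coincident) point set; ",
         "rotation is not uniquely determined")
  H <- crossprod(X, Y)               # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(rc - R %*% mc)
  new_rigid_transform(R, t_vec)
}

new_rigid_transform <- function(rotation, translation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-10)
    stop("rigid_transform: rotation determinant is not +1")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("<rigid_transform> rotation ", format(ang, digits = 4),
      " deg, translation |t| = ",
      format(sqrt(sum(x$translation^2)), digits = 4), " nm\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix (nm).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_coord_matrix(points)
  sweep(points %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' Remove global translation and rotation from a trajectory
#'
#' Superposes every frame onto `reference` by the least-squares fit of
#' `fit_selection` (typically all protein C-alpha atoms); the fitted
#' transform is applied to all atoms of the frame, so internal motions
#' are untouched. This mirrors standard MD post-processing in which
#' whole-body drift and tumbling are removed before any analysis.
#'
#' @param traj A `trajectory`.
#' @param fit_selection Integer atom indices used for the fit (>= 3).
#' @param reference Atoms x 3 reference coordinate matrix (nm), e.g. the
#'   equilibrated structure or the first frame.
#' @return A `trajectory` with superposed frames.
#' @export
remove_global_motion <- function(traj, fit_selection, reference) {
  stopifnot(inherits(traj, "trajectory"))
  fit_selection <- as.integer(fit_selection)
  if (length(fit_selection) < 3L)
    stop("remove_global_motion: fit selection needs >= 3 atoms")
  reference <- as_coord_matrix(reference)
  ref_sel <- reference[fit_selection, , drop = FALSE]
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = TRUE]
    tr <- tryCatch(kabsch_fit(xyz[fit_selection, , drop = FALSE], ref_sel),
                   error = function(e)
                     stop("remove_global_motion: frame ", f, ": ",
                          conditionMessage(e), call. = FALSE))
    out[, , f] <- apply_transform(tr, xyz)
  }
  new_trajectory(traj$topology, out, traj$times)
}

#' Inter-domain distance time series
#'
#' Per-frame Euclidean distance between the geometric centers of two
#' domains' C-alpha atoms. The distance is invariant under any rigid
#' transform applied to whole frames, so it may be computed before or
#' after global-motion removal.
#'
#' @param traj A `trajectory`.
#' @param spec_a,spec_b `domain_spec` objects (or integer index vectors).
#' @return A data frame of class `distance_series` with columns
#'   `time_ns`, `distance_nm`, and attributes `domain_a`, `domain_b`.
#' @export
interdomain_distance_series <- function(traj, spec_a, spec_b) {
  stopifnot(inherits(traj, "trajectory"))
  idx_a <- resolve_selection(traj$topology, spec_a)
  idx_b <- resolve_selection(traj$topology, spec_b)
  nf <- n_frames(traj)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    ca <- colMeans(xyz[idx_a, , drop = FALSE])
    cb <- colMeans(xyz[idx_b, , drop = FALSE])
    d[f] <- sqrt(sum((ca - cb)^2))
  }
  out <- data.frame(time_ns = traj$times, distance_nm = d)
  attr(out, "domain_a") <- selection_name(spec_a)
  attr(out, "domain_b") <- selection_name(spec_b)
  class(out) <- c("distance_series", "data.frame")
  out
}

resolve_selection <- function(topology, spec) {
  if (inherits(spec, "domain_spec")) return(select_domain(topology, spec))
  idx <- as.integer(spec)
  if (length(idx) == 0L) stop("empty atom selection")
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(topology$atoms)))
    stop("atom selection indices out of range")
  idx
}

selection_name <- function(spec) {
  if (inherits(spec, "domain_spec")) spec$name else "selection"
}
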