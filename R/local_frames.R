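# Per-frame local coordinate systems: the three principal axes of a
# domain's C-alpha cloud, ordered by decreasing spatial variance. PCA
# eigenvectors are unique in direction but ambiguous in orientation
# (sign); a deterministic raw sign rule plus standardization against a
# reference triad (the crystal structure) makes triads comparable across
# frames and across independent runs.

#' Principal-axis local frame of one domain in one frame
#'
#' Eigen-decomposes the 3x3 covariance (1/N normalization) of the centered
#' coordinates. Eigenvectors are sorted by descending eigenvalue, each
#' flipped so its largest-magnitude component is positive (ties: first
#' such component), and the third axis is recomputed as `v1 x v2` so the
#' triad is always right-handed.
#'
#' @param coords n x 3 matrix of the domain's C-alpha coordinates (nm).
#' @return A `local_frame`: list with `origin` (geometric center, nm),
#'   `axes` (3x3 matrix, columns v1,v2,v3, orthonormal, right-handed),
#'   `eigenvalues` (nm^2, descending) and `warnings` (character).
#' @export
pca_frame <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 3L)
    stop("pca_frame: need at least 3 points, got ", nrow(coords))
  origin <- colMeans(coords)
  X <- sweep(coords, 2L, origin)
  covm <- crossprod(X) / nrow(X)          # population (1/N) covariance
  ev <- eigen(covm, symmetric = TRUE)     # eigenvalues already descending
  lam <- pmax(ev$values, 0)
  if (lam[2] <= 1e-12 * max(lam[1], 1e-300))
    stop("pca_frame: degenerate (collinear) coordinate cloud; ",
         "second principal axis undefined")
  V <- ev$vectors
  warnings_out <- character(0)
  if (any(lam[1:2] - lam[2:3] < 1e-3 * lam[1]))
    warnings_out <- "near-degenerate eigenvalue pair; axis directions unstable"
  for (j in 1:2) V[, j] <- raw_sign_fix(V[, j])
  V[, 3] <- cross3(V[, 1], V[, 2])
  new_local_frame(origin, V, lam, warnings_out)
}

raw_sign_fix <- function(v) {
  k <- which.max(abs(v))                   # first maximal-|.| component
  if (v[k] < 0) -v else v
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_local_frame <- function(origin, axes, eigenvalues,
                            warnings = character(0)) {
  stopifnot(length(origin) == 3L, is.matrix(axes),
            all(dim(axes) == c(3L, 3L)), length(eigenvalues) == 3L)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stop("local_frame: axes not orthonormal")
  if (sum(cross3(axes[, 1], axes[, 2]) * axes[, 3]) <= 0)
    stop("local_frame: axes not right-handed")
  if (any(diff(eigenvalues) > 1e-12))
    stop("local_frame: eigenvalues must be non-increasing")
  structure(list(origin = as.numeric(origin), axes = axes,
                 eigenvalues = as.numeric(eigenvalues),
                 warnings = warnings),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame> origin (", paste(format(x$origin, digits = 4),
                                      collapse = ", "),
      ") nm, eigenvalues ", paste(format(x$eigenvalues, digits = 4),
                                  collapse = " >= "), " nm^2\n", sep = "")
  if (length(x$warnings)) cat("  warning: ", x$warnings, "\n", sep = "")
  invisible(x)
}

#' Standardize a local frame's eigenvector signs against a reference
#'
#' Flips `v1` and `v2` independently so that each has a non-negative dot
#' product with the corresponding reference axis, then recomputes
#' `v3 = v1 x v2` to restore right-handedness. Eigenvalues are unchanged.
#' An exactly-zero dot product keeps the raw sign (recorded in the
#' frame's warnings).
#'
#' @param frame,reference `local_frame` objects.
#' @return A standardized `local_frame`.
#' @export
standardize_frame <- function(frame, reference) {
  stopifnot(inherits(frame, "local_frame"),
            inherits(reference, "local_frame"))
  V <- frame$axes
  warn <- frame$warnings
  for (j in 1:2) {
    dp <- sum(V[, j] * reference$axes[, j])
    if (dp < 0) V[, j] <- -V[, j]
    else if (dp == 0)
      warn <- c(warn, paste0("axis ", j,
                             " orthogonal to reference; raw sign kept"))
  }
  V[, 3] <- cross3(V[, 1], V[, 2])
  new_local_frame(frame$origin, V, frame$eigenvalues, warn)
}

#' Per-frame local frames of one domain along a trajectory
#'
#' Computes the reference triad once from the (crystal) reference
#' coordinates with the raw sign rule, then the triad of every trajectory
#' frame, standardized against the reference. Using the untransformed
#' crystal structure as the common reference makes triads comparable
#' between independent runs and between bound and free ensembles.
#'
#' @param traj A `trajectory`.
#' @param spec A `domain_spec` (or integer atom indices).
#' @param reference_coords Atoms x 3 reference coordinate matrix (nm),
#'   indexed by the same topology as `traj`.
#' @return A `frame_series`: list with `frames` (list of `local_frame`),
#'   `times`, `domain`, `reference` (the reference `local_frame`).
#' @export
frame_series <- function(traj, spec, reference_coords) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(traj$topology, spec)
  reference_coords <- as_coord_matrix(reference_coords)
  if (max(idx) > nrow(reference_coords))
    stop("frame_series: selection exceeds reference structure atom count")
  ref_frame <- pca_frame(reference_coords[idx, , drop = FALSE])
  nf <- n_frames(traj)
  frames <- vector("list", nf)
  n_warn <- 0L
  for (f in seq_len(nf)) {
    lf <- tryCatch(
      pca_frame(traj$coords[idx, , f, drop = TRUE]),
      error = function(e) stop("frame_series: frame ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    lf <- standardize_frame(lf, ref_frame)
    if (length(lf$warnings)) n_warn <- n_warn + 1L
    frames[[f]] <- lf
  }
  if (n_warn > 0L)
    warning("frame_series ('", selection_name(spec), "'): ", n_warn, " of ",
            nf, " frames carry eigen-decomposition warnings ",
            "(near-degenerate principal axes)")
  structure(list(frames = frames, times = traj$times,
                 domain = selection_name(spec), reference = ref_frame),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> domain '", x$domain, "', ", length(x$frames),
      " frames\n", sep = "")
  invisible(x)
}

#' Flatten a frame series to a data frame
#'
#' One row per frame: time, the nine axis components (column-major:
#' v1x,v1y,v1z,v2x,...) and the three eigenvalues.
#'
#' @param fs A `frame_series`.
#' @return A data frame.
#' @export
frame_series_table <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  mat <- t(vapply(fs$frames,
                  function(f) c(as.numeric(f$axes), f$eigenvalues),
                  numeric(12)))
  colnames(mat) <- c(paste0("v", rep(1:3, each = 3), "_", rep(c("x", "y", "z"), 3)),
                     paste0("lambda", 1:3, "_nm2"))
  cbind(data.frame(time_ns = fs$times), as.data.frame(mat))
}
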