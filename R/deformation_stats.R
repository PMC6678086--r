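# Deformation statistics: RMSD(t) of a domain's C-alpha atoms after
# least-squares superposition onto a reference (intra-domain shape
# change), and per-residue RMSF about the time-averaged position
# (per-atom flexibility), plus per-run / pooled summaries.

#' RMSD time series of a domain
#'
#' For each frame, the domain's C-alpha atoms are least-squares fitted
#' onto the reference domain coordinates and
#' `RMSD = sqrt(mean(|r_i - r_i_ref|^2))` is evaluated over the domain's
#' N atoms. With the default domain-local fit the series measures pure
#' intra-domain deformation; `fit = "none"` skips the superposition
#' (useful when frames are already aligned on a parent selection).
#'
#' @param traj A `trajectory`.
#' @param spec A `domain_spec` (or integer atom indices) with >= 3 atoms.
#' @param reference Reference coordinates: either an atoms x 3 matrix for
#'   the whole topology, or `NULL` (default) to use the trajectory's
#'   first frame.
#' @param fit `"domain"` (default): fit on the domain's own atoms before
#'   the deviation sum; `"none"`: no superposition.
#' @return Data frame of class `rmsd_series` with columns `time_ns`,
#'   `rmsd_nm` and attribute `domain`.
#' @export
rmsd_series <- function(traj, spec, reference = NULL,
                        fit = c("domain", "none")) {
  stopifnot(inherits(traj, "trajectory"))
  fit <- match.arg(fit)
  idx <- resolve_selection(traj$topology, spec)
  if (length(idx) < 3L)
    stop("rmsd_series: domain '", selection_name(spec),
         "' has fewer than 3 atoms")
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  reference <- as_coord_matrix(reference)
  ref_dom <- reference[idx, , drop = FALSE]
  nf <- n_frames(traj)
  r <- numeric(nf)
  for (f in seq_len(nf)) {
    dom <- traj$coords[idx, , f, drop = TRUE]
    if (fit == "domain") {
      tr <- tryCatch(kabsch_fit(dom, ref_dom),
                     error = function(e)
                       stop("rmsd_series: frame ", f, ": ",
                            conditionMessage(e), call. = FALSE))
      dom <- apply_transform(tr, dom)
    }
    r[f] <- sqrt(mean(rowSums((dom - ref_dom)^2)))
  }
  out <- data.frame(time_ns = traj$times, rmsd_nm = r)
  attr(out, "domain") <- selection_name(spec)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-residue RMSF profile
#'
#' Per-atom root-mean-square fluctuation about the atom's time-averaged
#' position, `RMSF(i) = sqrt(mean_t |r_i(t) - <r_i>|^2)`. In the C-alpha
#' representation the residue value is its C-alpha atom's RMSF. Global
#' translation/rotation must have been removed beforehand (see
#' [remove_global_motion()]): RMSF on an unaligned trajectory mixes
#' whole-body tumbling into every atom.
#'
#' @param traj A `trajectory`, already superposed on the parent molecule.
#' @param spec A `domain_spec` (or integer atom indices).
#' @return Data frame of class `rmsf_profile` with columns `chain_id`,
#'   `resnum`, `resname`, `rmsf_nm`.
#' @export
rmsf_profile <- function(traj, spec) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L)
    stop("rmsf_profile: need at least 2 frames")
  idx <- resolve_selection(traj$topology, spec)
  sub <- traj$coords[idx, , , drop = FALSE]          # atoms x 3 x frames
  mean_pos <- apply(sub, c(1L, 2L), mean)
  dev2 <- sweep(sub, c(1L, 2L), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 1L, function(a) mean(colSums(a))))
  at <- traj$topology$atoms[idx, , drop = FALSE]
  out <- data.frame(chain_id = at$chain_id, resnum = at$resnum,
                    resname = at$resname, rmsf_nm = rmsf)
  rownames(out) <- NULL
  attr(out, "domain") <- selection_name(spec)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Per-run and pooled summaries of scalar series grouped by state
#'
#' Emits, for each run: mean, sample SD (n-1) and a Tukey five-number
#' summary (quartiles by linear interpolation, whiskers at the most
#' extreme values within 1.5 IQR of the quartiles, outliers listed); and
#' per state: the pooled (concatenated) mean and SD.
#'
#' @param series Named list of numeric vectors, one per run.
#' @param states Character vector (same length) of state labels, e.g.
#'   `"free"` / `"bound"`.
#' @return A `run_summary`: list with `runs` (data frame), `pooled`
#'   (data frame), `outliers` (named list).
#' @export
summarize_runs <- function(series, states) {
  if (!is.list(series) || length(series) == 0L)
    stop("summarize_runs: 'series' must be a non-empty list")
  if (length(states) != length(series))
    stop("summarize_runs: 'states' length must match 'series'")
  if (is.null(names(series)))
    names(series) <- paste0("run", seq_along(series))
  rows <- vector("list", length(series))
  outliers <- vector("list", length(series))
  for (i in seq_along(series)) {
    v <- as.numeric(series[[i]])
    if (length(v) == 0L)
      stop("summarize_runs: run '", names(series)[i], "' is empty")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    rows[[i]] <- data.frame(
      run = names(series)[i], state = states[i], n = length(v),
      mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
      whisker_lo = min(inside), q1 = q[1], median = q[2], q3 = q[3],
      whisker_hi = max(inside))
    outliers[[i]] <- v[v < lo_fence | v > hi_fence]
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  names(outliers) <- names(series)
  pooled_rows <- lapply(unique(states), function(s) {
    v <- unlist(series[states == s], use.names = FALSE)
    data.frame(state = s, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  pooled <- do.call(rbind, pooled_rows)
  rownames(pooled) <- NULL
  structure(list(runs = runs, pooled = pooled, outliers = outliers),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> ", nrow(x$runs), " runs, states: ",
      paste(x$pooled$state, collapse = ", "), "\n", sep = "")
  print(x$pooled)
  invisible(x)
}
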