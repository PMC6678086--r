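# Orientation statistics: directional cosines between corresponding
# principal axes of two domains, their time series and distributions, and
# descriptive bound-vs-free comparisons via the two-sample
# Kolmogorov-Smirnov statistic D (used as an effect-size style
# descriptor, never as a hypothesis test).

#' Angles between corresponding axes of two local frames
#'
#' For standardized triads (v1,v2,v3) and (w1,w2,w3), returns
#' `acos(clamp(dot(vi, wi), -1, 1))` in degrees for i = 1,2,3. The signed
#' (standardized) cosine is used, not its absolute value, so angles span
#' the full 0-180 degree range.
#'
#' @param frame_a,frame_b `local_frame` objects.
#' @return Named numeric vector `c(alpha=, beta=, gamma=)` in degrees.
#' @export
pair_angles <- function(frame_a, frame_b) {
  stopifnot(inherits(frame_a, "local_frame"),
            inherits(frame_b, "local_frame"))
  d <- colSums(frame_a$axes * frame_b$axes)
  ang <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  names(ang) <- c("alpha", "beta", "gamma")
  ang
}

#' Orientation-angle time series between two domains
#'
#' Elementwise [pair_angles()] over two per-domain frame series with
#' matching times.
#'
#' @param frames_a,frames_b `frame_series` objects of equal length and
#'   identical times.
#' @return A data frame of class `orientation_series` with columns
#'   `time_ns`, `alpha_deg`, `beta_deg`, `gamma_deg` and attributes
#'   `domain_a`, `domain_b`.
#' @export
orientation_series <- function(frames_a, frames_b) {
  stopifnot(inherits(frames_a, "frame_series"),
            inherits(frames_b, "frame_series"))
  if (length(frames_a$frames) != length(frames_b$frames))
    stop("orientation_series: series lengths differ (",
         length(frames_a$frames), " vs ", length(frames_b$frames), ")")
  if (max(abs(frames_a$times - frames_b$times)) > 1e-9)
    stop("orientation_series: frame times do not match")
  ang <- t(vapply(seq_along(frames_a$frames), function(i)
    pair_angles(frames_a$frames[[i]], frames_b$frames[[i]]), numeric(3)))
  out <- data.frame(time_ns = frames_a$times,
                    alpha_deg = ang[, 1],
                    beta_deg = ang[, 2],
                    gamma_deg = ang[, 3])
  attr(out, "domain_a") <- frames_a$domain
  attr(out, "domain_b") <- frames_b$domain
  class(out) <- c("orientation_series", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Exact supremum distance between the two empirical CDFs, evaluated over
#' the pooled sample points (right-continuous ECDFs). No asymptotic
#' approximation and no p-value: D itself is the reported quantity.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A `ks_result`: list with `D`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("ks_two_sample: both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("ks_two_sample: NA in input")
  pooled <- sort(unique(c(x, y)))
  # counts #{x <= t}, #{y <= t} at each pooled point; D is computed as a
  # ratio of integers so it is exact, not accumulated in floating point
  cx <- vapply(pooled, function(t) sum(x <= t), numeric(1))
  cy <- vapply(pooled, function(t) sum(y <= t), numeric(1))
  D <- max(abs(cx * length(y) - cy * length(x))) /
    (length(x) * length(y))
  structure(list(D = D, n1 = length(x), n2 = length(y)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("<ks_result> D = ", format(x$D, digits = 4), " (n1 = ", x$n1,
      ", n2 = ", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Descriptive comparison of a scalar series between two states
#'
#' Arithmetic means, sample standard deviations (n-1 denominator) and the
#' two-sample KS statistic for any scalar quantity (orientation angle,
#' distance, RMSD) pooled per state.
#'
#' @param free_values,bound_values Numeric samples (non-empty).
#' @return A `state_comparison`: list with `mean_free`, `sd_free`,
#'   `mean_bound`, `sd_bound`, `ks` (a `ks_result`).
#' @export
compare_states <- function(free_values, bound_values) {
  free_values <- as.numeric(free_values)
  bound_values <- as.numeric(bound_values)
  if (length(free_values) == 0L || length(bound_values) == 0L)
    stop("compare_states: both samples must be non-empty")
  sd1 <- function(v, lab) {
    if (length(v) == 1L) {
      warning("compare_states: single-element ", lab,
              " sample; SD reported as 0")
      return(0)
    }
    stats::sd(v)
  }
  structure(list(mean_free = mean(free_values),
                 sd_free = sd1(free_values, "free"),
                 mean_bound = mean(bound_values),
                 sd_bound = sd1(bound_values, "bound"),
                 ks = ks_two_sample(free_values, bound_values)),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("<state_comparison>\n",
      "  free : mean = ", format(x$mean_free, digits = 5), ", sd = ",
      format(x$sd_free, digits = 4), " (n = ", x$ks$n1, ")\n",
      "  bound: mean = ", format(x$mean_bound, digits = 5), ", sd = ",
      format(x$sd_bound, digits = 4), " (n = ", x$ks$n2, ")\n",
      "  KS D = ", format(x$ks$D, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Frequency histogram of orientation angles
#'
#' Counts (not densities) over `[0, 180]` degrees with half-open bins
#' `[a, b)`; the final bin is closed so 180 degrees is counted.
#'
#' @param values Numeric angles in degrees (may be empty).
#' @param bin_width_deg Positive bin width in degrees.
#' @return List with `bin_edges` (length nbins+1) and `counts`.
#' @export
angle_histogram <- function(values, bin_width_deg = 1) {
  if (!is.numeric(bin_width_deg) || length(bin_width_deg) != 1L ||
      bin_width_deg <= 0)
    stop("angle_histogram: bin width must be a positive number")
  nb <- as.integer(ceiling(180 / bin_width_deg - 1e-9))
  edges <- (0:nb) * bin_width_deg
  counts <- integer(nb)
  values <- as.numeric(values)
  if (length(values)) {
    if (any(values < 0 | values > 180))
      stop("angle_histogram: values outside [0, 180] degrees")
    bin <- pmin(floor(values / bin_width_deg) + 1L, nb)  # last bin closed
    tab <- tabulate(bin, nbins = nb)
    counts <- as.integer(tab)
  }
  list(bin_edges = edges, counts = counts)
}
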