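## Cartesian-to-polar step kinematics. At a fixed 10 s cadence the step size
## r is a velocity proxy; the heading theta is a quadrant-adjusted
## arctangent; the turning angle delta is the wrapped heading difference
## scaled to the unit interval.

#' Wrapped absolute difference between two headings
#'
#' `angle_diff(a, b)` returns `min(|a - b|, 2*pi - |a - b|)`, the magnitude of
#' the turn needed to go from heading `b` to heading `a` (a 90-degree right
#' turn equals a 270-degree left turn). Symmetric, zero iff the headings
#' coincide modulo 2*pi, bounded by pi.
#'
#' @param a,b Headings in radians.
#' @return Non-negative radians, at most pi. Vectorised.
#' @export
#' @examples
#' angle_diff(-3 * pi / 4, 3 * pi / 4) # pi / 2, via the wrap-around branch
angle_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Convert a track to a polar step series
#'
#' For each pair of consecutive fixes within a segment (trips split at cadence
#' gaps), computes the step size `r` (metres, Euclidean), the heading `theta`
#' (radians in (-pi, pi], via `atan2`), and the unit-scaled turning angle
#' `delta = angle_diff(theta[t], theta[t-1]) / pi` in `[0, 1]`.
#'
#' Steps shorter than the stationarity threshold `epsilon` (GPS jitter while
#' standing still) have no meaningful heading: `theta` is marked invalid
#' there, the last valid heading is carried forward for the next turning
#' angle, and `delta` is `NA` wherever either heading involved is undefined.
#'
#' @param track An [as_ars_track()] tibble.
#' @param epsilon Stationarity threshold in metres; steps shorter than this
#'   get no heading.
#' @return A tibble of class `ars_polar`, one row per step (the step ending
#'   at fix `t`), with columns `trip_id`, `segment`, `step` (index of the
#'   ending fix within its trip), `r`, `theta`, `theta_valid`, `delta`, `E`,
#'   `E_kind`.
#' @export
#' @examples
#' tr <- as_ars_track(data.frame(t = c(0, 10, 20), x = c(0, 3, 3), y = c(0, 4, 8)))
#' to_polar(tr)
to_polar <- function(track, epsilon = 0.5) {
  stopifnot(inherits(track, "ars_track"))
  steps <- dplyr::group_by(track, .data$trip_id) |>
    dplyr::mutate(step = dplyr::row_number()) |>
    dplyr::group_by(.data$trip_id, .data$segment) |>
    dplyr::reframe(
      step = .data$step[-1],
      t = .data$t[-1],
      r = sqrt(diff(.data$x)^2 + diff(.data$y)^2),
      theta = atan2(diff(.data$y), diff(.data$x)),
      E = .data$E[-1],
      E_kind = .data$E_kind[-1]
    )
  steps$theta_valid <- steps$r >= epsilon
  steps$theta[!steps$theta_valid] <- NA_real_
  steps <- dplyr::group_by(steps, .data$trip_id, .data$segment) |>
    dplyr::mutate(delta = turning_angles(.data$theta)) |>
    dplyr::ungroup()
  out <- steps[, c("trip_id", "segment", "step", "t", "r", "theta",
                   "theta_valid", "delta", "E", "E_kind")]
  class(out) <- c("ars_polar", class(out))
  attr(out, "epsilon") <- epsilon
  attr(out, "cadence_s") <- attr(track, "cadence_s")
  out
}

#' Unit-scaled turning angles from a heading series
#'
#' `delta[t] = angle_diff(theta[t], theta[t-1]) / pi`, using the last valid
#' (non-`NA`) heading before `t` as the reference when intermediate headings
#' are undefined. `NA` where the current heading is undefined or no valid
#' predecessor exists.
#'
#' @param theta Numeric vector of headings in radians, `NA` for undefined
#'   (stationary) steps.
#' @return Numeric vector of the same length, values in `[0, 1]` or `NA`.
#' @export
#' @examples
#' turning_angles(c(0, pi / 2, pi / 2)) # NA, 0.5, 0
turning_angles <- function(theta) {
  n <- length(theta)
  delta <- rep(NA_real_, n)
  last_valid <- NA_real_
  for (i in seq_len(n)) {
    if (!is.na(theta[i])) {
      if (!is.na(last_valid)) delta[i] <- angle_diff(theta[i], last_valid) / pi
      last_valid <- theta[i]
    }
  }
  delta
}

#' Label in-patch steps
#'
#' A step is in a patch when at least one prey encounter occurred in the
#' previous `W` steps of the same trip (the encounter step itself is not
#' in-patch). With an encounter at step `k`, steps `k + 1` to `k + W` are
#' in-patch.
#'
#' @param x An `ars_polar` tibble (adds an `in_patch` column, per trip), or a
#'   0/1 encounter vector (returns a logical vector).
#' @param W Patch window in steps (default 50, i.e. 500 s at 10 s cadence).
#' @return Same type as `x`.
#' @export
#' @examples
#' which(label_patches(replace(numeric(20), 5, 1), W = 3)) # 6, 7, 8
label_patches <- function(x, W = 50) {
  UseMethod("label_patches")
}

#' @export
label_patches.default <- function(x, W = 50) {
  stopifnot(W >= 1, all(x %in% c(0, 1)))
  n <- length(x)
  out <- logical(n)
  for (k in which(x == 1)) {
    if (k < n) out[(k + 1):min(k + W, n)] <- TRUE
  }
  out
}

#' @export
label_patches.data.frame <- function(x, W = 50) {
  stopifnot("E" %in% names(x), "trip_id" %in% names(x))
  dplyr::group_by(x, .data$trip_id) |>
    dplyr::mutate(in_patch = label_patches.default(.data$E, W = W)) |>
    dplyr::ungroup()
}

#' Squeeze unit-interval data off the boundary
#'
#' The Beta density is undefined at 0 and 1; observed turning angles hit both
#' endpoints (perfectly straight steps, exact reversals). Endpoint values are
#' mapped to `(d * (n - 1) + 0.5) / n` where `n` is the number of
#' observations; interior values are left untouched.
#'
#' @param d Numeric vector in `[0, 1]`.
#' @param n Sample size used in the mapping; defaults to `length(d)` (NAs
#'   excluded).
#' @return Vector in the open interval (0, 1).
#' @export
squeeze_unit <- function(d, n = sum(!is.na(d))) {
  stopifnot(all(d >= 0 & d <= 1, na.rm = TRUE), n > 0)
  at_edge <- !is.na(d) & (d == 0 | d == 1)
  d[at_edge] <- (d[at_edge] * (n - 1) + 0.5) / n
  d
}
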