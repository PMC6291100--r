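## Design construction for the lagged encounter regressions: the outcome at
## step t is modelled on indicators of an encounter s steps earlier, for
## s = 1..S, with no carry-over across trips or across cadence gaps.

#' Build a lagged-encounter design from a polar step series
#'
#' For every step with a defined outcome, records the encounter indicators
#' `E[t - s]`, `s = 1..S`, looking back only within the same segment (trips
#' are split at cadence gaps of more than one missed fix). Lags that would
#' reach before the start of a segment are 0.
#'
#' @param polar An [to_polar()] series (needs an `E` column; `E_kind` enables
#'   the encounter-type split variant).
#' @param outcome `"delta"` (unit-scaled turning angle) or `"r"` (step size,
#'   metres). Steps with an undefined turning angle are dropped for
#'   `"delta"`.
#' @param S Number of lags (default 90, i.e. 15 min at 10 s cadence).
#' @param r_floor Positive floor (metres) applied to step sizes before the
#'   log-normal likelihood, since exact zero displacements occur while the
#'   forager waits.
#' @return An object of class `ars_lag_design`: outcome vector `y`, `n x S`
#'   lag matrix `X`, per-kind lag matrices `X_hit`/`X_nonhit` when kinds are
#'   available, the previous outcome `prev` (for the AR-1 variant), and
#'   bookkeeping columns.
#' @export
build_lag_design <- function(polar, outcome = c("delta", "r"), S = 90,
                             r_floor = 0.05) {
  outcome <- match.arg(outcome)
  stopifnot(S >= 1, r_floor > 0, all(c("E", "r") %in% names(polar)))
  if (!"segment" %in% names(polar)) polar$segment <- polar$trip_id
  seg_len <- table(polar$segment)
  trip_len <- table(polar$trip_id)
  if (S >= max(trip_len)) {
    stop("S (", S, ") must be smaller than the longest trip (",
         max(trip_len), " steps)")
  }
  has_kind <- "E_kind" %in% names(polar)
  segs <- split(seq_len(nrow(polar)), polar$segment)
  lag_mat <- function(e, S) {
    m <- length(e)
    vapply(seq_len(S), function(s) {
      if (s >= m) numeric(m) else c(numeric(s), e[seq_len(m - s)])
    }, numeric(m))
  }
  parts <- lapply(segs, function(idx) {
    e <- polar$E[idx]
    X <- lag_mat(e, S)
    out <- list(X = X)
    if (has_kind) {
      out$X_hit <- lag_mat(as.numeric(polar$E_kind[idx] == "hit"), S)
      out$X_nonhit <- lag_mat(as.numeric(polar$E_kind[idx] == "nonhit"), S)
    }
    y <- if (outcome == "delta") polar$delta[idx] else polar$r[idx]
    out$y <- y
    out$prev <- c(NA_real_, y[-length(y)])
    out$row <- idx
    out
  })
  y <- unname(unlist(lapply(parts, `[[`, "y")))
  keep <- !is.na(y)
  bind <- function(nm) do.call(rbind, lapply(parts, `[[`, nm))[keep, , drop = FALSE]
  design <- list(
    outcome = outcome,
    y = y[keep],
    X = bind("X"),
    X_hit = if (has_kind) bind("X_hit"),
    X_nonhit = if (has_kind) bind("X_nonhit"),
    prev = unname(unlist(lapply(parts, `[[`, "prev")))[keep],
    trip_id = polar$trip_id[unlist(lapply(parts, `[[`, "row"))][keep],
    S = S,
    n = sum(keep),
    r_floor = r_floor
  )
  structure(design, class = "ars_lag_design")
}

#' @export
print.ars_lag_design <- function(x, ...) {
  cat("<ars_lag_design> outcome:", x$outcome, " n:", x$n, " S:", x$S,
      " encounters in window:", sum(x$X[, 1]), "\n")
  invisible(x)
}
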