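## Patch-conditional descriptive regressions. A "patch" is operational: any
## step within W = 50 steps after a prey encounter. These simple regressions
## summarise the same structure the lagged models estimate, as single slope
## coefficients beta with central 90% intervals.

#' Regress a movement outcome on the in-patch indicator
#'
#' Linear regression of the outcome (turning angle `delta` or step size `r`)
#' on the binary in-patch label; with a single binary regressor the slope is
#' exactly the in-patch minus out-of-patch mean difference.
#'
#' @param polar An `ars_polar` tibble carrying an `in_patch` column (see
#'   [label_patches()]).
#' @param outcome `"delta"` or `"r"`.
#' @param level Interval coverage (default 0.90).
#' @return A one-row tibble: `outcome`, `predictor`, `model`, `estimate`
#'   (beta), `conf.low`, `conf.high`, `n`.
#' @export
regress_on_patch <- function(polar, outcome = c("delta", "r"), level = 0.9) {
  outcome <- match.arg(outcome)
  stopifnot("in_patch" %in% names(polar))
  d <- polar[!is.na(polar[[outcome]]), ]
  if (all(d$in_patch) || !any(d$in_patch)) {
    stop("degenerate contrast: in_patch labels are all ",
         if (nrow(d) && all(d$in_patch)) "TRUE" else "FALSE")
  }
  fit <- lm(d[[outcome]] ~ d$in_patch)
  ci <- unname(suppressWarnings(confint(fit, level = level))[2, ])
  if (anyNA(ci)) ci <- rep(unname(coef(fit)[2]), 2) # zero residual variance
  tibble::tibble(outcome = outcome, predictor = "in_patch", model = "linear",
                 estimate = unname(coef(fit)[2]),
                 conf.low = ci[1], conf.high = ci[2], n = nrow(d))
}

#' Regress encounter occurrence on the previous step's movement
#'
#' Logistic regression of the encounter indicator `E[t]` on a single
#' predictor (turning angle or step size) at `t - 1`, lagged within trips.
#' The slope is on the log-odds scale with a Wald interval.
#'
#' @param polar An `ars_polar` tibble.
#' @param predictor `"delta"` or `"r"`.
#' @param level Interval coverage (default 0.90).
#' @return A one-row tibble as in [regress_on_patch()].
#' @export
encounter_regression <- function(polar, predictor = c("delta", "r"),
                                 level = 0.9) {
  predictor <- match.arg(predictor)
  if (!"segment" %in% names(polar)) polar$segment <- polar$trip_id
  d <- dplyr::group_by(polar, .data$trip_id, .data$segment) |>
    dplyr::mutate(x_lag1 = dplyr::lag(.data[[predictor]])) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$x_lag1))
  if (sum(d$E) == 0) stop("no encounters in the data")
  fit <- glm(E ~ x_lag1, data = d, family = binomial())
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(vcov(fit)))[2]
  b <- coef(fit)[2]
  tibble::tibble(outcome = "E", predictor = paste0(predictor, "[t-1]"),
                 model = "logistic", estimate = unname(b),
                 conf.low = unname(b - z * se), conf.high = unname(b + z * se),
                 n = nrow(d))
}
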