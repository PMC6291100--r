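## Candidate step-size distributions and WAIC comparison. The Levy flight
## foraging hypothesis implies a heavy, power-law-like tail (Pareto); the
## alternatives are folded-normal and log-normal bodies. Each family is fit
## plain and with a free upper truncation point tau (density renormalised to
## (0, tau]), six models in all, and compared by the Watanabe-Akaike
## information criterion on the deviance scale.

DIST_FAMILIES <- c("folded_normal", "lognormal", "pareto")

dist_label <- function(family, truncated) {
  lab <- c(folded_normal = "Folded Normal", lognormal = "Log Normal",
           pareto = "Pareto")[[family]]
  if (truncated) paste("Truncated", lab) else lab
}

## log density / log CDF pairs; pars on the natural scale
dist_logpdf <- function(family, x, pars, x_min) {
  switch(family,
    folded_normal = {
      ## log(f(x; mu) + f(x; -mu)) via log-sum-exp: stable in the far tail
      la <- dnorm(x, pars[["mu"]], pars[["sigma"]], log = TRUE)
      lb <- dnorm(x, -pars[["mu"]], pars[["sigma"]], log = TRUE)
      m <- pmax(la, lb)
      m + log1p(exp(pmin(la, lb) - m))
    },
    lognormal = dlnorm(x, pars[["mu"]], pars[["sigma"]], log = TRUE),
    pareto = {
      k <- pars[["shape"]]
      ifelse(x >= x_min, log(k) + k * log(x_min) - (k + 1) * log(x), -Inf)
    }
  )
}

dist_logcdf <- function(family, q, pars, x_min) {
  switch(family,
    folded_normal = log(pnorm(q, pars[["mu"]], pars[["sigma"]]) -
                          pnorm(-q, pars[["mu"]], pars[["sigma"]])),
    lognormal = plnorm(q, pars[["mu"]], pars[["sigma"]], log.p = TRUE),
    pareto = log1p(-(x_min / q)^pars[["shape"]])
  )
}

#' Fit a candidate step-size distribution
#'
#' Bayesian fit of one of six models for positive step sizes: folded-normal,
#' log-normal or Pareto, each either plain or upper-truncated with a free
#' truncation point `tau` (likelihood `f(x) / F(tau)` for `x <= tau`, with
#' `tau` bounded below by the sample maximum and given a uniform prior on
#' `[max(r), 2 max(r)]`). Priors: location Normal(0, 5), scale and Pareto
#' shape Exponential(1). The Pareto lower bound is the smallest observed
#' (floored) step. Pointwise posterior log-likelihoods are stored for
#' [waic()].
#'
#' @param r Positive step sizes (metres per 10 s interval); values below
#'   `r_floor` are floored.
#' @param family `"folded_normal"`, `"lognormal"` or `"pareto"`.
#' @param truncated Logical; fit the upper-truncated variant?
#' @param sampler See [sampler_config()].
#' @param r_floor Floor (metres) for zero steps.
#' @param pointwise_draws Maximum number of posterior draws for which
#'   pointwise log-likelihoods are stored.
#' @return An `ars_dist_fit` with posterior draws, a parameter summary
#'   (medians and 95% credible intervals), the pointwise log-likelihood
#'   matrix, and its WAIC.
#' @export
fit_step_distribution <- function(r, family = DIST_FAMILIES, truncated = FALSE,
                                  sampler = sampler_config(),
                                  r_floor = 0.05, pointwise_draws = 500) {
  family <- match.arg(family)
  stopifnot(is.logical(truncated), length(truncated) == 1)
  r <- pmax(r[!is.na(r)], r_floor)
  n <- length(r)
  if (n < 100) stop("need at least 100 step sizes for a stable fit")
  x_min <- min(r)
  max_r <- max(r)
  base_pars <- switch(family,
    folded_normal = c("mu", "sigma"),
    lognormal = c("mu", "sigma"),
    pareto = "shape"
  )
  ## unconstrained parameterisation: sigma/shape on log scale, tau via logit
  to_natural <- function(th) {
    pars <- switch(family,
      folded_normal = c(mu = th[1], sigma = exp(th[2])),
      lognormal = c(mu = th[1], sigma = exp(th[2])),
      pareto = c(shape = exp(th[1]))
    )
    if (truncated) pars <- c(pars, tau = max_r * (1 + plogis(th[length(th)])))
    pars
  }
  log_prior <- function(th, pars) {
    lp <- switch(family,
      folded_normal = dnorm(pars[["mu"]], 0, 5, log = TRUE) +
        dexp(pars[["sigma"]], 1, log = TRUE) + th[2],
      lognormal = dnorm(pars[["mu"]], 0, 5, log = TRUE) +
        dexp(pars[["sigma"]], 1, log = TRUE) + th[2],
      pareto = dexp(pars[["shape"]], 1, log = TRUE) + th[1]
    )
    if (truncated) {
      p <- plogis(th[length(th)])
      lp <- lp - log(max_r) + log(max_r * p * (1 - p)) # uniform tau + Jacobian
    }
    lp
  }
  lp_fun <- function(th) {
    pars <- to_natural(th)
    ll <- sum(dist_logpdf(family, r, pars, x_min))
    if (truncated) ll <- ll - n * dist_logcdf(family, pars[["tau"]], pars, x_min)
    val <- ll + log_prior(th, pars)
    if (!is.finite(val)) -Inf else val
  }
  init <- switch(family,
    folded_normal = c(mean(r), log(sd(r))),
    lognormal = c(mean(log(r)), log(sd(log(r)))),
    pareto = log(1 / max(mean(log(r / x_min)), 0.05))
  )
  if (truncated) init <- c(init, 0)
  par_names <- c(base_pars, if (truncated) "tau")
  post <- sample_posterior(lp_fun, gr = NULL, init, sampler)
  nat <- apply(post$draws, 1, to_natural)
  nat <- if (is.null(dim(nat))) matrix(nat, ncol = 1) else t(nat)
  colnames(nat) <- par_names
  keep <- unique(round(seq(1, nrow(nat), length.out = min(pointwise_draws, nrow(nat)))))
  ll_mat <- t(apply(nat[keep, , drop = FALSE], 1, function(pars) {
    ll <- dist_logpdf(family, r, pars, x_min)
    if (truncated) ll <- ll - dist_logcdf(family, pars[["tau"]], pars, x_min)
    ll
  }))
  fit <- structure(list(family = family, truncated = truncated,
                        label = dist_label(family, truncated),
                        draws = nat, loglik = ll_mat, n = n,
                        x_min = x_min, max_r = max_r,
                        summary = summarise_draws_ci(nat, level = 0.95),
                        diagnostics = post$diagnostics),
                   class = "ars_dist_fit")
  fit$waic <- waic(ll_mat)
  fit
}

#' Watanabe-Akaike information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_i log mean_d exp(ll[d, i])`, `p_waic = sum_i var_d(ll[d, i])`,
#' `waic = -2 (lppd - p_waic)` (deviance scale; lower is better). The
#' standard error is `sqrt(n * var_i)` of the pointwise contributions.
#'
#' @param x A draws-by-observations matrix of pointwise log-likelihoods (at
#'   least 2 draws), or an `ars_dist_fit`.
#' @return A list with `waic`, `se`, `p_waic`, `lppd` and `n`.
#' @export
waic <- function(x) {
  if (inherits(x, "ars_dist_fit")) x <- x$loglik
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  if (!all(is.finite(x))) {
    bad <- which(!apply(is.finite(x), 2, all))
    stop("non-finite log-likelihoods for observation(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  D <- nrow(x)
  mx <- apply(x, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2, mx)))) # log-mean-exp, stable
  p_i <- apply(x, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), se = sqrt(length(waic_i) * var(waic_i)),
       p_waic = sum(p_i), lppd = sum(lppd_i), n = length(waic_i))
}

#' Compare fitted step-size distributions by WAIC
#'
#' @param ... `ars_dist_fit` objects (or a single list of them), all fit to
#'   the same data.
#' @return A tibble of class `ars_dist_comparison`, sorted by WAIC
#'   ascending, with `delta_waic` relative to the best model and Akaike
#'   weights proportional to `exp(-delta_waic / 2)` (summing to 1).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ars_dist_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "ars_dist_fit")))
  ns <- vapply(fits, `[[`, 0, "n")
  if (length(unique(ns)) != 1) {
    stop("fits were made on different data lengths: ",
         paste(ns, collapse = ", "))
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$label, family = f$family, truncated = f$truncated,
                   waic = f$waic$waic, se = f$waic$se, p_waic = f$waic$p_waic)
  })
  out <- dplyr::arrange(out, .data$waic)
  out$delta_waic <- out$waic - out$waic[1]
  w <- exp(-out$delta_waic / 2)
  out$weight <- w / sum(w)
  class(out) <- c("ars_dist_comparison", class(out))
  out
}

#' @rdname fit_step_distribution
#' @param x An `ars_dist_fit`.
#' @param ... Unused.
#' @export
tidy.ars_dist_fit <- function(x, ...) {
  x$summary
}

#' @rdname fit_step_distribution
#' @export
glance.ars_dist_fit <- function(x, ...) {
  tibble::tibble(model = x$label, family = x$family, truncated = x$truncated,
                 n = x$n, waic = x$waic$waic, p_waic = x$waic$p_waic,
                 accept_rate = x$diagnostics$accept_rate,
                 converged = x$diagnostics$converged)
}

#' @export
print.ars_dist_fit <- function(x, ...) {
  cat("<ars_dist_fit>", x$label, " n =", x$n,
      " WAIC =", round(x$waic$waic, 1), "\n")
  print(x$summary)
  invisible(x)
}

#' Plot a WAIC model comparison
#'
#' @param object An [compare_models()] table.
#' @param ... Unused.
#' @return A ggplot of WAIC (with +/- 1 SE bars) per model.
#' @export
autoplot.ars_dist_comparison <- function(object, ...) {
  d <- dplyr::mutate(object, model = factor(.data$model, rev(.data$model)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$waic, y = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$waic - .data$se,
                                          xmax = .data$waic + .data$se)) +
    ggplot2::labs(x = "WAIC (deviance scale)", y = NULL,
                  title = "Step-size distribution comparison") +
    ggplot2::theme_minimal()
}
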