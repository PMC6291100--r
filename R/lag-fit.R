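## Lagged Bayesian regressions of movement on past prey encounters.
##
## Turning angles delta in [0, 1] follow a Beta regression,
##   delta[t] ~ Beta(mu[t] * nu, (1 - mu[t]) * nu),
##   mu[t] = logit^-1(psi0 + sum_s psi[s] * E[t - s]),
## so psi[s] is the effect, on the log-odds scale, of an encounter s steps
## ago on the expected turning angle now. Step sizes follow a log-normal
## regression, log r[t] ~ Normal(phi0 + sum_s phi[s] * E[t - s], omega).
## Area-restricted search predicts psi[s] > 0 and phi[s] < 0 at short lags;
## a non-conditional Levy forager has psi[s] = phi[s] = 0 (and uniform
## turning angles: psi0 = 0, nu = 2).

#' Priors for the lagged regressions
#'
#' Weakly informative defaults: intercepts Normal(0, 5), lag coefficients
#' independent Normal(0, 1), dispersion (nu or omega) Exponential(0.1), AR-1
#' coefficient Normal(0, 1). `smooth_sd` optionally adds a first-difference
#' (random-walk) penalty across adjacent lag coefficients; it is off
#' (`NULL`) by default so lags are a priori exchangeable.
#'
#' @param intercept_sd,lag_sd,rho_sd Normal prior standard deviations.
#' @param disp_rate Rate of the exponential prior on the dispersion.
#' @param smooth_sd Standard deviation of the optional random-walk smoothing
#'   prior on successive lag coefficients, or `NULL` for none.
#' @return A list of class `ars_lag_priors`.
#' @export
lag_priors <- function(intercept_sd = 5, lag_sd = 1, disp_rate = 0.1,
                       rho_sd = 1, smooth_sd = NULL) {
  stopifnot(intercept_sd > 0, lag_sd > 0, disp_rate > 0, rho_sd > 0,
            is.null(smooth_sd) || smooth_sd > 0)
  structure(list(intercept_sd = intercept_sd, lag_sd = lag_sd,
                 disp_rate = disp_rate, rho_sd = rho_sd,
                 smooth_sd = smooth_sd),
            class = "ars_lag_priors")
}

#' Fit the lagged Beta regression of turning angle on encounters
#'
#' @param design An [build_lag_design()] object with outcome `"delta"`.
#' @param priors See [lag_priors()].
#' @param sampler See [sampler_config()].
#' @return An `ars_lag_fit`: posterior draws of `psi0`, `psi[1..S]`, `nu`
#'   (natural scale), a summary tibble of medians and central 90% credible
#'   intervals, and sampler diagnostics. Use [tidy()], [glance()],
#'   [autoplot()] and [first_crossing_lag()] on it.
#' @export
fit_beta_lag <- function(design, priors = lag_priors(),
                         sampler = sampler_config()) {
  fit_lag(design, model = "beta", variant = "plain", priors, sampler)
}

#' Fit the lagged log-normal regression of step size on encounters
#'
#' @inheritParams fit_beta_lag
#' @return An `ars_lag_fit` with draws of `phi0`, `phi[1..S]`, `omega`.
#' @export
fit_lognormal_lag <- function(design, priors = lag_priors(),
                              sampler = sampler_config()) {
  fit_lag(design, model = "lognormal", variant = "plain", priors, sampler)
}

#' Robustness variants of the lagged regressions
#'
#' `variant = "ar1"` adds a lag-1 autoregressive term on the link scale (the
#' previous outcome, link-transformed and centred, with coefficient `rho`) to
#' control for temporal autocorrelation. `variant = "split"` estimates
#' separate lag curves for the two encounter types (prey shot-and-hit versus
#' not), since post-hit behaviour may reflect item recovery rather than
#' continued search.
#'
#' @inheritParams fit_beta_lag
#' @param model `"beta"` (turning angle) or `"lognormal"` (step size).
#' @param variant `"ar1"` or `"split"`.
#' @return An `ars_lag_fit`.
#' @export
fit_lag_variant <- function(design, model = c("beta", "lognormal"),
                            variant = c("ar1", "split"),
                            priors = lag_priors(),
                            sampler = sampler_config()) {
  fit_lag(design, match.arg(model), match.arg(variant), priors, sampler)
}

fit_lag <- function(design, model, variant, priors, sampler) {
  stopifnot(inherits(design, "ars_lag_design"))
  beta_model <- model == "beta"
  if (beta_model && design$outcome != "delta") {
    stop("Beta lag model needs the 'delta' outcome")
  }
  if (!beta_model && design$outcome != "r") {
    stop("log-normal lag model needs the 'r' outcome")
  }
  S <- design$S
  sym <- if (beta_model) "psi" else "phi"
  y <- design$y
  keep <- rep(TRUE, design$n)
  z <- NULL
  if (variant == "ar1") {
    keep <- !is.na(design$prev)
    prev <- design$prev[keep]
    z <- if (beta_model) qlogis(squeeze_unit(prev, sum(keep))) else
      log(pmax(prev, design$r_floor))
    z <- z - mean(z)
  }
  if (variant == "split" && is.null(design$X_hit)) {
    stop("split variant requires encounter kinds (E_kind) in the data")
  }
  M <- switch(variant,
    plain = cbind(1, design$X),
    ar1 = cbind(1, design$X[keep, , drop = FALSE], z),
    split = cbind(1, design$X_hit, design$X_nonhit)
  )
  y <- y[keep]
  n <- length(y)
  lag_names <- function(suffix) paste0(sym, suffix, "[", seq_len(S), "]")
  par_names <- switch(variant,
    plain = c(paste0(sym, "0"), lag_names("")),
    ar1 = c(paste0(sym, "0"), lag_names(""), "rho"),
    split = c(paste0(sym, "0"), lag_names("_hit"), lag_names("_nonhit"))
  )
  k <- length(par_names)
  prior_sd <- rep(priors$lag_sd, k)
  prior_sd[1] <- priors$intercept_sd
  if (variant == "ar1") prior_sd[k] <- priors$rho_sd
  lag_idx <- grep("\\[", par_names) + 0 # columns of M holding lag coefficients
  smooth <- priors$smooth_sd
  prior_extra <- function(b) {
    if (is.null(smooth)) return(0)
    s <- 0
    for (grp in split(lag_idx, sub("\\[.*", "", par_names[lag_idx]))) {
      s <- s + sum(dnorm(diff(b[grp]), 0, smooth, log = TRUE))
    }
    s
  }
  grad_extra <- function(b) {
    g <- numeric(k)
    if (is.null(smooth)) return(g)
    for (grp in split(lag_idx, sub("\\[.*", "", par_names[lag_idx]))) {
      d <- diff(b[grp]) / smooth^2
      g[grp] <- g[grp] + c(d, 0) - c(0, d)
    }
    g
  }
  if (beta_model) {
    yb <- squeeze_unit(y, n)
    ld <- log(yb); l1d <- log1p(-yb)
    lp <- function(th) {
      b <- th[seq_len(k)]; lnu <- th[k + 1]; nu <- exp(lnu)
      mu <- plogis(drop(M %*% b))
      a <- mu * nu; bb <- (1 - mu) * nu
      sum(lgamma(nu) - lgamma(a) - lgamma(bb) + (a - 1) * ld + (bb - 1) * l1d) +
        sum(dnorm(b, 0, prior_sd, log = TRUE)) + prior_extra(b) +
        dexp(nu, priors$disp_rate, log = TRUE) + lnu
    }
    gr <- function(th) {
      b <- th[seq_len(k)]; lnu <- th[k + 1]; nu <- exp(lnu)
      mu <- plogis(drop(M %*% b))
      a <- mu * nu; bb <- (1 - mu) * nu
      u <- ld - digamma(a); v <- l1d - digamma(bb)
      w <- nu * (u - v) * mu * (1 - mu)
      gb <- drop(crossprod(M, w)) - b / prior_sd^2 + grad_extra(b)
      gnu <- sum(digamma(nu) + mu * u + (1 - mu) * v)
      c(gb, (gnu - priors$disp_rate) * nu + 1)
    }
    init <- c(qlogis(mean(yb)), numeric(k - 1), log(5))
    disp_name <- "nu"
  } else {
    ly <- log(pmax(y, design$r_floor))
    lp <- function(th) {
      b <- th[seq_len(k)]; lom <- th[k + 1]; om <- exp(lom)
      eta <- drop(M %*% b)
      sum(dnorm(ly, eta, om, log = TRUE)) - sum(ly) +
        sum(dnorm(b, 0, prior_sd, log = TRUE)) + prior_extra(b) +
        dexp(om, priors$disp_rate, log = TRUE) + lom
    }
    gr <- function(th) {
      b <- th[seq_len(k)]; lom <- th[k + 1]; om <- exp(lom)
      res <- ly - drop(M %*% b)
      gb <- drop(crossprod(M, res)) / om^2 - b / prior_sd^2 + grad_extra(b)
      gom <- (sum(res^2) / om^2 - n) / om
      c(gb, (gom - priors$disp_rate) * om + 1)
    }
    init <- c(mean(ly), numeric(k - 1), log(sd(ly)))
    disp_name <- "omega"
  }
  post <- sample_posterior(lp, gr, init, sampler,
                           param_names = c(par_names, paste0("log_", disp_name)))
  draws <- post$draws
  draws[, k + 1] <- exp(draws[, k + 1])
  colnames(draws)[k + 1] <- disp_name
  summary <- summarise_draws_ci(draws, level = 0.9)
  summary$role <- "lag"
  summary$role[1] <- "intercept"
  summary$role[k + 1] <- "dispersion"
  if (variant == "ar1") summary$role[k] <- "ar1"
  summary$lag <- NA_integer_
  summary$lag[summary$role == "lag"] <-
    as.integer(sub(".*\\[(\\d+)\\]", "\\1", summary$term[summary$role == "lag"]))
  summary$kind <- NA_character_
  if (variant == "split") {
    summary$kind[grepl("_hit\\[", summary$term)] <- "hit"
    summary$kind[grepl("_nonhit\\[", summary$term)] <- "nonhit"
  }
  structure(list(model = model, variant = variant, outcome = design$outcome,
                 draws = draws, summary = summary, n = n, S = S,
                 priors = priors, sampler = sampler,
                 diagnostics = post$diagnostics),
            class = "ars_lag_fit")
}

#' First lag at which the credible intervals reach zero
#'
#' Scanning lags s = 1, 2, ..., returns the smallest s whose central 90%
#' credible interval fails to exclude zero on the stated side -- i.e. lag
#' effects are "significant" for all `s <` the returned value. Returns
#' `S + 1` when every interval excludes zero.
#'
#' @param fit An `ars_lag_fit`.
#' @param side `"above"` (effects significantly greater than zero; default
#'   for the Beta model) or `"below"` (less than zero; default for the
#'   log-normal model).
#' @param kind For split fits, which encounter-type curve to scan.
#' @return Integer lag index in `1..S + 1`.
#' @export
first_crossing_lag <- function(fit, side = NULL, kind = NULL) {
  stopifnot(inherits(fit, "ars_lag_fit"))
  side <- side %||% if (fit$model == "beta") "above" else "below"
  side <- match.arg(side, c("above", "below"))
  s <- fit$summary[fit$summary$role == "lag", ]
  if (fit$variant == "split") {
    if (is.null(kind)) stop("split fit: specify kind = 'hit' or 'nonhit'")
    s <- s[s$kind == kind, ]
  }
  s <- s[order(s$lag), ]
  crossed <- if (side == "above") s$conf.low <= 0 else s$conf.high >= 0
  idx <- which(crossed)
  if (length(idx) == 0) fit$S + 1L else s$lag[idx[1]]
}

#' @export
print.ars_lag_fit <- function(x, ...) {
  cat("<ars_lag_fit>", x$model, "model (", x$variant, "), outcome:",
      x$outcome, "\n  n =", x$n, ", S =", x$S,
      ", accept =", round(x$diagnostics$accept_rate, 2),
      ", max R-hat =", round(x$diagnostics$rhat_max, 3), "\n")
  print(x$summary[x$summary$role != "lag", ])
  invisible(x)
}

#' @rdname fit_beta_lag
#' @param x An `ars_lag_fit`.
#' @param ... Unused.
#' @export
tidy.ars_lag_fit <- function(x, ...) {
  x$summary
}

#' @rdname fit_beta_lag
#' @export
glance.ars_lag_fit <- function(x, ...) {
  tibble::tibble(model = x$model, variant = x$variant, outcome = x$outcome,
                 n = x$n, S = x$S,
                 accept_rate = x$diagnostics$accept_rate,
                 rhat_max = x$diagnostics$rhat_max,
                 converged = x$diagnostics$converged)
}

#' Plot the posterior lag-effect curve
#'
#' Medians and 90% credible intervals of the lag coefficients against lag,
#' with a zero reference line; split fits are faceted by encounter kind.
#'
#' @param object An `ars_lag_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ars_lag_fit <- function(object, ...) {
  s <- object$summary[object$summary$role == "lag", ]
  if (object$variant != "split") s$kind <- "all"
  ggplot2::ggplot(s, ggplot2::aes(x = .data$lag, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(
      x = "lag s (10 s steps)",
      y = if (object$model == "beta") expression(psi[s]) else expression(phi[s]),
      title = sprintf("Lagged effect of encounters on %s",
                      if (object$model == "beta") "turning angle" else "step size")
    ) +
    ggplot2::theme_minimal()
}
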