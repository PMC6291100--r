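## Posterior computation used by all Bayesian fits in the package.
##
## The posteriors here (lagged Beta / log-normal regressions at n in the
## thousands, and 2-4 parameter distribution fits) are smooth and unimodal,
## so we locate the posterior mode with BFGS on the log posterior (analytic
## gradients where supplied), take a Laplace (negative inverse Hessian)
## Gaussian approximation, and then correct it by independence
## Metropolis-Hastings with a heavy-tailed multivariate-t proposal centred at
## the mode. Acceptance rates are high because the large-n posteriors are
## close to Gaussian; the MH correction makes the draws exact samples from
## the stated posterior, not from the approximation. Multiple chains give a
## split R-hat convergence diagnostic.

#' Sampler settings for the package's posterior fits
#'
#' @param chains Number of independent MH chains.
#' @param iter Post-warmup draws kept per chain.
#' @param warmup Burn-in iterations discarded per chain.
#' @param proposal_df Degrees of freedom of the multivariate-t independence
#'   proposal (heavier than the Gaussian Laplace approximation so tails are
#'   dominated).
#' @param proposal_inflate Scalar inflation of the Laplace covariance used in
#'   the proposal.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `ars_sampler_config`.
#' @export
sampler_config <- function(chains = 4, iter = 1000, warmup = 250,
                           proposal_df = 8, proposal_inflate = 1.1,
                           seed = NULL) {
  stopifnot(chains >= 1, iter >= 2, warmup >= 0, proposal_df > 2,
            proposal_inflate > 0)
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 proposal_df = proposal_df, proposal_inflate = proposal_inflate,
                 seed = seed),
            class = "ars_sampler_config")
}

## central-difference gradient for low-dimensional targets
num_grad <- function(f, x, h = 1e-5) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h * max(1, abs(x[j]))
    g[j] <- (f(x + e) - f(x - e)) / (2 * e[j])
  }
  g
}

## posterior mode + Laplace covariance factor
map_laplace <- function(lp, gr, init) {
  if (is.null(gr)) gr <- function(th) num_grad(lp, th)
  fit <- optim(init, lp, gr, method = "BFGS",
               control = list(fnscale = -1, maxit = 1000, reltol = 1e-12))
  th0 <- fit$par
  p <- length(th0)
  H <- matrix(0, p, p)
  h <- 1e-4
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h * max(1, abs(th0[j]))
    H[, j] <- (gr(th0 + e) - gr(th0 - e)) / (2 * e[j])
  }
  H <- (H + t(H)) / 2
  ## ridge until the negative Hessian is positive definite
  ridge <- 0
  repeat {
    U <- tryCatch(chol(-H + diag(ridge, p)), error = function(e) NULL)
    if (!is.null(U)) break
    ridge <- if (ridge == 0) 1e-8 * max(1, max(abs(diag(H)))) else ridge * 10
    if (ridge > 1e6) stop("posterior Hessian could not be stabilised")
  }
  Sigma_chol <- chol(chol2inv(U)) # upper triangular, Sigma = t(U) %*% U
  list(mode = th0, Sigma_chol = Sigma_chol, lp_mode = fit$value,
       converged = fit$convergence == 0, ridge = ridge)
}

## independence Metropolis-Hastings around the Laplace approximation
sample_posterior <- function(lp, gr = NULL, init, config = sampler_config(),
                             param_names = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  la <- map_laplace(lp, gr, init)
  p <- length(la$mode)
  R <- la$Sigma_chol * sqrt(config$proposal_inflate)
  df <- config$proposal_df
  log_prop <- function(z2) -(df + p) / 2 * log1p(z2 / df) # up to a constant
  chains <- vector("list", config$chains)
  n_acc <- 0L
  n_tot <- 0L
  for (ch in seq_len(config$chains)) {
    cur <- la$mode
    lp_cur <- lp(cur)
    lq_cur <- log_prop(0)
    niter <- config$warmup + config$iter
    out <- matrix(NA_real_, niter, p)
    for (i in seq_len(niter)) {
      z <- rnorm(p) / sqrt(rchisq(1, df) / df)
      prop <- la$mode + drop(z %*% R)
      lp_prop <- lp(prop)
      if (is.finite(lp_prop) &&
          log(runif(1)) < (lp_prop - lp_cur) - (log_prop(sum(z^2)) - lq_cur)) {
        cur <- prop; lp_cur <- lp_prop; lq_cur <- log_prop(sum(z^2))
        n_acc <- n_acc + 1L
      }
      out[i, ] <- cur
    }
    n_tot <- n_tot + niter
    chains[[ch]] <- out[(config$warmup + 1):niter, , drop = FALSE]
  }
  draws <- do.call(rbind, chains)
  if (!is.null(param_names)) colnames(draws) <- param_names
  rhat <- split_rhat(chains)
  accept <- n_acc / n_tot
  diag <- list(accept_rate = accept,
               rhat_max = max(rhat, na.rm = TRUE),
               map_converged = la$converged,
               ridge = la$ridge)
  diag$converged <- la$converged && accept > 0.02 && diag$rhat_max < 1.1
  if (!diag$converged) {
    warning(sprintf(
      "posterior fit may not have converged (accept = %.3f, max R-hat = %.3f); summaries are still reported",
      accept, diag$rhat_max))
  }
  list(draws = draws, chains = chains, mode = la$mode, diagnostics = diag)
}

## split R-hat (each chain halved) per parameter
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    if (n < 4) return(rep(NA_real_, ncol(chains[[1]])))
    halves <- c(halves, list(ch[1:(n %/% 2), , drop = FALSE],
                             ch[(n %/% 2 + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  sapply(seq_len(ncol(halves[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), 0)
    vars <- vapply(halves, function(h) var(h[, j]), 0)
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

## median + central credible interval summary of a draws matrix
summarise_draws_ci <- function(draws, level = 0.9) {
  a <- (1 - level) / 2
  tibble::tibble(
    term = colnames(draws),
    estimate = apply(draws, 2, median),
    conf.low = apply(draws, 2, quantile, a),
    conf.high = apply(draws, 2, quantile, 1 - a)
  )
}
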