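mini_polar <- function(E, delta = NULL, r = NULL, trip = "t1") {
  n <- length(E)
  if (is.null(r)) r <- rep(2, n)
  if (is.null(delta)) delta <- rep(0.3, n)
  tibble::tibble(
    trip_id = rep(trip, n), segment = rep(trip, n),
    r = r, delta = delta, E = as.integer(E)
  )
}

test_that("lag design records within-trip encounter history only", {
  pol <- mini_polar(c(0, 0, 1, 0))
  des <- build_lag_design(pol, "delta", S = 2)
  expect_equal(dim(des$X), c(4, 2))
  expect_equal(des$X[4, ], c(1, 0)) # E[3] = 1 at lag 1, E[2] = 0 at lag 2
  expect_equal(des$X[1, ], c(0, 0)) # pre-trip lags are zero
  ## two concatenated trips: trip-1 encounter contributes nothing to trip 2
  pol2 <- dplyr::bind_rows(mini_polar(c(0, 0, 0, 1), trip = "a"),
                           mini_polar(c(0, 0, 0, 0), trip = "b"))
  des2 <- build_lag_design(pol2, "delta", S = 3)
  expect_true(all(des2$X[5:8, ] == 0))
  ## S must be smaller than the longest trip
  expect_error(build_lag_design(pol, "delta", S = 4), "smaller than")
})

test_that("rows with undefined turning angles are excluded from the design", {
  pol <- mini_polar(c(0, 1, 0, 0, 0), delta = c(NA, 0.2, NA, 0.4, 0.5))
  des <- build_lag_design(pol, "delta", S = 2)
  expect_equal(des$n, 3)
  expect_equal(des$y, c(0.2, 0.4, 0.5))
  expect_equal(des$X[2, ], c(0, 1)) # lags still indexed by step, not by row
})

test_that("beta lag fit recovers a known step curve", {
  S <- 15
  cfg <- sim_config(n_trips = 4, n_steps = 800, S = S, psi0 = -1, nu = 4,
                    psi = c(rep(0.8, 8), rep(0, 7)),
                    phi = numeric(S), encounter_rate = 0.03)
  covered <- c(); crossings <- c()
  for (s in 1:2) {
    d <- simulate_from_lag_model(cfg, seed = 200 + s)
    des <- build_lag_design(sim_to_polar(d), "delta", S = S)
    fit <- fit_beta_lag(des, sampler = test_sampler(300 + s))
    lagrows <- dplyr::arrange(dplyr::filter(tidy(fit), role == "lag"), lag)
    covered <- c(covered, lagrows$conf.low <= cfg$psi & cfg$psi <= lagrows$conf.high)
    crossings <- c(crossings, first_crossing_lag(fit))
    expect_true(all(tidy(fit)$conf.low <= tidy(fit)$estimate))
    expect_gt(min(fit$draws[, "nu"]), 0)
  }
  expect_gte(mean(covered), 0.7)
  expect_true(all(abs(crossings - 9) <= 3))
})

test_that("log-normal lag fit recovers a known negative step curve", {
  S <- 15
  cfg <- sim_config(n_trips = 4, n_steps = 800, S = S, phi0 = 0.64,
                    omega = 0.9, psi = numeric(S),
                    phi = c(rep(-0.6, 8), rep(0, 7)), encounter_rate = 0.03)
  d <- simulate_from_lag_model(cfg, seed = 210)
  des <- build_lag_design(sim_to_polar(d), "r", S = S)
  fit <- fit_lognormal_lag(des, sampler = test_sampler(310))
  lagrows <- dplyr::arrange(dplyr::filter(tidy(fit), role == "lag"), lag)
  expect_gte(mean(lagrows$conf.low <= cfg$phi & cfg$phi <= lagrows$conf.high), 0.7)
  expect_lte(abs(first_crossing_lag(fit) - 9), 3)
  om <- tidy(fit)[tidy(fit)$role == "dispersion", ]
  expect_lt(abs(om$estimate - 0.9), 0.05)
})

test_that("with no encounters the beta fit matches a direct ML beta fit", {
  skip_if_not_installed("fitdistrplus")
  set.seed(77)
  n <- 3000
  y <- rbeta(n, 2, 3)
  pol <- mini_polar(numeric(n), delta = y)
  des <- build_lag_design(pol, "delta", S = 5)
  fit <- fit_beta_lag(des, sampler = test_sampler(88))
  mle <- fitdistrplus::fitdist(y, "beta")$estimate
  mu_mle <- mle[["shape1"]] / (mle[["shape1"]] + mle[["shape2"]])
  nu_mle <- mle[["shape1"]] + mle[["shape2"]]
  mu_draws <- plogis(fit$draws[, "psi0"])
  expect_lt(abs(median(mu_draws) - mu_mle), 0.02)
  expect_lt(abs(median(fit$draws[, "nu"]) - nu_mle), 0.2)
  ## MLE lies inside the central 99% posterior interval
  expect_true(quantile(mu_draws, 0.005) < mu_mle &&
                mu_mle < quantile(mu_draws, 0.995))
})

test_that("AR-1 variant covers rho = 0 on serially independent data", {
  S <- 10
  cfg <- sim_config(n_trips = 2, n_steps = 700, S = S, psi = numeric(S),
                    phi = numeric(S), encounter_rate = 0.02)
  covers <- vapply(1:5, function(s) {
    d <- simulate_from_lag_model(cfg, seed = 400 + s)
    des <- build_lag_design(sim_to_polar(d), "delta", S = S)
    fit <- fit_lag_variant(des, "beta", "ar1", sampler = test_sampler(410 + s))
    rho <- tidy(fit)[tidy(fit)$role == "ar1", ]
    rho$conf.low <= 0 && 0 <= rho$conf.high
  }, TRUE)
  expect_gte(sum(covers), 4)
})

test_that("split variant gives overlapping curves when kinds are identical", {
  S <- 12
  cfg <- sim_config(n_trips = 4, n_steps = 700, S = S,
                    psi = rep(0.5, S), phi = numeric(S),
                    encounter_rate = 0.03)
  d <- simulate_from_lag_model(cfg, seed = 55)
  pol <- sim_to_polar(d)
  ## assign kinds at random: both kinds share the same true effect
  set.seed(56)
  pol$E_kind[pol$E == 1] <- sample(c("hit", "nonhit"), sum(pol$E), TRUE)
  des <- build_lag_design(pol, "delta", S = S)
  fit <- fit_lag_variant(des, "beta", "split", sampler = test_sampler(57))
  td <- dplyr::filter(tidy(fit), role == "lag")
  hit <- dplyr::arrange(dplyr::filter(td, kind == "hit"), lag)
  non <- dplyr::arrange(dplyr::filter(td, kind == "nonhit"), lag)
  overlap <- hit$conf.low <= non$conf.high & non$conf.low <= hit$conf.high
  expect_gte(mean(overlap), 0.8)
  expect_equal(nrow(td), 2 * S)
})

test_that("split variant requires encounter kinds", {
  pol <- mini_polar(c(0, 1, 0, 0, 0, 0)) # no E_kind column
  des <- build_lag_design(pol, "delta", S = 2)
  expect_error(fit_lag_variant(des, "beta", "split"), "E_kind")
  expect_error(fit_beta_lag(build_lag_design(pol, "r", S = 2)), "delta")
})

test_that("AR-1 control preserves the sign pattern of significant effects", {
  S <- 12
  cfg <- sim_config(n_trips = 4, n_steps = 800, S = S,
                    psi = rep(0.8, S), phi = numeric(S), encounter_rate = 0.03)
  d <- simulate_from_lag_model(cfg, seed = 70)
  des <- build_lag_design(sim_to_polar(d), "delta", S = S)
  plain <- fit_beta_lag(des, sampler = test_sampler(71))
  ar1 <- fit_lag_variant(des, "beta", "ar1", sampler = test_sampler(72))
  sig_pos <- function(f) {
    td <- dplyr::arrange(dplyr::filter(tidy(f), role == "lag"), lag)
    td$conf.low > 0
  }
  ## significant-positive lags under the AR-1 control stay a recognisable
  ## superset/subset: require agreement at 80% of lags
  expect_gte(mean(sig_pos(plain) == sig_pos(ar1)), 0.8)
})

test_that("first crossing returns S + 1 when no interval reaches zero", {
  fake <- structure(list(
    model = "beta", variant = "plain", S = 4L,
    summary = tibble::tibble(
      term = c("psi0", paste0("psi[", 1:4, "]"), "nu"),
      estimate = c(0, 1, 1, 1, 1, 4),
      conf.low = c(-1, 0.5, 0.5, 0.5, 0.5, 3),
      conf.high = c(1, 1.5, 1.5, 1.5, 1.5, 5),
      role = c("intercept", rep("lag", 4), "dispersion"),
      lag = c(NA, 1:4, NA), kind = NA_character_
    )), class = "ars_lag_fit")
  expect_equal(first_crossing_lag(fake), 5L)
  fake$summary$conf.low[4] <- -0.1 # lag 3 interval now includes zero
  expect_equal(first_crossing_lag(fake), 3L)
  expect_equal(first_crossing_lag(fake, side = "below"), 1L)
})

test_that("posterior mu draws stay in (0, 1) and dispersions positive", {
  S <- 8
  cfg <- sim_config(n_trips = 2, n_steps = 400, S = S, encounter_rate = 0.02)
  d <- simulate_from_lag_model(cfg, seed = 91)
  des <- build_lag_design(sim_to_polar(d), "delta", S = S)
  fit <- fit_beta_lag(des, sampler = test_sampler(92, iter = 200))
  mu <- plogis(fit$draws[, "psi0"])
  expect_true(all(mu > 0 & mu < 1))
  expect_true(all(fit$draws[, "nu"] > 0))
  desr <- build_lag_design(sim_to_polar(d), "r", S = S)
  fitr <- fit_lognormal_lag(desr, sampler = test_sampler(93, iter = 200))
  expect_true(all(fitr$draws[, "omega"] > 0))
  expect_true(all(exp(fitr$draws[, "phi0"]) > 0))
  g <- glance(fitr)
  expect_true(is.finite(g$rhat_max))
})
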