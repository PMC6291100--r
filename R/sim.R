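## Forager simulator. Three generators share one configuration:
##   * simulate_from_lag_model(): the lagged Beta / log-normal observation
##     model run generatively, with an exogenous encounter sequence;
##   * simulate_forager(mode = "ars"): an agent whose turning angle and step
##     size respond to its own prey encounters (through the same lag curves)
##     while moving through a clustered (Thomas-process) prey field;
##   * simulate_forager(mode = "levy"): non-conditional Levy flight --
##     uniform turning angles, truncated-Pareto step lengths -- in the same
##     prey field, with encounters recorded but ignored by movement.

#' Simulation configuration
#'
#' Defaults emulate the structure of a multi-trip blowgun-hunt data set: 6
#' trips of 1,100 fixes at a 10 s cadence (about 6,600 fixes in all), sparse
#' encounters near 1.5% of fixes, turning angles whose mean rises after an
#' encounter and decays over tens of lags, and log-normal step sizes whose
#' log-mean drops after an encounter. The default lag-effect curves are
#' smooth exponential decays `psi[s] = lag_effect_delta * exp(-s / lag_decay)`
#' and `phi[s] = -lag_effect_r * exp(-s / lag_decay)`; pass explicit `psi` /
#' `phi` vectors to override.
#'
#' @param n_trips,n_steps Trips per simulation and steps per trip.
#' @param cadence_s Fix spacing, seconds.
#' @param S Lag horizon of the generative curves.
#' @param psi0,nu Intercept (log-odds) and precision of the Beta turning-angle
#'   model.
#' @param phi0,omega Intercept (log metres) and log-scale SD of the
#'   log-normal step-size model.
#' @param psi,phi Optional explicit lag-effect vectors of length `S`.
#' @param lag_effect_delta,lag_effect_r,lag_decay Parameters of the default
#'   exponential-decay curves (effect sizes at lag 0+, decay constant in
#'   steps).
#' @param encounter_rate Bernoulli rate of exogenous encounters (used by
#'   [simulate_from_lag_model()]).
#' @param p_hit Probability that a simulated encounter is of kind `"hit"`.
#' @param kappa Prey cluster intensity, clusters per square km.
#' @param cluster_mean Mean prey items per cluster.
#' @param cluster_sd Gaussian scatter of items around the cluster centre,
#'   metres.
#' @param half_width Half-width of the square simulation arena, metres.
#' @param detection_radius Prey detection radius, metres.
#' @param levy_alpha Power-law density exponent of Levy steps
#'   (`f(x) ~ x^-alpha`, `alpha > 1`; the Pareto shape is `alpha - 1`).
#' @param levy_xmin,levy_xmax Lower bound and truncation of Levy step
#'   lengths, metres.
#' @param origin Geographic origin `c(lon, lat)` used when exporting
#'   simulated tracks to GPX.
#' @param seed Integer seed recorded in the config and used by the
#'   generators.
#' @return A list of class `ars_sim_config`.
#' @export
sim_config <- function(n_trips = 6, n_steps = 1100, cadence_s = 10,
                       S = 90, psi0 = -1, nu = 4, phi0 = 0.64, omega = 0.9,
                       psi = NULL, phi = NULL,
                       lag_effect_delta = 1, lag_effect_r = 0.6,
                       lag_decay = 30,
                       encounter_rate = 0.015, p_hit = 0.15,
                       kappa = 40, cluster_mean = 25, cluster_sd = 30,
                       half_width = 1500, detection_radius = 20,
                       levy_alpha = 2, levy_xmin = 1, levy_xmax = 500,
                       origin = c(-75.9, 4.9), seed = NULL) {
  if (is.null(psi)) psi <- lag_effect_delta * exp(-seq_len(S) / lag_decay)
  if (is.null(phi)) phi <- -lag_effect_r * exp(-seq_len(S) / lag_decay)
  stopifnot(length(psi) == S, length(phi) == S,
            n_trips >= 1, n_steps >= 2, cadence_s > 0,
            kappa >= 0, cluster_mean > 0, cluster_sd > 0, half_width > 0,
            detection_radius > 0, encounter_rate >= 0, encounter_rate <= 1,
            p_hit >= 0, p_hit <= 1,
            levy_alpha > 1, levy_xmin > 0, levy_xmax > levy_xmin)
  if (nu <= 0) stop("nu must be positive")
  if (omega <= 0) stop("omega must be positive")
  structure(as.list(environment()), class = "ars_sim_config")
}

#' Simulate a clustered prey field
#'
#' Thomas-type Poisson cluster process on the square arena: parent (cluster)
#' count Poisson(`kappa` x area), items per cluster Poisson(`cluster_mean`),
#' items scattered around their parent with isotropic Gaussian sd
#' `cluster_sd`. Expected total items: `kappa * area_km2 * cluster_mean`.
#'
#' @param config An [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A tibble of prey coordinates `x`, `y` (metres) with a `cluster`
#'   index.
#' @export
gen_prey_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ars_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  hw <- config$half_width
  area_km2 <- (2 * hw / 1000)^2
  n_parents <- rpois(1, config$kappa * area_km2)
  if (n_parents == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), cluster = integer(0)))
  }
  px <- runif(n_parents, -hw, hw)
  py <- runif(n_parents, -hw, hw)
  n_off <- rpois(n_parents, config$cluster_mean)
  cl <- rep(seq_len(n_parents), n_off)
  tibble::tibble(
    x = rep(px, n_off) + rnorm(sum(n_off), 0, config$cluster_sd),
    y = rep(py, n_off) + rnorm(sum(n_off), 0, config$cluster_sd),
    cluster = cl
  )
}

## lag contribution at step t from past encounter steps (sparse form)
lag_contribution <- function(enc_steps, t, curve) {
  if (length(enc_steps) == 0) return(0)
  s <- t - enc_steps
  s <- s[s >= 1 & s <= length(curve)]
  sum(curve[s])
}

#' Draw turning angles and step sizes from the lag model
#'
#' Runs the lagged observation model generatively: given an exogenous
#' encounter sequence, draws `delta[t] ~ Beta(mu[t] nu, (1 - mu[t]) nu)` and
#' `r[t] ~ LogNormal(eta[t], omega)` with `mu[t]` and `eta[t]` determined by
#' the configured lag curves.
#'
#' @param config An [sim_config()] (supplies curves, intercepts, dispersions).
#' @param E Encounter indicator sequence: a 0/1 vector (one trip), or a list
#'   of such vectors (one per trip). `NULL` draws
#'   Bernoulli(`config$encounter_rate`) sequences for `config$n_trips` trips.
#' @param seed Seed (defaults to `config$seed`).
#' @return A tibble with columns `trip_id`, `step`, `E`, `mu`, `eta`,
#'   `delta`, `r`.
#' @export
simulate_from_lag_model <- function(config, E = NULL, seed = config$seed) {
  stopifnot(inherits(config, "ars_sim_config"))
  if (config$nu <= 0) stop("nu must be positive")
  if (config$omega <= 0) stop("omega must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(E)) {
    E <- replicate(config$n_trips,
                   rbinom(config$n_steps, 1, config$encounter_rate),
                   simplify = FALSE)
  }
  if (!is.list(E)) E <- list(E)
  purrr::imap_dfr(E, function(e, i) {
    stopifnot(all(e %in% c(0, 1)))
    m <- length(e)
    enc <- which(e == 1)
    lin_d <- config$psi0 + vapply(seq_len(m), lag_contribution, 0,
                                  enc_steps = enc, curve = config$psi)
    lin_r <- config$phi0 + vapply(seq_len(m), lag_contribution, 0,
                                  enc_steps = enc, curve = config$phi)
    mu <- plogis(lin_d)
    tibble::tibble(
      trip_id = paste0("sim_", i), step = seq_len(m), E = as.integer(e),
      mu = mu, eta = lin_r,
      delta = rbeta(m, mu * config$nu, (1 - mu) * config$nu),
      r = rlnorm(m, lin_r, config$omega)
    )
  })
}

## truncated Pareto sampler: density ~ x^-alpha on [xmin, xmax]
rtrunc_pareto <- function(n, alpha, xmin, xmax) {
  k <- alpha - 1
  u <- runif(n)
  xmin * (1 - u * (1 - (xmin / xmax)^k))^(-1 / k)
}

#' Simulate a foraging track through a prey field
#'
#' In `"ars"` mode the agent turning angle and step size are drawn from
#' the lag model, fed by its own encounter history: after each move, any
#' prey item within `detection_radius` triggers an encounter at that fix
#' (and is removed from the field), which raises subsequent turning angles
#' and lowers subsequent step sizes through the configured lag curves. In
#' `"levy"` mode turning angles are uniform on the unit interval and steps are
#' truncated-Pareto; encounters are recorded identically but movement
#' ignores them. Each trip gets an independently generated prey field.
#'
#' @param config An [sim_config()].
#' @param mode `"ars"` or `"levy"`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A list of class `ars_sim`: `track` (an [as_ars_track()] with
#'   synthetic timestamps and geographic coordinates), `prey` (per-trip prey
#'   coordinates), `truth` (the generating parameters) and `mode`.
#' @export
simulate_forager <- function(config, mode = c("ars", "levy"),
                             seed = config$seed) {
  stopifnot(inherits(config, "ars_sim_config"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  trips <- vector("list", config$n_trips)
  preys <- vector("list", config$n_trips)
  for (trip in seq_len(config$n_trips)) {
    prey <- gen_prey_field(config, seed = NULL)
    alive <- rep(TRUE, nrow(prey))
    n <- config$n_steps
    x <- numeric(n); y <- numeric(n)
    E <- integer(n); kind <- rep("none", n)
    heading <- runif(1, -pi, pi)
    cx <- 0; cy <- 0
    enc <- integer(0)
    d2 <- config$detection_radius^2
    for (t in seq_len(n)) {
      if (mode == "ars") {
        mu <- plogis(config$psi0 + lag_contribution(enc, t, config$psi))
        delta <- rbeta(1, mu * config$nu, (1 - mu) * config$nu)
        r <- rlnorm(1, config$phi0 + lag_contribution(enc, t, config$phi),
                    config$omega)
      } else {
        delta <- runif(1)
        r <- rtrunc_pareto(1, config$levy_alpha, config$levy_xmin,
                           config$levy_xmax)
      }
      heading <- heading + sample(c(-1, 1), 1) * delta * pi
      cx <- cx + r * cos(heading)
      cy <- cy + r * sin(heading)
      x[t] <- cx; y[t] <- cy
      if (any(alive)) {
        near <- alive & abs(prey$x - cx) < config$detection_radius &
          abs(prey$y - cy) < config$detection_radius
        if (any(near)) {
          near[near] <- (prey$x[near] - cx)^2 + (prey$y[near] - cy)^2 <= d2
          if (any(near)) {
            E[t] <- 1L
            kind[t] <- if (runif(1) < config$p_hit) "hit" else "nonhit"
            alive[near] <- FALSE
            enc <- c(enc, t)
          }
        }
      }
    }
    trips[[trip]] <- tibble::tibble(
      trip_id = sprintf("sim_%d", trip),
      t = seq_len(n) * config$cadence_s,
      x = x, y = y, E = E, E_kind = kind
    )
    preys[[trip]] <- dplyr::mutate(prey, trip_id = sprintf("sim_%d", trip))
  }
  fixes <- dplyr::bind_rows(trips)
  ll <- unproject_xy(fixes$x, fixes$y, config$origin)
  fixes$lon <- ll$lon
  fixes$lat <- ll$lat
  t0 <- as.POSIXct("2017-04-01 06:00:00", tz = "UTC")
  fixes$time <- t0 + 86400 * (match(fixes$trip_id, unique(fixes$trip_id)) - 1) +
    fixes$t
  track <- as_ars_track(fixes, cadence_s = config$cadence_s,
                        origin = config$origin)
  structure(list(track = track, prey = dplyr::bind_rows(preys),
                 truth = config[c("psi0", "psi", "nu", "phi0", "phi", "omega",
                                  "levy_alpha", "levy_xmin", "levy_xmax")],
                 mode = mode, config = config),
            class = "ars_sim")
}

#' @export
print.ars_sim <- function(x, ...) {
  cat("<ars_sim>", x$mode, "mode:", length(unique(x$track$trip_id)),
      "trips,", nrow(x$track), "fixes,", sum(x$track$E), "encounters (",
      sprintf("%.2f%%", 100 * mean(x$track$E)), ")\n")
  invisible(x)
}
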