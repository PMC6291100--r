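## Shared fixtures: all built in code at test time.

## a light sampler for tests; seeds are always passed explicitly
test_sampler <- function(seed, chains = 2, iter = 400, warmup = 120) {
  sampler_config(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

## planar track at fixed cadence from coordinate vectors
make_track <- function(x, y, E = 0L, trip_id = "t1", cadence = 10,
                       elev = NA_real_, E_kind = NULL) {
  df <- data.frame(trip_id = trip_id, t = (seq_along(x) - 1) * cadence,
                   x = x, y = y, elev = elev,
                   E = rep_len(E, length(x)))
  if (!is.null(E_kind)) df$E_kind <- E_kind
  as_ars_track(df, cadence_s = cadence)
}

## minimal GPX file; times are ISO strings, ele optional, waypoints optional
write_mini_gpx <- function(path, lat, lon, times, ele = NULL, name = "hunt",
                           wpt = NULL) {
  pts <- vapply(seq_along(lat), function(i) {
    e <- if (!is.null(ele)) sprintf("<ele>%.1f</ele>", ele[i]) else ""
    tm <- if (!is.na(times[i])) sprintf("<time>%s</time>", times[i]) else ""
    sprintf('<trkpt lat="%.7f" lon="%.7f">%s%s</trkpt>', lat[i], lon[i], e, tm)
  }, "")
  wl <- if (!is.null(wpt)) {
    sprintf('<wpt lat="%.7f" lon="%.7f"><time>%s</time><name>%s</name></wpt>',
            wpt$lat, wpt$lon, wpt$time, wpt$name)
  } else character(0)
  writeLines(c('<?xml version="1.0"?>', '<gpx version="1.1" creator="test">',
               wl, "<trk>", sprintf("<name>%s</name>", name), "<trkseg>",
               pts, "</trkseg>", "</trk>", "</gpx>"), path)
  path
}

## polar-shaped tibble from a simulate_from_lag_model() draw, ready for
## build_lag_design() / label_patches()
sim_to_polar <- function(sim) {
  sim$segment <- sim$trip_id
  sim$E_kind <- ifelse(sim$E == 1, "hit", "none")
  sim
}

## brute-force WAIC oracle: plain loops, independent of the package code
waic_oracle <- function(ll) {
  D <- nrow(ll); n <- ncol(ll)
  lppd <- 0; p <- 0; waic_i <- numeric(n)
  for (i in seq_len(n)) {
    m <- mean(exp(ll[, i]))
    v <- sum((ll[, i] - mean(ll[, i]))^2) / (D - 1)
    lppd <- lppd + log(m)
    p <- p + v
    waic_i[i] <- -2 * (log(m) - v)
  }
  list(waic = -2 * (lppd - p), p_waic = p, lppd = lppd)
}
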