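test_that("GPX trackpoints are read with timestamps, elevation and cadence", {
  f <- withr::local_tempfile(fileext = ".gpx")
  write_mini_gpx(f, lat = c(4.9, 4.9001, 4.9002), lon = c(-75.9, -75.9, -75.9),
                 times = sprintf("2017-04-01T06:00:%02dZ", c(0, 10, 20)),
                 ele = c(1500, 1501, 1503))
  tr <- read_gpx_track(f)
  expect_s3_class(tr, "ars_track")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$t, c(0, 10, 20))
  expect_equal(tr$elev, c(1500, 1501, 1503))
  cad <- attr(tr, "cadence")
  expect_true(cad$cadence_ok)
  expect_equal(cad$n_gaps, 0)
})

test_that("untimed and degenerate GPX inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".gpx")
  write_mini_gpx(f, lat = c(4.9, 4.9001), lon = c(-75.9, -75.9),
                 times = c("2017-04-01T06:00:00Z", NA))
  expect_error(read_gpx_track(f), "untimed track")
  f2 <- withr::local_tempfile(fileext = ".gpx")
  write_mini_gpx(f2, lat = 4.9, lon = -75.9, times = "2017-04-01T06:00:00Z")
  expect_error(read_gpx_track(f2), "degenerate track")
  expect_error(as_ars_track(data.frame(x = 1, y = 1)), "untimed|degenerate")
})

test_that("projection round-trips to sub-centimetre over a 10 km span", {
  lon <- -75.9 + seq(0, 0.09, length.out = 50) # ~10 km east-west
  lat <- 4.9 + seq(0, 0.04, length.out = 50)
  xy <- project_lonlat(lon, lat)
  back <- unproject_xy(xy$x, xy$y, attr(xy, "origin"))
  xy2 <- project_lonlat(back$lon, back$lat, attr(xy, "origin"))
  expect_lt(max(abs(xy2$x - xy$x), abs(xy2$y - xy$y)), 0.01)
  expect_gt(max(xy$x) - min(xy$x), 9000)
})

test_that("encounter annotations flag the nearest fix, ties to the earlier", {
  tr <- make_track(x = seq(0, 100, by = 10), y = 0)
  tr$time <- as.POSIXct("2017-04-01 06:00:00", tz = "UTC") + tr$t
  ann <- tibble::tibble(
    time = tr$time[3] + c(0, 4, 5), # exact, nearest-forward, tie
    kind = c("hit", "nonhit", "nonhit")
  )
  ## exact hit on fix 3
  out <- align_encounters(tr, ann[1, ])
  expect_equal(which(out$E == 1), 3)
  expect_equal(out$E_kind[3], "hit")
  ## 4 s after fix 3 -> still fix 3
  out <- align_encounters(tr, ann[2, ])
  expect_equal(which(out$E == 1), 3)
  ## 5 s after fix 3 is equidistant to fixes 3 and 4 -> earlier fix wins
  out <- align_encounters(tr, ann[3, ])
  expect_equal(which(out$E == 1), 3)
  ## outside range + tolerance errors and names the offender
  bad <- tibble::tibble(time = max(tr$time) + 60, kind = "hit")
  expect_error(align_encounters(tr, bad), "outside track time range")
})

test_that("alignment never flags more fixes than there are annotations", {
  set.seed(42)
  tr <- make_track(x = cumsum(rnorm(80, 2)), y = cumsum(rnorm(80)))
  tr$time <- as.POSIXct("2017-04-01 06:00:00", tz = "UTC") + tr$t
  for (k in c(1, 5, 12)) {
    ann <- tibble::tibble(time = sample(tr$time, k) + runif(k, -4, 4),
                          kind = sample(c("hit", "nonhit"), k, TRUE))
    out <- align_encounters(tr, ann)
    expect_lte(sum(out$E), k)
  }
})

test_that("hunt summaries compute distance, duration, speed and elevation", {
  tr <- make_track(x = c(0, 5), y = c(0, 0))
  hs <- hunt_summary(tr)
  expect_equal(hs$dist_km, 0.005)
  expect_equal(hs$duration_hr, 10 / 3600)
  expect_equal(hs$avg_speed_kmh, 1.8)
  expect_true(is.na(hs$elev_change_m)) # absent elevation, not zero
  expect_true(is.na(hs$n_shots))
  ## straight line of 11 fixes, 2 m apart
  tr2 <- make_track(x = seq(0, 20, by = 2), y = 0)
  expect_equal(hunt_summary(tr2)$dist_km, 0.020)
})

test_that("summary distance is invariant to rotation and translation", {
  set.seed(11)
  x <- cumsum(rnorm(60, 1)); y <- cumsum(rnorm(60, 1))
  d0 <- hunt_summary(make_track(x, y))$dist_km
  for (ang in c(0.3, 1.2, 2.9)) {
    xr <- cos(ang) * x - sin(ang) * y + 500
    yr <- sin(ang) * x + cos(ang) * y - 200
    expect_equal(hunt_summary(make_track(xr, yr))$dist_km, d0)
  }
})

test_that("cadence gaps split trips into segments and are reported", {
  t <- c(0, 10, 20, 60, 70, 80) # 2 missed fixes between rows 3 and 4
  tr <- as_ars_track(data.frame(t = t, x = seq_along(t), y = 0))
  expect_equal(length(unique(tr$segment)), 2)
  expect_equal(attr(tr, "cadence")$n_splits, 1)
  pol <- to_polar(tr)
  expect_equal(nrow(pol), 4) # no step across the gap
})

test_that("tracks round-trip through GPX writer and reader", {
  cfg <- sim_config(n_trips = 2, n_steps = 120, seed = 5)
  sim <- simulate_forager(cfg, "ars")
  f <- withr::local_tempfile(fileext = ".gpx")
  write_gpx_track(sim$track, f)
  tr2 <- read_gpx_track(f, origin = cfg$origin)
  expect_equal(nrow(tr2), nrow(sim$track))
  expect_lt(max(abs(tr2$x - sim$track$x)), 0.005) # 8-decimal lon/lat precision
  tr2 <- align_encounters(tr2, read_gpx_waypoints(f))
  expect_equal(sum(tr2$E), sum(sim$track$E))
  expect_equal(tr2$E_kind, sim$track$E_kind)
})

test_that("the pipeline writes all four report sections deterministically", {
  cfg <- pipeline_config(
    sim = sim_config(n_trips = 2, n_steps = 250, S = 20),
    S = 10, W = 20, seed = 9,
    sampler = sampler_config(chains = 2, iter = 150, warmup = 60)
  )
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- suppressWarnings(run_pipeline(cfg, out1))
  files <- c("hunt_summaries.csv", "lag_beta.csv", "lag_lognormal.csv",
             "crossing_lags.csv", "dist_comparison.csv", "patch_stats.csv")
  expect_true(all(file.exists(file.path(out1, files))))
  expect_equal(nrow(res$dist_comparison), 6)
  suppressWarnings(run_pipeline(cfg, out2))
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
  }
})

test_that("pipeline configuration rejects missing inputs and zero lags", {
  expect_error(pipeline_config(S = 0), "at least one lag")
  cfg <- pipeline_config(tracks = "/no/such/file.gpx", S = 5)
  expect_error(run_pipeline(cfg, withr::local_tempdir()), "not found")
})
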