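test_that("scenarios are fully deterministic given their configuration", {
  a <- simulate_scenario(test_config("coastal", seed = 21, days = 3))
  b <- simulate_scenario(test_config("coastal", seed = 21, days = 3))
  expect_identical(a$survey$effort, b$survey$effort)
  expect_identical(a$survey$sightings, b$survey$sightings)
  expect_identical(a$fields$static$depth$values, b$fields$static$depth$values)
  expect_identical(a$truth$N_true, b$truth$N_true)
  # different seed, different survey
  c <- simulate_scenario(test_config("coastal", seed = 22, days = 3))
  expect_false(identical(a$survey$effort, c$survey$effort))
})

test_that("the coastline is a simple polygon with peninsula and gulf", {
  cfg <- test_config("coastal")
  geom <- make_coastline(cfg)
  expect_false(coastdsm:::.ring_self_intersects(geom$region))
  yp <- cfg$peninsula_frac * cfg$extent[2]
  yg <- cfg$gulf_frac * cfg$extent[2]
  expect_gt(geom$coast_x(yp), cfg$coast_base_x + 0.9 * cfg$peninsula_depth)
  expect_lt(geom$coast_x(yg), cfg$coast_base_x - 0.5 * cfg$gulf_depth)
  # flat-coast control used by the leakage comparison
  flat <- make_coastline(test_config("coastal", peninsula_depth = 0,
                                     gulf_depth = 0))
  expect_equal(flat$coast_x(100), flat$coast_x(200))
  # shoelace area vs fine rasterization
  a_shoe <- polygon_area(geom$region)
  step <- 1
  gx <- seq(step / 2, 300, by = step)
  pts <- as.matrix(expand.grid(gx, gx))
  a_rast <- sum(point_in_polygon(pts, geom$region)) * step^2
  expect_lt(abs(a_shoe / a_rast - 1), 0.005)
  expect_error(make_coastline(test_config("coastal", peninsula_depth = 500)),
               "outside the region")
})

test_that("covariate fields match their stated construction", {
  cfg <- test_config("coastal", seed = 31)
  geom <- make_coastline(cfg)
  f <- make_covariate_fields(cfg, geom)
  sea <- f$sea
  depth <- as.vector(f$static$depth$values)
  dc <- as.vector(f$static$dist_coast$values)
  # depth near zero at the coast, maximal offshore
  expect_lt(min(depth[sea & dc < 3], na.rm = TRUE), 15)
  expect_gt(stats::cor(depth[sea], dc[sea], use = "complete"), 0.9)
  # SST spans roughly the configured 4-19 range over months
  sst_all <- unlist(lapply(f$dynamic$sst, function(g) g$values[!is.na(g$values)]))
  expect_lt(min(sst_all), 7)
  expect_gt(max(sst_all), 15)
  expect_gt(min(sst_all), 0); expect_lt(max(sst_all), 23)
  # cloud mask: configured missing fraction, none when disabled
  miss <- vapply(f$dynamic$chla, function(g) mean(is.na(g$values[sea])), 0)
  expect_true(all(abs(miss - cfg$cloud_fraction) < 0.12))
  f0 <- make_covariate_fields(test_config("coastal", seed = 31,
                                          cloud_fraction = 0), geom)
  expect_true(all(vapply(f0$dynamic$chla,
                         function(g) !anyNA(g$values[sea]), TRUE)))
})

test_that("the density surface obeys its closed forms", {
  # zero effects: uniform intensity, N_true = exp(b0) * area
  cfg <- test_config("coastal", seed = 41, coastal_decay_km = 1e9, b0 = -2, hotspot_amp = 0)
  geom <- make_coastline(cfg)
  f <- make_covariate_fields(cfg, geom)
  tr <- make_density_surface(cfg, geom, f)
  sea_area <- sum(f$sea) * cfg$cell_km^2
  expect_equal(tr$N_true, exp(-2) * sea_area, tolerance = 1e-6)
  # intercept shift scales the total log-linearly
  cfg2 <- test_config("coastal", seed = 41, coastal_decay_km = 1e9, b0 = -1, hotspot_amp = 0)
  tr2 <- make_density_surface(cfg2, geom, f)
  expect_equal(tr2$N_true / tr$N_true, exp(1), tolerance = 1e-9)
  # coastal decay concentrates mass against the shore
  cfgd <- test_config("coastal", seed = 41)
  trd <- make_density_surface(cfgd, geom, f)
  lam <- as.vector(trd$lambda[[1]]$values)
  dc <- as.vector(f$static$dist_coast$values)
  inshore <- !is.na(lam) & dc <= 5 * cfgd$coastal_decay_km
  expect_gt(sum(lam[inshore]) / sum(lam, na.rm = TRUE), 0.99)
})

test_that("group sizes reproduce both reported moment pairs", {
  set.seed(51)
  for (tgt in list(c(2, 2.28, 20), c(3.4, 2.1, 15))) {
    gs <- ztnb_params(tgt[1], tgt[2], tgt[3])
    expect_equal(gs$mean, tgt[1], tolerance = 1e-4)
    expect_equal(gs$sd, tgt[2], tolerance = 1e-4)
    x <- sample.int(tgt[3], 1e5, replace = TRUE, prob = gs$pmf)
    expect_equal(mean(x), tgt[1], tolerance = 0.03)
    expect_equal(stats::sd(x), tgt[2], tolerance = 0.05)
    expect_gte(min(x), 1)
  }
})

test_that("survey counts match quadrature expectations and thin with width", {
  cfg <- test_config("coastal", seed = 61, days = 2)
  scn <- simulate_scenario(cfg)
  geom <- scn$geom; truth <- scn$truth

  # zero density -> zero sightings
  t0 <- truth
  for (k in names(t0$lambda)) t0$lambda[[k]]$values[] <- 0
  s0 <- simulate_survey(t0, cfg, geom)
  expect_equal(nrow(s0$sightings), 0)

  # fixed tracks: Monte-Carlo mean in-strip individuals vs line quadrature,
  # and halving the strip width halving the expectation
  tracks <- scn$survey$tracks_xy
  reps <- 150
  cfg_half <- test_config("coastal", seed = 61, days = 2,
                          half_width_km = cfg$half_width_km / 2)
  tot_w <- numeric(reps); tot_half <- numeric(reps)
  for (i in seq_len(reps)) {
    ci <- cfg; ci$seed <- 1000L + i
    tot_w[i] <- sum(simulate_survey(truth, ci, geom, tracks)$sightings$group_size)
    ch <- cfg_half; ch$seed <- 5000L + i
    tot_half[i] <- sum(simulate_survey(truth, ch, geom, tracks)$sightings$group_size)
  }
  day_month <- scn$survey$day_month
  expected <- sum(vapply(seq_along(tracks), function(d) {
    segs <- segment_track(tracks[[d]], 10, cfg$half_width_km, "t")
    sum(expected_segment_counts(truth, tracks[[d]], segs,
                                cfg$half_width_km, day_month[d]))
  }, 0))
  mc_se <- stats::sd(tot_w) / sqrt(reps)
  expect_lt(abs(mean(tot_w) - expected), 3 * mc_se + 0.03 * expected)
  expect_equal(mean(tot_w) / mean(tot_half), 2, tolerance = 0.2)
})
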