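straight_track <- function(L, step = 0.5) cbind(seq(0, L, by = step), 0)

test_that("tracks divide into round(L/target) equal segments", {
  s <- segment_track(straight_track(30), 10, 0.3)
  expect_equal(nrow(s), 3)
  expect_equal(s$length, rep(10, 3))
  expect_equal(s$area, rep(2 * 0.3 * 10, 3))

  s2 <- segment_track(straight_track(26), 10, 0.3)
  expect_equal(nrow(s2), 3)
  expect_equal(s2$length, rep(26 / 3, 3), tolerance = 1e-12)

  expect_error(segment_track(cbind(c(0, 0), c(0, 0)), 10, 0.3), "degenerate")
})

test_that("segment lengths conserve track length for random tracks", {
  set.seed(3)
  for (i in 1:500) {
    n <- sample(3:20, 1)
    xy <- cbind(cumsum(runif(n, -3, 5)), cumsum(runif(n, -4, 4)))
    L <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
    if (L <= 0) next
    s <- segment_track(xy, 10, 0.3)
    expect_equal(sum(s$length), L, tolerance = 1e-9)
    # contiguity: each segment starts where the previous ended
    expect_equal(s$s0[-1], s$s1[-nrow(s)], tolerance = 1e-12)
    expect_equal(nrow(s), max(1, round(L / 10)))
  }
})

test_that("strip half-width selection reproduces the field choices", {
  # 23 initial distances, none beyond 280 m -> 300 m
  set.seed(4)
  d1 <- runif(23, 10, 280)
  expect_equal(select_strip_halfwidth(d1), 300)
  # 79 distances, exactly 2 beyond 600 m -> 600 m (77/79 = 0.975 >= 0.97)
  d2 <- c(runif(77, 350, 600), 700, 900)
  expect_equal(select_strip_halfwidth(d2), 600)
  expect_equal(select_strip_halfwidth(rep(50, 12)), 100)
  expect_error(select_strip_halfwidth(runif(9, 0, 100)), "fewer than 10")
})

test_that("sightings land in the right segments with strip filtering", {
  sp <- proj_spec(0, 0)
  # straight 30 km track due east along the equator
  km_per_deg <- 111.19493
  lons <- seq(0, 30 / km_per_deg, length.out = 61)
  eff <- data.frame(survey_day_id = "d1",
                    timestamp = format(as.POSIXct("2013-01-05 09:00",
                                                  tz = "UTC") +
                                         seq_along(lons) * 120,
                                       "%Y-%m-%dT%H:%M:%S"),
                    lon = lons, lat = 0)
  eff$timestamp <- as.POSIXct(eff$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S")
  tracks <- build_tracks(eff, sp)
  segs <- segment_tracks(tracks, 10, half_width = 0.3)
  expect_equal(nrow(segs), 3)

  mk_sight <- function(km_along, km_off, size) {
    data.frame(timestamp = as.POSIXct("2013-01-05 10:00", tz = "UTC"),
               lon = km_along / km_per_deg, lat = km_off / km_per_deg,
               species = "sp", group_size = size,
               radial_distance_m = abs(km_off) * 1000, bearing_deg = 90,
               initial_location = 1)
  }
  # outside the strip (0.4 km > 0.3 km) excluded; mid-segment school of 5 in
  sgt <- rbind(mk_sight(5, 0.4, 3), mk_sight(15, 0.1, 5))
  out <- assign_sightings(segs, sgt, tracks, sp, 0.3)
  expect_equal(out$count, c(0, 5, 0))
  out_sch <- assign_sightings(segs, sgt, tracks, sp, 0.3, unit = "schools")
  expect_equal(out_sch$count, c(0, 1, 0))

  # 200 random sightings vs a brute-force point-in-rectangle count
  set.seed(5)
  along <- runif(200, 0, 30); off <- runif(200, -0.6, 0.6)
  sgt2 <- do.call(rbind, lapply(1:200, function(i)
    mk_sight(along[i], off[i], 1L)))
  out2 <- assign_sightings(segs, sgt2, tracks, sp, 0.3)
  brute <- vapply(1:3, function(j) {
    sum(abs(off) <= 0.3 + 1e-9 & along >= (j - 1) * 10 & along < j * 10)
  }, 0L)
  expect_equal(out2$count, brute)
  expect_equal(sum(out2$count), sum(abs(off) <= 0.3 + 1e-9))

  # widening the strip never decreases any count
  out3 <- assign_sightings(segs, sgt2, tracks, sp, 0.5)
  expect_true(all(out3$count >= out2$count))

  # a sighting on an unsurveyed day is excluded with a warning
  sgt3 <- mk_sight(5, 0.1, 2)
  sgt3$timestamp <- as.POSIXct("2013-02-20 10:00", tz = "UTC")
  expect_warning(out4 <- assign_sightings(segs, sgt3, tracks, sp, 0.3),
                 "no matching survey day")
  expect_equal(attr(out4, "excluded"), 1L)
})

test_that("effort and count conservation hold on a simulated survey", {
  fx <- scenario_fixture("coastal", 11)
  track_len <- sum(vapply(fx$tracks, function(tr) {
    sum(sqrt(diff(tr$xy[, 1])^2 + diff(tr$xy[, 2])^2))
  }, 0))
  expect_equal(sum(fx$segs$length), track_len, tolerance = 1e-9)
  expect_equal(fx$segs$area, 2 * fx$segs$half_width * fx$segs$length)
  # every simulated sighting is in-strip by construction, so counts conserve
  expect_equal(sum(fx$segs$count), sum(fx$sightings$group_size))
})

test_that("implausible vessel speeds and bad effort files are rejected", {
  sp <- proj_spec(0, 0)
  eff <- data.frame(survey_day_id = "d1",
                    timestamp = as.POSIXct("2013-01-05 09:00", tz = "UTC") +
                      c(0, 60),
                    lon = c(0, 1), lat = c(0, 0))   # ~111 km in a minute
  expect_error(build_tracks(eff, sp), "implausible speed")
  eff$timestamp <- rep(eff$timestamp[1], 2)
  expect_error(build_tracks(eff, sp), "non-increasing")
})
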