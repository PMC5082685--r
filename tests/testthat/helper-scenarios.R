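# Shared fixtures: reduced-size scenarios and cached expensive objects.
# Reduced settings (300 km region, 15 days, 2 months) are the desk-scale
# stand-in for the full 600 km / 55 day world; chosen once, not tuned.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_config <- function(kind = "coastal", seed = 11, ...) {
  if (kind == "coastal") {
    scenario_config("coastal", seed = seed, extent = c(300, 300), days = 15,
                    km_per_day = 120, half_width_km = 0.5,
                    target_total = 8000,
                    survey_months = c("2013-01", "2013-02"), ...)
  } else {
    scenario_config("shelf", seed = seed, extent = c(300, 300), days = 15,
                    km_per_day = 120, half_width_km = 0.6,
                    target_total = 8000,
                    survey_months = c("2013-01", "2013-02"), ...)
  }
}

# simulate + segmentize + annotate, returning everything a model needs
prep_survey <- function(scn) {
  cfg <- scn$config
  eff <- scn$survey$effort
  eff$timestamp <- as.POSIXct(eff$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S")
  sig <- scn$survey$sightings
  sig$timestamp <- as.POSIXct(sig$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S")
  pspec <- scn$survey$proj
  tracks <- build_tracks(eff, pspec)
  segs <- segment_tracks(tracks, 10, cfg$half_width_km)
  segs <- assign_sightings(segs, sig, tracks, pspec, cfg$half_width_km)
  segs <- suppressMessages(
    annotate_segments(segs, static = scn$fields$static,
                      dynamic = scn$fields$dynamic,
                      coastline = scn$geom$coastline))
  list(segs = segs, tracks = tracks, sightings = sig, effort = eff,
       pspec = pspec)
}

scenario_fixture <- function(kind = "coastal", seed = 11) {
  cached(paste0("scn_", kind, "_", seed), {
    scn <- simulate_scenario(test_config(kind, seed))
    c(scn, prep_survey(scn))
  })
}

# one cached coastal soap-film fit used by several test files
coastal_fit_fixture <- function() {
  cached("coastal_fit", {
    fx <- scenario_fixture("coastal", 11)
    soap <- build_soap_film(fx$geom$region, n_knots = 40,
                            vars = c("cx", "cy"))
    fit <- suppressMessages(
      fit_gam(count ~ s(cx, cy, bs = "so", xt = soap$xt), fx$segs,
              family = dsm_family("nb"), knots = soap$knots))
    grid <- build_grid(fx$geom$region, 100)
    grid <- annotate_grid(grid, static = fx$fields$static,
                          coastline = fx$geom$coastline)
    list(fx = fx, soap = soap, fit = fit, grid = grid)
  })
}

# small deterministic segment table for fast GLM-level tests
toy_segments <- function(n = 60, seed = 42) {
  set.seed(seed)
  x <- runif(n, -1, 1)
  area <- runif(n, 5, 15)
  eta <- 0.2 + 0.8 * x
  data.frame(count = rnbinom(n, size = 2, mu = area * exp(eta) * 0.05),
             x = x, area = area,
             transect_id = rep(paste0("t", 1:5), each = n / 5),
             seg_index = rep(seq_len(n / 5), 5))
}
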