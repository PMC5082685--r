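#' Read an effort (trackline) CSV
#'
#' Expected columns: `survey_day_id`, `timestamp` (ISO 8601), `lon`, `lat`.
#'
#' @param path CSV path.
#' @return data.frame with parsed `timestamp` (POSIXct, UTC).
#' @export
read_effort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("survey_day_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("effort CSV missing column(s): ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$timestamp)) stop("effort CSV has unparseable timestamps")
  df
}

#' Read a sightings CSV
#'
#' Expected columns: `timestamp`, `lon`, `lat`, `species`, `group_size`,
#' `radial_distance_m`, `bearing_deg`, `initial_location` (0/1).
#'
#' @param path CSV path.
#' @return data.frame with parsed `timestamp`.
#' @export
read_sightings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "lon", "lat", "species", "group_size",
            "radial_distance_m", "bearing_deg", "initial_location")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sightings CSV missing column(s): ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$timestamp)) stop("sightings CSV has unparseable timestamps")
  if (any(df$group_size < 1)) stop("group_size must be >= 1")
  if (any(df$radial_distance_m < 0)) stop("radial_distance_m must be >= 0")
  df
}

#' Build projected daily tracklines from effort records
#'
#' Each survey day becomes one transect: fixes are ordered in time,
#' projected, and validated (at least two fixes, strictly increasing
#' timestamps, plausible inter-fix speed).
#'
#' @param effort data.frame as from [read_effort_csv()].
#' @param spec a [proj_spec()].
#' @param max_speed_kmh maximum plausible vessel speed between fixes; the
#'   surveys emulated here ran near 10 knots (~18.5 km/h), so the default 30
#'   flags only gross GPS errors.
#' @return named list of tracks; each has `xy` (projected km), `time`,
#'   `date`, `survey_day_id`.
#' @export
build_tracks <- function(effort, spec, max_speed_kmh = 30) {
  out <- list()
  for (day in unique(effort$survey_day_id)) {
    e <- effort[effort$survey_day_id == day, , drop = FALSE]
    e <- e[order(e$timestamp), , drop = FALSE]
    if (nrow(e) < 2) stop("survey day ", day, " has fewer than 2 fixes")
    dt <- as.numeric(diff(e$timestamp), units = "hours")
    if (any(dt <= 0)) stop("survey day ", day, " has non-increasing timestamps")
    xy <- project(cbind(e$lon, e$lat), spec)
    step <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    spd <- step / dt
    if (any(spd > max_speed_kmh))
      stop(sprintf("survey day %s has implausible speed %.1f km/h (max %.1f)",
                   day, max(spd), max_speed_kmh))
    out[[as.character(day)]] <- list(survey_day_id = day, xy = xy,
                                     time = e$timestamp,
                                     date = as.Date(e$timestamp[1], tz = "UTC"))
  }
  out
}

#' Cut one projected trackline into equal-length segments
#'
#' The transect of total arc length L is divided into `k = max(1,
#' round(L/target_length))` contiguous segments of equal length `L/k`, so
#' segment areas are never degenerate stubs and summed segment length equals
#' trackline length exactly.
#'
#' @param xy projected polyline (n x 2 matrix, km).
#' @param target_length nominal segment length (km), default 10.
#' @param half_width strip half-width w (km); segment area is `2*w*length`.
#' @param transect_id identifier copied onto each segment.
#' @return data.frame, one row per segment: endpoints of the chord between
#'   the cut points (`x0`,`y0`,`x1`,`y1`), centroid (`cx`,`cy`), arc `length`,
#'   `half_width`, `area`, `seg_index`, and the along-track cut positions
#'   (`s0`, `s1`) used to place sightings.
#' @export
segment_track <- function(xy, target_length = 10, half_width,
                          transect_id = "t1") {
  xy <- as.matrix(xy)
  cs <- .cum_arclength(xy)
  L <- cs[length(cs)]
  if (L <= 0) stop("degenerate track: zero length")
  if (target_length <= 0 || half_width <= 0)
    stop("target_length and half_width must be positive")
  k <- max(1L, as.integer(round(L / target_length)))
  cuts <- seq(0, L, length.out = k + 1)
  p <- .point_at_arclength(xy, cs, cuts)
  mid <- .point_at_arclength(xy, cs, (cuts[-1] + cuts[-(k + 1)]) / 2)
  len <- L / k
  data.frame(transect_id = transect_id, seg_index = seq_len(k),
             segment_id = paste0(transect_id, "-", seq_len(k)),
             x0 = p[-(k + 1), 1], y0 = p[-(k + 1), 2],
             x1 = p[-1, 1], y1 = p[-1, 2],
             cx = mid[, 1], cy = mid[, 2],
             s0 = cuts[-(k + 1)], s1 = cuts[-1],
             length = len, half_width = half_width,
             area = 2 * half_width * len,
             stringsAsFactors = FALSE)
}

#' Segment all daily tracklines
#'
#' @param tracks list from [build_tracks()].
#' @param target_length nominal segment length (km).
#' @param half_width strip half-width (km).
#' @return segment data.frame (all transects), with `year` and `month`
#'   columns taken from each track's date.
#' @export
segment_tracks <- function(tracks, target_length = 10, half_width) {
  segs <- lapply(tracks, function(tr) {
    s <- segment_track(tr$xy, target_length, half_width,
                       transect_id = as.character(tr$survey_day_id))
    s$year <- as.integer(format(tr$date, "%Y"))
    s$month <- as.integer(format(tr$date, "%m"))
    s
  })
  do.call(rbind, c(segs, list(make.row.names = FALSE)))
}

#' Select strip half-width from initial-location sighting distances
#'
#' Returns the smallest multiple of `rounding` metres that covers at least a
#' `coverage` fraction of the distances at which animals were first detected
#' (before any responsive approach to the vessel). This reproduces the
#' field practice of choosing 300 m when no initial sighting exceeded 300 m
#' and 600 m when only 2 of 79 exceeded 600 m.
#'
#' @param initial_distances_m radial distances (m) of initial-location
#'   sightings; at least 10 required.
#' @param coverage required coverage fraction (default 0.97).
#' @param rounding candidate widths are multiples of this (m, default 100).
#' @return half-width in metres.
#' @export
select_strip_halfwidth <- function(initial_distances_m, coverage = 0.97,
                                   rounding = 100) {
  d <- initial_distances_m[is.finite(initial_distances_m)]
  if (length(d) < 10)
    stop("fewer than 10 initial-location distances; set a fixed half-width ",
         "in the configuration instead")
  if (any(d < 0)) stop("distances must be nonnegative")
  w <- rounding
  while (mean(d <= w) < coverage) w <- w + rounding
  w
}

#' Assign sightings to segments as strip-transect counts
#'
#' Each sighting is matched to the trackline of its survey day (by calendar
#' date), its perpendicular distance to the trackline and its along-track
#' position are computed in the projected plane, and it contributes to the
#' segment containing that position iff the perpendicular distance does not
#' exceed the strip half-width. Contribution is `group_size` when counting
#' individuals, 1 when counting schools.
#'
#' @param segments segment data.frame from [segment_tracks()].
#' @param sightings data.frame as from [read_sightings_csv()].
#' @param tracks list from [build_tracks()].
#' @param spec a [proj_spec()].
#' @param half_width strip half-width (km).
#' @param unit `"individuals"` (default) or `"schools"`.
#' @param species optional species code filter.
#' @return `segments` with a `count` column; attribute `"excluded"` holds the
#'   number of sightings dropped for having no matching survey day.
#' @export
assign_sightings <- function(segments, sightings, tracks, spec, half_width,
                             unit = c("individuals", "schools"),
                             species = NULL) {
  unit <- match.arg(unit)
  if (!is.null(species))
    sightings <- sightings[sightings$species %in% species, , drop = FALSE]
  segments$count <- 0
  n_excluded <- 0L
  if (nrow(sightings)) {
    track_dates <- vapply(tracks, function(tr) as.character(tr$date), "")
    sdate <- as.character(as.Date(sightings$timestamp, tz = "UTC"))
    for (i in seq_len(nrow(sightings))) {
      j <- match(sdate[i], track_dates)
      if (is.na(j)) { n_excluded <- n_excluded + 1L; next }
      tr <- tracks[[j]]
      pxy <- project(cbind(sightings$lon[i], sightings$lat[i]), spec)
      pr <- .project_onto_polyline(pxy, tr$xy)
      if (pr$perp > half_width) next
      segs_t <- which(segments$transect_id == as.character(tr$survey_day_id))
      if (!length(segs_t)) next
      hit <- segs_t[pr$along >= segments$s0[segs_t] - 1e-9 &
                      pr$along <= segments$s1[segs_t] + 1e-9][1]
      if (is.na(hit)) next
      segments$count[hit] <- segments$count[hit] +
        if (unit == "individuals") sightings$group_size[i] else 1L
    }
  }
  if (n_excluded > 0)
    warning(n_excluded, " sighting(s) had no matching survey day and were excluded")
  attr(segments, "excluded") <- n_excluded
  segments
}

#' Annotate segments with environmental covariates
#'
#' Depth, SST and chlorophyll-a are averaged over each segment's rectangular
#' strip footprint; distance to coast is measured from the segment centroid.
#' Dynamic variables are taken from the raster of the segment's own
#' (year, month); a segment whose footprint is fully cloud-masked gets `NA`
#' for that variable (and is later dropped only from models that use it).
#'
#' @param segments segment data.frame (needs `year`, `month` for dynamics).
#' @param static named list of [ascii_grid()]s (e.g. `depth`).
#' @param dynamic named list of lists of [ascii_grid()]s keyed by
#'   `"YYYY-MM"` (e.g. `sst[["2013-01"]]`).
#' @param coastline coastline vertex matrix (projected km) for
#'   distance-to-coast; omit with `NULL`.
#' @return `segments` with covariate columns appended; attribute
#'   `"n_missing"` counts segment x dynamic-variable missing values.
#' @export
annotate_segments <- function(segments, static = list(), dynamic = list(),
                              coastline = NULL) {
  n <- nrow(segments)
  for (v in names(static)) {
    g <- static[[v]]
    segments[[v]] <- vapply(seq_len(n), function(i) {
      grid_mean_in_strip(g, c(segments$x0[i], segments$y0[i]),
                         c(segments$x1[i], segments$y1[i]),
                         segments$half_width[i])
    }, 0)
  }
  n_missing <- 0L
  for (v in names(dynamic)) {
    keys <- sprintf("%04d-%02d", segments$year, segments$month)
    segments[[v]] <- vapply(seq_len(n), function(i) {
      g <- dynamic[[v]][[keys[i]]]
      if (is.null(g)) return(NA_real_)
      grid_mean_in_strip(g, c(segments$x0[i], segments$y0[i]),
                         c(segments$x1[i], segments$y1[i]),
                         segments$half_width[i])
    }, 0)
    nm <- sum(is.na(segments[[v]]))
    if (nm) message(nm, " segment(s) have missing ", v,
                    " (cloud mask or no raster for the period)")
    n_missing <- n_missing + nm
  }
  if (!is.null(coastline)) {
    segments$dist_coast <- distance_to_coast(cbind(segments$cx, segments$cy),
                                             coastline)
  }
  attr(segments, "n_missing") <- n_missing
  segments
}

#' Write the segment table
#'
#' One row per segment with projected coordinates to 6 decimals.
#'
#' @param segments annotated segment data.frame.
#' @param path CSV path.
#' @export
write_segments_csv <- function(segments, path) {
  out <- segments
  for (v in c("x0", "y0", "x1", "y1", "cx", "cy", "s0", "s1", "length", "area"))
    if (v %in% names(out)) out[[v]] <- round(out[[v]], 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
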