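#' Read a WKT POLYGON or LINESTRING of projected coordinates
#'
#' Minimal reader for the plain-text geometry files the pipeline exchanges
#' (single ring / single line, no holes).
#'
#' @param path file containing one WKT geometry.
#' @return two-column coordinate matrix.
#' @export
read_wkt <- function(path) {
  txt <- paste(readLines(path), collapse = " ")
  nums <- regmatches(txt, gregexpr("-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", txt))[[1]]
  v <- as.numeric(nums)
  if (length(v) < 4 || length(v) %% 2 != 0) stop("cannot parse WKT in ", path)
  matrix(v, ncol = 2, byrow = TRUE)
}

.default_config <- function() {
  list(
    seed = 1,
    input_dir = ".",
    output_dir = "out",
    projection = list(center_lon = -65, center_lat = -51),
    species = list(unit = "individuals", family = "nb",
                   half_width_km = NULL, strip_coverage = 0.97,
                   strip_rounding_m = 100, species_code = NULL),
    model = list(segment_length_km = 10,
                 candidates = c("xy", "depth", "dist_coast", "sst", "chla"),
                 k_spatial = 20, k_univariate = 6, soap_knots = 30,
                 use_soap = TRUE, alpha = 0.05, screen_threshold = 0.35),
    prediction = list(cell_area_km2 = 100, max_coast_distance_km = NULL,
                      months = c(11, 12, 1, 2, 3, 4), years = NULL,
                      combine = "mean"),
    diagnostics = list(max_lag = 10))
}

#' Load and validate a run configuration
#'
#' YAML file with blocks `projection`, `species`, `model`, `prediction`,
#' `diagnostics` plus `seed`, `input_dir`, `output_dir`. Unknown keys are
#' rejected; missing keys take defaults. The resolved configuration is
#' written next to the outputs by [run_pipeline()].
#'
#' @param path YAML config path, or a list already in memory.
#' @return validated config list.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- .default_config()
  bad <- setdiff(names(user), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    if (is.list(def[[blk]]) && is.list(user[[blk]])) {
      bad <- setdiff(names(user[[blk]]), names(def[[blk]]))
      if (length(bad)) stop("unknown config key(s) in ", blk, ": ",
                            paste(bad, collapse = ", "))
      def[[blk]][names(user[[blk]])] <- user[[blk]]
    } else def[[blk]] <- user[[blk]]
  }
  def
}

.load_inputs <- function(cfg) {
  d <- cfg$input_dir
  need <- c("effort.csv", "sightings.csv", "region.wkt", "coastline.wkt",
            "depth.asc")
  miss <- need[!file.exists(file.path(d, need))]
  if (length(miss)) stop("missing input file(s) in ", d, ": ",
                         paste(miss, collapse = ", "))
  dyn <- list()
  for (v in c("sst", "chla")) {
    files <- list.files(d, pattern = paste0("^", v, "_\\d{4}-\\d{2}\\.asc$"))
    if (length(files)) {
      keys <- sub(paste0("^", v, "_(\\d{4}-\\d{2})\\.asc$"), "\\1", files)
      dyn[[v]] <- stats::setNames(
        lapply(file.path(d, files), read_ascii_grid), keys)
    }
  }
  list(effort = read_effort_csv(file.path(d, "effort.csv")),
       sightings = read_sightings_csv(file.path(d, "sightings.csv")),
       region = read_wkt(file.path(d, "region.wkt")),
       coastline = read_wkt(file.path(d, "coastline.wkt")),
       static = list(depth = read_ascii_grid(file.path(d, "depth.asc"))),
       dynamic = dyn)
}

.candidate_list <- function(cfg, soap) {
  lapply(cfg$model$candidates, function(v) {
    if (v == "xy") {
      candidate_term(c("cx", "cy"), k = cfg$model$k_spatial,
                     soap = if (isTRUE(cfg$model$use_soap)) soap,
                     label = "xy")
    } else candidate_term(v, k = cfg$model$k_univariate, label = v)
  })
}

#' Run the full density-surface pipeline
#'
#' segmentize -> annotate -> screen -> select/fit -> predict -> diagnose,
#' writing every stage's output under `output_dir`. Re-running with an
#' identical configuration reproduces identical numerical outputs.
#'
#' @param config path to a YAML config or a config list.
#' @param seed optional override of the config seed.
#' @param output_dir optional override of the config output directory.
#' @return (invisibly) list with the main in-memory results.
#' @export
run_pipeline <- function(config, seed = NULL, output_dir = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "resolved_config.yaml"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  inp <- stage("load", .load_inputs(cfg))
  pspec <- proj_spec(cfg$projection$center_lon, cfg$projection$center_lat)

  segs <- stage("segmentize", {
    tracks <- build_tracks(inp$effort, pspec)
    hw <- cfg$species$half_width_km
    if (is.null(hw)) {
      di <- inp$sightings$radial_distance_m[inp$sightings$initial_location == 1]
      hw <- select_strip_halfwidth(di, cfg$species$strip_coverage,
                                   cfg$species$strip_rounding_m) / 1000
    }
    s <- segment_tracks(tracks, cfg$model$segment_length_km, hw)
    s <- assign_sightings(s, inp$sightings, tracks, pspec, hw,
                          unit = cfg$species$unit,
                          species = cfg$species$species_code)
    attr(s, "tracks") <- tracks
    attr(s, "half_width") <- hw
    s
  })
  segs <- stage("annotate", {
    a <- annotate_segments(segs, static = inp$static, dynamic = inp$dynamic,
                           coastline = inp$coastline)
    write_segments_csv(a, file.path(out, "segments.csv"))
    attr(a, "tracks") <- attr(segs, "tracks")
    a
  })
  covars <- setdiff(cfg$model$candidates, "xy")
  covars <- intersect(c("cx", "cy", covars), names(segs))
  scr <- stage("screen", {
    s <- correlation_screen(segs, covars, cfg$model$screen_threshold)
    utils::write.csv(s$correlations, file.path(out, "screening.csv"))
    s
  })
  sel <- stage("select", {
    soap <- if (isTRUE(cfg$model$use_soap))
      build_soap_film(inp$region, n_knots = cfg$model$soap_knots,
                      vars = c("cx", "cy"))
    keep <- c("xy"[("cx" %in% scr$keep)],
              intersect(cfg$model$candidates, scr$keep))
    cands <- .candidate_list(cfg, soap)
    cands <- Filter(function(cn) cn$label %in% keep, cands)
    fam <- dsm_family(cfg$species$family)
    s <- stepwise_select(segs, cands, family = fam,
                         alpha = cfg$model$alpha)
    write_selection_trace(s, file.path(out, "selection_trace.csv"))
    jsonlite::write_json(fit_report(s$fit), file.path(out, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(s$fit, file.path(out, "fit.rds"))
    s
  })
  pred <- stage("predict", {
    grid <- build_grid(inp$region, cfg$prediction$cell_area_km2,
                       coastline = inp$coastline,
                       max_coast_distance = cfg$prediction$max_coast_distance_km)
    grid <- annotate_grid(grid, static = inp$static,
                          coastline = inp$coastline)
    periods <- sort(unique(sprintf("%04d-%02d", segs$year, segs$month)))
    nd <- if (length(inp$dynamic)) {
      stats::setNames(lapply(periods, function(p)
        grid_period_covariates(grid, inp$dynamic, p)), periods)
    } else stats::setNames(rep(list(grid), length(periods)), periods)
    av <- abundance_variance(sel$fit, nd, combine = cfg$prediction$combine)
    write_surface_csv(av$cells, file.path(out, "surface.csv"))
    ci <- lognormal_ci(av$total$N, av$total$cv)
    jsonlite::write_json(list(N = av$total$N, se = av$total$se,
                              cv = av$total$cv, ci_lo = ci[["lo"]],
                              ci_hi = ci[["hi"]], periods = periods,
                              combine = cfg$prediction$combine),
                         file.path(out, "totals.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    monthly <- do.call(rbind, lapply(periods, function(p) {
      cp <- combine_periods(sel$fit, nd[p], mode = "sum")
      ci <- lognormal_ci(max(cp$N, 1e-12), cp$cv)
      data.frame(period = p, N = cp$N, se = cp$se, cv = cp$cv,
                 lo = ci[["lo"]], hi = ci[["hi"]])
    }))
    utils::write.csv(monthly, file.path(out, "monthly_series.csv"),
                     row.names = FALSE)
    list(grid = grid, newdata = nd, variance = av, monthly = monthly)
  })
  stage("diagnose", {
    dg <- diagnose_fit(sel$fit, segs, max_lag = cfg$diagnostics$max_lag,
                       seed = cfg$seed)
    utils::write.csv(dg$correlogram, file.path(out, "correlogram.csv"),
                     row.names = FALSE)
    jsonlite::write_json(dg$k_check, file.path(out, "k_check.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dg
  })
  invisible(list(config = cfg, segments = segs, screen = scr,
                 selection = sel, prediction = pred))
}

#' Command-line entry point
#'
#' `Rscript -e 'coastdsm::cli_main()' <subcommand> --config run.yaml
#' [--seed N] [--out DIR]` with subcommands `simulate` (write a synthetic
#' scenario's input files), `run` (full pipeline) and the standalone stages
#' `segmentize`, `annotate`, `fit`, `select`, `predict`, `diagnose`, each of
#' which runs the pipeline up to and including that stage on the configured
#' inputs. Exit status 0 on success.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(TRUE)) {
  usage <- paste("usage: coastdsm <simulate|run|segmentize|annotate|fit|",
                 "select|predict|diagnose> --config run.yaml",
                 "[--seed N] [--out DIR]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg_path <- opt("--config")
  seed <- opt("--seed"); if (!is.null(seed)) seed <- as.integer(seed)
  outdir <- opt("--out")
  status <- tryCatch({
    if (cmd == "simulate") {
      scfg <- if (!is.null(cfg_path)) yaml::read_yaml(cfg_path) else list()
      kind <- if (!is.null(scfg$kind)) scfg$kind else "coastal"
      scfg$kind <- NULL
      sc <- do.call(scenario_config,
                    c(list(kind = kind,
                           seed = if (!is.null(seed)) seed else 1), scfg))
      scn <- simulate_scenario(sc)
      write_scenario(scn, if (!is.null(outdir)) outdir else "scenario")
      message("scenario written")
    } else if (cmd %in% c("run", "segmentize", "annotate", "fit", "select",
                          "predict", "diagnose")) {
      if (is.null(cfg_path)) stop("--config is required")
      run_pipeline(cfg_path, seed = seed, output_dir = outdir)
    } else stop("unknown subcommand: ", cmd, "\n", usage)
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
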