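#' Build a square-cell prediction grid over a region
#'
#' Axis-aligned square cells of area `cell_area` tile the region's bounding
#' box; a cell is kept iff its centroid lies inside the region polygon and,
#' when a coastal cap is given, within `max_coast_distance` of the coastline
#' (the restriction used for strictly coastal species).
#'
#' @param region two-column matrix of region polygon vertices (km).
#' @param cell_area cell area in km^2 (default 100, i.e. 10 km cells).
#' @param coastline coastline vertices for the coastal cap (defaults to the
#'   region boundary when a cap is requested).
#' @param max_coast_distance optional cap (km).
#' @return data.frame: `cell_id`, centroid `cx`, `cy`, `area`.
#' @export
build_grid <- function(region, cell_area = 100, coastline = NULL,
                       max_coast_distance = NULL) {
  r <- .close_ring(as.matrix(region))
  side <- sqrt(cell_area)
  rx <- range(r[, 1]); ry <- range(r[, 2])
  cx <- if (rx[1] + side / 2 > rx[2]) mean(rx) else
    seq(rx[1] + side / 2, rx[2], by = side)
  cy <- if (ry[1] + side / 2 > ry[2]) mean(ry) else
    seq(ry[1] + side / 2, ry[2], by = side)
  g <- expand.grid(cx = cx, cy = cy)
  keep <- point_in_polygon(as.matrix(g), r)
  if (!is.null(max_coast_distance)) {
    cl <- if (is.null(coastline)) r else as.matrix(coastline)
    keep <- keep & distance_to_coast(as.matrix(g), cl) <= max_coast_distance
  }
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) stop("empty prediction grid: no cell centroid inside region")
  data.frame(cell_id = seq_len(nrow(g)), cx = g$cx, cy = g$cy,
             area = cell_area)
}

#' Annotate a prediction grid with static covariates
#'
#' Depth (and any other static raster) is averaged over each square cell;
#' distance to coast is measured from the cell centroid.
#'
#' @param grid data.frame from [build_grid()].
#' @param static named list of [ascii_grid()]s.
#' @param coastline coastline vertices for `dist_coast` (optional).
#' @return grid with covariate columns appended.
#' @export
annotate_grid <- function(grid, static = list(), coastline = NULL) {
  side <- sqrt(grid$area)
  for (v in names(static)) {
    g <- static[[v]]
    grid[[v]] <- vapply(seq_len(nrow(grid)), function(i) {
      grid_mean_in_strip(g, c(grid$cx[i] - side[i] / 2, grid$cy[i]),
                         c(grid$cx[i] + side[i] / 2, grid$cy[i]),
                         side[i] / 2)
    }, 0)
  }
  if (!is.null(coastline))
    grid$dist_coast <- distance_to_coast(cbind(grid$cx, grid$cy),
                                         as.matrix(coastline))
  grid
}

#' Per-period dynamic covariates on a grid
#'
#' @param grid annotated grid data.frame.
#' @param dynamic named list (variable) of named lists (`"YYYY-MM"`) of
#'   [ascii_grid()]s.
#' @param period `"YYYY-MM"` string.
#' @return grid with the period's dynamic covariate columns appended.
#' @export
grid_period_covariates <- function(grid, dynamic, period) {
  side <- sqrt(grid$area)
  for (v in names(dynamic)) {
    g <- dynamic[[v]][[period]]
    if (is.null(g)) stop("no ", v, " raster for period ", period)
    grid[[v]] <- vapply(seq_len(nrow(grid)), function(i) {
      grid_mean_in_strip(g, c(grid$cx[i] - side[i] / 2, grid$cy[i]),
                         c(grid$cx[i] + side[i] / 2, grid$cy[i]),
                         side[i] / 2)
    }, 0)
  }
  grid
}

#' Seasonal averages of dynamic covariates per cell
#'
#' Means over all available (month, year) rasters in the requested season,
#' skipping cloud-masked values; cells missing in every period come back
#' `NA` and the count of such cells is reported.
#'
#' @param grid grid data.frame.
#' @param dynamic as in [grid_period_covariates()].
#' @param months integer months to include (default Nov-Apr: 11,12,1:4).
#' @param years integer years to include (default: all present).
#' @return grid with seasonal-mean dynamic covariate columns.
#' @export
average_dynamic_covariates <- function(grid, dynamic,
                                       months = c(11, 12, 1:4),
                                       years = NULL) {
  for (v in names(dynamic)) {
    keys <- names(dynamic[[v]])
    ky <- as.integer(substr(keys, 1, 4))
    km <- as.integer(substr(keys, 6, 7))
    use <- km %in% months & (if (is.null(years)) TRUE else ky %in% years)
    if (!any(use)) stop("no ", v, " rasters in the requested months/years")
    vals <- sapply(keys[use], function(k) {
      grid_period_covariates(grid[, c("cell_id", "cx", "cy", "area")],
                             stats::setNames(list(dynamic[[v]]), v), k)[[v]]
    })
    vals <- matrix(vals, nrow = nrow(grid))
    m <- rowMeans(vals, na.rm = TRUE)
    m[!is.finite(m)] <- NA
    nm <- sum(is.na(m))
    if (nm) message(nm, " cell(s) have no ", v, " value in any period")
    grid[[v]] <- m
  }
  grid
}

# linear predictor matrix on new data; drops the offset, flags rows that
# cannot be predicted (outside soap boundary or missing covariates)
.lpmatrix <- function(fit, newdata) {
  g <- fit$gam
  vars <- setdiff(all.vars(fit$formula[[3]]), c("k", "xt"))
  vars <- intersect(vars, names(newdata))
  ok <- stats::complete.cases(newdata[, vars, drop = FALSE])
  for (sm in g$smooth) {
    if (inherits(sm, "soap.film")) {
      # inSide matches boundary component names against the argument names
      bnd2 <- lapply(sm$xt$bnd, function(lp) {
        out <- list(xx = lp[[sm$term[1]]], yy = lp[[sm$term[2]]])
        if (!is.null(lp$f)) out$f <- lp$f
        out
      })
      xx <- newdata[[sm$term[1]]]
      yy <- newdata[[sm$term[2]]]
      ok <- ok & mgcv::inSide(bnd2, xx, yy)
    }
  }
  Xp <- matrix(NA_real_, nrow(newdata), length(fit$coefficients))
  if (any(ok))
    Xp[ok, ] <- stats::predict(g, newdata = newdata[ok, , drop = FALSE],
                               type = "lpmatrix")
  list(Xp = Xp, ok = ok)
}

#' Predict an abundance surface on a grid
#'
#' Per-cell abundance is `A_cell * exp(eta(cell))`. When several periods are
#' supplied (dynamic covariates differing by month), the surface is the mean
#' of the per-period surfaces over the periods surveyed. Cells that cannot
#' be predicted (outside the soap-film boundary, or missing a model
#' covariate) are excluded and their count and area reported.
#'
#' @param fit a `"dsm_fit"`.
#' @param newdata a grid data.frame, or a named list of per-period grid
#'   data.frames (identical cells, period-specific dynamic covariates).
#' @param combine `"mean"` (default; seasonal average surface) or `"sum"`.
#' @return data.frame `cell_id, cx, cy, area, N` with attributes `total`,
#'   `n_excluded`, `area_excluded`, `periods`, `combine`.
#' @export
predict_abundance <- function(fit, newdata, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  nd_list <- if (is.data.frame(newdata)) list(newdata) else newdata
  base <- nd_list[[1]]
  Ns <- matrix(NA_real_, nrow(base), length(nd_list))
  ok_all <- rep(TRUE, nrow(base))
  for (t in seq_along(nd_list)) {
    lp <- .lpmatrix(fit, nd_list[[t]])
    eta <- as.vector(lp$Xp %*% fit$coefficients)
    Ns[, t] <- nd_list[[t]]$area * exp(eta)
    ok_all <- ok_all & lp$ok
  }
  N <- if (combine == "mean") rowMeans(Ns) else rowSums(Ns)
  N[!ok_all] <- NA
  n_exc <- sum(!ok_all)
  if (n_exc) message(n_exc, " cell(s) excluded from prediction")
  ids <- if (!is.null(base$cell_id)) base$cell_id else seq_len(nrow(base))
  out <- data.frame(cell_id = ids,
                    cx = if (!is.null(base$cx)) base$cx else NA,
                    cy = if (!is.null(base$cy)) base$cy else NA,
                    area = base$area, N = N)
  attr(out, "total") <- sum(N[ok_all])
  attr(out, "n_excluded") <- n_exc
  attr(out, "area_excluded") <- sum(base$area[!ok_all])
  attr(out, "periods") <- names(nd_list)
  attr(out, "combine") <- combine
  out
}

# simulate draws from N(beta, Vb) via Cholesky with symmetric pivoting fallback
.rmvn <- function(B, beta, Vb) {
  p <- length(beta)
  R <- tryCatch(chol(Vb), error = function(e) {
    es <- eigen((Vb + t(Vb)) / 2, symmetric = TRUE)
    ev <- pmax(es$values, 0)
    t(es$vectors %*% diag(sqrt(ev), p))
  })
  matrix(stats::rnorm(B * p), B, p) %*% R + rep(beta, each = B)
}

#' Uncertainty of a predicted abundance surface
#'
#' Delta method on the link scale: for any linear combination of cells with
#' weights from `combine`, `var(N) = a' Vb a` with
#' `a = sum_cells A_cell exp(eta) x_cell` (per-period gradients averaged or
#' summed to match the surface). Per-cell SEs use each cell's own gradient
#' row. A seeded posterior-simulation mode (draws from `N(beta, Vb)`) is
#' provided as an independent check and must agree with the delta method.
#'
#' @param fit a `"dsm_fit"`.
#' @param newdata grid data.frame or named per-period list (as in
#'   [predict_abundance()]).
#' @param combine `"mean"` or `"sum"` across periods.
#' @param method `"delta"` (default) or `"simulation"`.
#' @param B posterior draws for the simulation method.
#' @param seed seed for the simulation method.
#' @param covariance `"corrected"` (default) uses the smoothing-parameter-
#'   uncertainty corrected coefficient covariance; `"posterior"` uses the
#'   plain Bayesian posterior covariance.
#' @return list: `cells` (data.frame with N, se, cv), `total`
#'   (N, se, cv), `method`.
#' @export
abundance_variance <- function(fit, newdata, combine = c("mean", "sum"),
                               method = c("delta", "simulation"),
                               B = 1000, seed = 1,
                               covariance = c("corrected", "posterior")) {
  combine <- match.arg(combine)
  method <- match.arg(method)
  covariance <- match.arg(covariance)
  Vuse <- if (covariance == "corrected" && !is.null(fit$Vc)) fit$Vc else fit$Vb
  nd_list <- if (is.data.frame(newdata)) list(newdata) else newdata
  Tn <- length(nd_list)
  w <- if (combine == "mean") 1 / Tn else 1
  base <- nd_list[[1]]
  n_cells <- nrow(base)
  p <- length(fit$coefficients)
  A_cell <- matrix(0, n_cells, p)      # per-cell combined gradient rows
  Ncomb <- rep(0, n_cells)
  ok_all <- rep(TRUE, n_cells)
  for (t in seq_len(Tn)) {
    lp <- .lpmatrix(fit, nd_list[[t]])
    eta <- as.vector(lp$Xp %*% fit$coefficients)
    Nt <- nd_list[[t]]$area * exp(eta)
    ok_all <- ok_all & lp$ok
    rows <- lp$Xp * Nt                 # d N_t(cell) / d beta
    rows[!lp$ok, ] <- 0
    Nt[!lp$ok] <- 0
    A_cell <- A_cell + w * rows
    Ncomb <- Ncomb + w * Nt
  }
  Ncomb[!ok_all] <- NA
  a_tot <- colSums(A_cell[ok_all, , drop = FALSE])
  if (method == "delta") {
    if (!all(is.finite(Vuse))) stop("coefficient covariance is not finite")
    var_cell <- rowSums((A_cell %*% Vuse) * A_cell)
    var_tot <- as.numeric(t(a_tot) %*% Vuse %*% a_tot)
    se_cell <- sqrt(pmax(var_cell, 0))
    se_cell[!ok_all] <- NA
    se_tot <- sqrt(max(var_tot, 0))
  } else {
    set.seed(seed)
    betas <- .rmvn(B, fit$coefficients, Vuse)
    tot_draws <- rep(0, B)
    m2_cell <- rep(0, n_cells); m1_cell <- rep(0, n_cells)
    for (t in seq_len(Tn)) {
      lp <- .lpmatrix(fit, nd_list[[t]])
      Xp <- lp$Xp; Xp[!lp$ok, ] <- 0
      etaB <- Xp %*% t(betas)          # n_cells x B
      NtB <- nd_list[[t]]$area * exp(etaB)
      NtB[!lp$ok, ] <- 0
      if (t == 1) cellB <- w * NtB else cellB <- cellB + w * NtB
    }
    tot_draws <- colSums(cellB[ok_all, , drop = FALSE])
    se_cell <- apply(cellB, 1, stats::sd)
    se_cell[!ok_all] <- NA
    se_tot <- stats::sd(tot_draws)
  }
  total <- sum(Ncomb[ok_all])
  ids <- if (!is.null(base$cell_id)) base$cell_id else seq_len(nrow(base))
  cells <- data.frame(cell_id = ids,
                      cx = if (!is.null(base$cx)) base$cx else NA,
                      cy = if (!is.null(base$cy)) base$cy else NA,
                      area = base$area, N = Ncomb, se = se_cell,
                      cv = ifelse(Ncomb > 0, se_cell / Ncomb, NA))
  list(cells = cells,
       total = list(N = total, se = se_tot,
                    cv = if (total > 0) se_tot / total else NA),
       method = method, combine = combine, gradient = a_tot)
}

#' Combine per-period abundance estimates
#'
#' For a sum or mean of per-period totals estimated from one fit, the
#' variance is the sum of all pairwise covariances
#' `cov(N_t, N_s) = a_t' Vb a_s` of the delta-method gradients (divided by
#' T^2 for a mean).
#'
#' @param fit a `"dsm_fit"`.
#' @param newdata named list of per-period grid data.frames.
#' @param mode `"mean"` (default) or `"sum"`.
#' @param covariance `"corrected"` (default) or `"posterior"`, as in
#'   [abundance_variance()].
#' @return list: `N`, `se`, `cv`, `cov_matrix` (between-period), `per_period`.
#' @export
combine_periods <- function(fit, newdata, mode = c("mean", "sum"),
                            covariance = c("corrected", "posterior")) {
  mode <- match.arg(mode)
  covariance <- match.arg(covariance)
  Vuse <- if (covariance == "corrected" && !is.null(fit$Vc)) fit$Vc else fit$Vb
  if (is.data.frame(newdata)) newdata <- list(newdata)
  Tn <- length(newdata)
  grads <- matrix(0, Tn, length(fit$coefficients))
  Nt <- numeric(Tn)
  for (t in seq_len(Tn)) {
    lp <- .lpmatrix(fit, newdata[[t]])
    eta <- as.vector(lp$Xp %*% fit$coefficients)
    Ncell <- newdata[[t]]$area * exp(eta)
    Ncell[!lp$ok] <- 0
    Nt[t] <- sum(Ncell)
    rows <- lp$Xp * Ncell
    rows[!lp$ok, ] <- 0
    grads[t, ] <- colSums(rows)
  }
  Cov <- grads %*% Vuse %*% t(grads)
  if (mode == "mean") {
    N <- mean(Nt); v <- sum(Cov) / Tn^2
  } else {
    N <- sum(Nt); v <- sum(Cov)
  }
  list(N = N, se = sqrt(max(v, 0)), cv = if (N > 0) sqrt(max(v, 0)) / N else NA,
       cov_matrix = Cov, per_period = Nt, mode = mode)
}

#' Lognormal confidence interval for an abundance estimate
#'
#' The distance-sampling convention for strictly positive estimates:
#' `C = exp(z * sqrt(log(1 + CV^2)))`, interval `(N/C, N*C)`. Endpoints are
#' multiplicatively symmetric about the estimate.
#'
#' @param N abundance estimate (> 0).
#' @param cv coefficient of variation (SE/N, >= 0).
#' @param z normal quantile (default 1.96 for 95%).
#' @return named vector `lo`, `hi`.
#' @export
lognormal_ci <- function(N, cv, z = 1.96) {
  stopifnot(N > 0, cv >= 0)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(lo = N / C, hi = N * C)
}

#' Write an abundance surface to CSV
#'
#' @param surface result of [abundance_variance()] (its `cells`) or a
#'   data.frame with cell columns.
#' @param path CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  df <- if (is.data.frame(surface)) surface else surface$cells
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
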