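#' Build a penalized cubic regression spline basis
#'
#' Cubic regression spline design matrix and second-derivative penalty for a
#' univariate covariate, as used for every univariate smoother in the
#' abundance models. Coefficients of the unconstrained parameterization are
#' function values at the knots, and the penalty quadratic form equals the
#' integrated squared second derivative of the natural cubic interpolant.
#'
#' @param x covariate values.
#' @param k basis dimension (>= 3); reduced with a warning when there are
#'   fewer distinct values than `k`.
#' @param absorb_constraint apply the sum-to-zero identifiability constraint
#'   (default TRUE; FALSE keeps the interpretable values-at-knots form).
#' @return list with design matrix `X`, penalty `S`, `knots`, and the
#'   underlying mgcv smooth object `sm`.
#' @export
build_cubic_basis <- function(x, k = 10, absorb_constraint = TRUE) {
  if (k < 3) stop("k must be at least 3")
  nd <- length(unique(x))
  if (nd < 3) stop("need at least 3 distinct covariate values")
  if (nd < k) {
    warning("only ", nd, " distinct values; reducing k from ", k, " to ", nd)
    k <- nd
  }
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k), data = dat,
                        absorb.cons = absorb_constraint,
                        scale.penalty = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]], knots = sm$xp, sm = sm)
}

#' Boundary-respecting soap-film smoother specification
#'
#' Packages a coastline polygon, interior knots and PDE grid resolution into
#' the pieces a spatial soap-film smooth needs. The film basis functions are
#' discrete solutions of the soap-film PDE on a finite-difference grid with
#' zero boundary conditions, so the smooth cannot "leak" across peninsulas.
#'
#' @param boundary two-column matrix of boundary vertices (projected km),
#'   open or closed ring; must be a simple polygon.
#' @param knots optional two-column matrix of interior knots; generated on a
#'   regular interior grid (about `n_knots` points) when omitted.
#' @param n_knots target number of auto-generated interior knots.
#' @param grid_step PDE grid resolution (km); default 1/200 of the
#'   bounding-box diagonal.
#' @param vars names of the two coordinate variables the spatial smooth will
#'   use (boundary loops and knots are named accordingly, as mgcv requires).
#' @return object of class `"soap_spec"` with elements `bnd` (mgcv boundary
#'   list), `knots` (data.frame named after `vars`), `xt` (to pass to
#'   `s(..., xt = )`), `boundary` (vertex matrix), `grid_step`, `vars`.
#' @export
build_soap_film <- function(boundary, knots = NULL, n_knots = 40,
                            grid_step = NULL, vars = c("x", "y")) {
  b <- .close_ring(as.matrix(boundary))
  if (.ring_self_intersects(b)) stop("boundary polygon is not simple")
  if (is.null(grid_step)) {
    dg <- sqrt(diff(range(b[, 1]))^2 + diff(range(b[, 2]))^2)
    grid_step <- dg / 200
  }
  nmax <- ceiling(max(diff(range(b[, 1])), diff(range(b[, 2]))) / grid_step)
  bnd <- list(stats::setNames(list(b[-nrow(b), 1], b[-nrow(b), 2]), vars))
  if (is.null(knots)) {
    knots <- .interior_knots(b, n_knots)
  } else {
    knots <- as.matrix(knots)
    inside <- point_in_polygon(knots, b) &
      distance_to_coast(knots, b) > 2 * grid_step
    if (!all(inside)) stop(sum(!inside), " knot(s) not strictly interior")
    knots <- data.frame(x = knots[, 1], y = knots[, 2])
  }
  names(knots) <- vars
  structure(list(bnd = bnd, knots = knots,
                 xt = list(bnd = bnd, nmax = nmax),
                 boundary = b, grid_step = grid_step, vars = vars),
            class = "soap_spec")
}

# brute segment-pair crossing test (n^2; boundaries are small)
.ring_self_intersects <- function(b) {
  n <- nrow(b) - 1
  seg <- function(i) rbind(b[i, ], b[i + 1, ])
  cross <- function(p, q, r) (q[1]-p[1])*(r[2]-p[2]) - (q[2]-p[2])*(r[1]-p[1])
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next
    a <- seg(i); c <- seg(j)
    d1 <- cross(a[1,], a[2,], c[1,]); d2 <- cross(a[1,], a[2,], c[2,])
    d3 <- cross(c[1,], c[2,], a[1,]); d4 <- cross(c[1,], c[2,], a[2,])
    if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
  }
  FALSE
}

# regular interior grid of about n knots, kept away from the boundary
.interior_knots <- function(b, n) {
  rx <- range(b[, 1]); ry <- range(b[, 2])
  area <- polygon_area(b)
  step <- sqrt(area / n)
  repeat {
    gx <- seq(rx[1] + step / 2, rx[2], by = step)
    gy <- seq(ry[1] + step / 2, ry[2], by = step)
    g <- as.matrix(expand.grid(x = gx, y = gy))
    keep <- point_in_polygon(g, b) & distance_to_coast(g, b) > step / 4
    if (sum(keep) >= min(n, 10) || step < 1e-6) break
    step <- step * 0.8
  }
  g <- g[keep, , drop = FALSE]
  data.frame(x = g[, 1], y = g[, 2])
}

#' Evaluate soap-film basis functions
#'
#' Evaluates the wiggly (interior) soap-film basis columns, and any fixed
#' boundary-condition offset, at arbitrary points. Points on the boundary
#' (within `tol`) get the exact boundary trace: 0 for every wiggly basis
#' function, the Dirichlet data for the offset. Points outside the region
#' are flagged invalid (`NA` rows, indices in attribute `"outside"`).
#'
#' @param soap a `"soap_spec"`; its boundary loop may carry known boundary
#'   values `f` (same length as the loop) for harmonic-extension work.
#' @param pts two-column matrix of evaluation points (km).
#' @param k basis dimension passed to the smooth constructor.
#' @param tol boundary snapping tolerance (km); default `grid_step/100`.
#' @param component `"film"` (default) evaluates the interior (wiggly) film
#'   basis, which satisfies the zero Dirichlet boundary condition; `"full"`
#'   includes the boundary-loop smooth, whose trace on the boundary is the
#'   boundary interpolant and is deliberately nonzero.
#' @return matrix of basis values (attributes: `"offset"` when boundary data
#'   are fixed, `"outside"` row indices).
#' @export
soap_basis_eval <- function(soap, pts, k = 20, tol = NULL,
                            component = c("film", "full")) {
  stopifnot(inherits(soap, "soap_spec"))
  component <- match.arg(component)
  if (is.null(tol)) tol <- soap$grid_step / 100
  pts <- as.matrix(pts)
  b <- soap$boundary
  v <- soap$vars
  # with known boundary values the "so" construction carries no boundary
  # smooth, so every free column is a zero-boundary film function already
  bs <- if (component == "film" && is.null(soap$bnd[[1]]$f)) "sw" else "so"
  scall <- parse(text = sprintf("mgcv::s(%s, %s, bs = \"%s\", k = %d, xt = soap$xt)",
                                v[1], v[2], bs, k))[[1]]
  sm <- mgcv::smoothCon(eval(scall), data = soap$knots,
                        knots = soap$knots)[[1]]
  dcoast <- distance_to_coast(pts, b)
  on_bnd <- dcoast <= tol
  inside <- point_in_polygon(pts, b) | on_bnd
  X <- matrix(NA_real_, nrow(pts), ncol(sm$X))
  off <- rep(NA_real_, nrow(pts))
  ev <- inside & !on_bnd
  if (any(ev)) {
    Xe <- mgcv::PredictMat(sm, stats::setNames(
      data.frame(pts[ev, 1], pts[ev, 2]), v))
    X[ev, ] <- Xe
    o <- attr(Xe, "offset")
    off[ev] <- if (is.null(o)) 0 else o
  }
  if (any(on_bnd)) {
    X[on_bnd, ] <- 0                 # zero Dirichlet trace of the film basis
    off[on_bnd] <- .boundary_f_at(soap, pts[on_bnd, , drop = FALSE])
  }
  attr(X, "offset") <- off
  attr(X, "outside") <- which(!inside)
  attr(X, "sm") <- sm
  X
}

# boundary-condition value at the nearest boundary vertex (0 when free)
.boundary_f_at <- function(soap, pts) {
  f <- soap$bnd[[1]]$f
  if (is.null(f)) return(rep(0, nrow(pts)))
  bx <- soap$bnd[[1]][[soap$vars[1]]]; by <- soap$bnd[[1]][[soap$vars[2]]]
  vapply(seq_len(nrow(pts)), function(i) {
    f[which.min((bx - pts[i, 1])^2 + (by - pts[i, 2])^2)]
  }, 0)
}

#' Harmonic extension of fixed boundary data
#'
#' Solves the soap-film PDE with known Dirichlet boundary values and no
#' interior data, i.e. returns the film component: the (approximately
#' harmonic) interior surface determined entirely by the boundary data.
#'
#' @param boundary two-column matrix of boundary vertices.
#' @param f boundary values, one per vertex (open-ring length).
#' @param pts evaluation points.
#' @param nmax PDE grid resolution parameter.
#' @return numeric vector of interior surface values (`NA` outside).
#' @export
soap_film_extension <- function(boundary, f, pts, nmax = 200) {
  b <- .close_ring(as.matrix(boundary))
  bx <- b[-nrow(b), 1]; by <- b[-nrow(b), 2]
  if (length(f) != length(bx)) stop("f must have one value per boundary vertex")
  soap <- build_soap_film(b, n_knots = 12)
  soap$bnd <- list(list(x = bx, y = by, f = f))
  soap$xt <- list(bnd = soap$bnd, nmax = nmax)
  X <- soap_basis_eval(soap, pts)
  attr(X, "offset")
}

.resolve_family <- function(family, p_fixed = NULL) {
  stopifnot(inherits(family, "dsm_family"))
  if (family$kind == "nb") {
    if (!is.null(family$theta)) mgcv::negbin(theta = family$theta) else mgcv::nb()
  } else {
    p <- if (!is.null(p_fixed)) p_fixed else family$p
    if (is.null(p)) stop("internal: Tweedie power must be resolved before fitting")
    mgcv::Tweedie(p = p, link = "log")
  }
}

#' Fit an overdispersed-count GAM with an effort-area offset
#'
#' Fits `count ~ smooth terms + offset(log(area))` by penalized IRLS with
#' REML smoothness selection (via mgcv). The negative binomial dispersion
#' is estimated within the outer REML optimization; the Tweedie power is
#' profiled over the grid p = 1.1, 1.2, ..., 1.9, keeping the power with the
#' lowest REML score. Fitting is deterministic: no randomness enters.
#'
#' @param formula model formula in mgcv syntax, e.g.
#'   `count ~ s(cx, cy, bs = "so", k = 20, xt = soap$xt) + s(depth, k = 10)`.
#'   The `offset(log(area))` term is appended automatically.
#' @param data segment data.frame (must contain the response, covariates and
#'   `offset_var`). Rows with missing values in used covariates are dropped
#'   (with a message reporting how many).
#' @param family a [dsm_family()].
#' @param offset_var name of the effort-area column (km^2), default "area".
#' @param knots optional knots list/data.frame (soap-film knots).
#' @param sp optional fixed smoothing parameters (passed to mgcv).
#' @param p_grid Tweedie power grid for REML profiling.
#' @return object of class `"dsm_fit"`: the mgcv fit plus extracted
#'   coefficients, Bayesian covariance, smoothing parameters, family
#'   parameters, per-term EDFs, deviance explained and adjusted R-squared.
#' @export
fit_gam <- function(formula, data, family = dsm_family("nb"),
                    offset_var = "area", knots = NULL, sp = NULL,
                    p_grid = seq(1.1, 1.9, by = 0.1)) {
  if (!offset_var %in% names(data)) stop("data lacks offset column ", offset_var)
  if (any(data[[offset_var]] <= 0)) stop("offset areas must be positive")
  resp <- all.vars(formula[[2]])
  if (!resp %in% names(data)) stop("response ", resp, " not in data")
  if (all(data[[resp]] == 0)) stop("all-zero response: nothing to fit")
  if (family$kind == "nb" && any(abs(data[[resp]] - round(data[[resp]])) > 1e-8))
    stop("negative binomial requires integer counts")
  used <- unique(c(all.vars(formula), offset_var))
  used <- intersect(used, names(data))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  if (!all(cc)) {
    message(sum(!cc), " segment(s) dropped for missing model covariates")
    data <- data[cc, , drop = FALSE]
  }
  f2 <- stats::as.formula(
    paste(deparse(formula[[2]]), "~",
          paste(deparse(formula[[3]], width.cutoff = 500), collapse = " "),
          "+ offset(log(", offset_var, "))"),
    env = environment(formula))
  fit_one <- function(fam) {
    mgcv::gam(f2, data = data, family = fam, method = "REML",
              knots = knots, sp = sp)
  }
  if (family$kind == "tweedie" && is.null(family$p)) {
    fits <- lapply(p_grid, function(p) fit_one(.resolve_family(family, p)))
    reml <- vapply(fits, function(g) as.numeric(g$gcv.ubre), 0)
    best <- which.min(reml)
    g <- fits[[best]]
    p_used <- p_grid[best]
    profile <- data.frame(p = p_grid, reml = reml)
  } else {
    g <- fit_one(.resolve_family(family))
    p_used <- family$p
    profile <- NULL
  }
  .wrap_fit(g, family, formula, offset_var, p_used, profile, knots)
}

.wrap_fit <- function(g, family, formula, offset_var, p_used, profile, knots) {
  theta <- if (family$kind == "nb") {
    if (!is.null(family$theta)) family$theta else g$family$getTheta(TRUE)
  } else NULL
  n <- length(g$y)
  total_edf <- sum(g$edf)
  mu <- stats::fitted(g)
  y <- g$y
  w <- g$prior.weights
  rss <- sum(w * (y - mu)^2)
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  adj_r2 <- 1 - (rss / (n - total_edf)) / (tss / (n - 1))
  structure(list(
    gam = g,
    formula = formula,
    family = family,
    offset_var = offset_var,
    coefficients = stats::coef(g),
    Vb = g$Vp,
    # smoothing-parameter-uncertainty corrected covariance (Wood, Pya &
    # Saefken 2016); used for abundance uncertainty, while Wald tests use Vb
    Vc = if (!is.null(g$Vc)) g$Vc else g$Vp,
    sp = g$sp,
    theta = theta,
    p = p_used,
    phi = g$scale,
    scale_estimated = g$scale.estimated,
    edf = .per_term_edf(g),
    total_edf = total_edf,
    deviance = stats::deviance(g),
    null_deviance = g$null.deviance,
    dev_expl = 100 * (1 - stats::deviance(g) / g$null.deviance),
    adj_r2 = adj_r2,
    reml = as.numeric(g$gcv.ubre),
    p_profile = profile,
    knots = knots,
    n = n), class = "dsm_fit")
}

.per_term_edf <- function(g) {
  if (!length(g$smooth)) return(numeric(0))
  out <- vapply(g$smooth, function(sm) {
    sum(g$edf[sm$first.para:sm$last.para])
  }, 0)
  names(out) <- vapply(g$smooth, function(sm) sm$label, "")
  out
}

#' Effective degrees of freedom of a fitted model
#'
#' Per-term EDFs are traces of the influence matrix
#' `F = (X'WX + sum lambda_i S_i)^-1 X'WX` restricted to each term's
#' coefficient block; parametric coefficients contribute 1 each.
#'
#' @param fit a `"dsm_fit"`.
#' @return list with `per_term`, `parametric`, `total`.
#' @export
edf <- function(fit) {
  stopifnot(inherits(fit, "dsm_fit"))
  g <- fit$gam
  sm_idx <- unlist(lapply(g$smooth, function(s) s$first.para:s$last.para))
  para <- setdiff(seq_along(g$edf), sm_idx)
  list(per_term = fit$edf,
       parametric = sum(g$edf[para]),
       total = fit$total_edf)
}

#' Approximate p-values for smooth terms
#'
#' Wald-type test for each smooth: the statistic `b' V^- b` uses the rank-r
#' pseudo-inverse of the term's Bayesian coefficient covariance block, with
#' `r = max(1, round(EDF))`. With known scale (negative binomial) the
#' statistic is referred to a chi-squared distribution on r df; with an
#' estimated scale (Tweedie) an F(r, n - total EDF) reference is used.
#'
#' @param fit a `"dsm_fit"`.
#' @param term optional smooth label (e.g. `"s(depth)"`); all smooths when
#'   omitted.
#' @return data.frame with columns term, edf, rank, statistic, p_value.
#' @export
approx_pvalue <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "dsm_fit"))
  g <- fit$gam
  labels <- vapply(g$smooth, function(s) s$label, "")
  if (!is.null(term)) {
    if (!term %in% labels) stop("term ", term, " not in model")
    idx <- match(term, labels)
  } else idx <- seq_along(labels)
  Xfull <- stats::predict(g, type = "lpmatrix")
  res <- lapply(idx, function(i) {
    sm <- g$smooth[[i]]
    cols <- sm$first.para:sm$last.para
    b <- fit$coefficients[cols]
    V <- fit$Vb[cols, cols, drop = FALSE]
    ed <- fit$edf[i]
    r <- max(1L, min(length(cols), as.integer(round(ed))))
    # re-parameterize on the scale of the term's fitted values (QR of the
    # term's design columns) so the rank-r truncation acts in function
    # space, then invert the top-r eigenspace of the transformed covariance
    Xt <- Xfull[, cols, drop = FALSE]
    qrx <- qr(Xt / sqrt(nrow(Xt)))
    R <- qr.R(qrx)[, order(qrx$pivot), drop = FALSE]
    bt <- drop(R %*% b)
    Vt <- R %*% V %*% t(R)
    es <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE)
    pos <- es$values[seq_len(r)]
    pos[pos < .Machine$double.eps * max(abs(es$values))] <-
      .Machine$double.eps * max(abs(es$values))
    Ui <- es$vectors[, seq_len(r), drop = FALSE]
    stat <- sum((crossprod(Ui, bt))^2 / pos)
    pv <- if (isTRUE(fit$scale_estimated)) {
      stats::pf(stat / r, r, fit$n - fit$total_edf, lower.tail = FALSE)
    } else {
      stats::pchisq(stat, r, lower.tail = FALSE)
    }
    data.frame(term = labels[i], edf = ed, rank = r, statistic = stat,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fit summaries: deviance explained and adjusted R-squared
#'
#' @param fit a `"dsm_fit"`.
#' @return list with `dev_expl` (percent), `adj_r2`, `deviance`,
#'   `null_deviance`, `reml`, `aic`.
#' @export
fit_summaries <- function(fit) {
  stopifnot(inherits(fit, "dsm_fit"))
  list(dev_expl = fit$dev_expl, adj_r2 = fit$adj_r2,
       deviance = fit$deviance, null_deviance = fit$null_deviance,
       reml = fit$reml, aic = stats::AIC(fit$gam))
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("Density surface GAM (", x$family$kind, " family)\n", sep = "")
  if (!is.null(x$theta)) cat(sprintf("  NB theta: %.4g\n", x$theta))
  if (!is.null(x$p)) cat(sprintf("  Tweedie p: %.2f, scale: %.4g\n", x$p, x$phi))
  cat(sprintf("  n = %d segments, REML = %.4f\n", x$n, x$reml))
  if (length(x$edf)) {
    pv <- approx_pvalue(x)
    for (i in seq_len(nrow(pv)))
      cat(sprintf("  %s  edf %.2f  p %.3g\n", pv$term[i], pv$edf[i], pv$p_value[i]))
  }
  cat(sprintf("  Deviance explained: %.1f%%, adj. R-sq: %.3f\n",
              x$dev_expl, x$adj_r2))
  invisible(x)
}

#' Fit report as a plain list (JSON-ready)
#'
#' @param fit a `"dsm_fit"`.
#' @return list mirroring the quantities reported for the dolphin models.
#' @export
fit_report <- function(fit) {
  pv <- if (length(fit$edf)) approx_pvalue(fit) else NULL
  list(family = fit$family$kind, theta = fit$theta, p = fit$p, phi = fit$phi,
       n_segments = fit$n, coefficients = as.list(fit$coefficients),
       smoothing_parameters = as.list(fit$sp),
       edf = as.list(fit$edf), total_edf = fit$total_edf,
       p_values = if (!is.null(pv)) stats::setNames(as.list(pv$p_value), pv$term),
       deviance = fit$deviance, null_deviance = fit$null_deviance,
       dev_expl_percent = fit$dev_expl, adj_r2 = fit$adj_r2, reml = fit$reml)
}
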