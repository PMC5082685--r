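#' Planar polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertices (closed or open ring).
#' @return unsigned area in squared input units.
#' @export
polygon_area <- function(poly) {
  p <- .close_ring(as.matrix(poly))
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

.close_ring <- function(p) {
  if (nrow(p) < 3) stop("polygon needs at least 3 vertices")
  if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

#' Point-in-polygon test
#'
#' Thin wrapper over `mgcv::in.out` so that region polygons are tested with
#' the same code the soap-film machinery uses.
#'
#' @param pts two-column matrix of points.
#' @param poly two-column matrix of polygon vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  p <- .close_ring(as.matrix(poly))
  m <- as.matrix(pts)
  if (is.null(dim(m)) || ncol(m) != 2) m <- matrix(m, ncol = 2)
  mgcv::in.out(p, m)
}

# squared distance from points (n x 2) to one segment a-b; vectorised over points
.pt_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-300) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Minimum distance from points to a coastline
#'
#' Minimum Euclidean distance, in the projected plane, from each point to any
#' edge of the coastline polyline/polygon. Geodesic distances are out of
#' scope by design: all distances live in the equal-area plane.
#'
#' @param pts two-column matrix of points (km).
#' @param coastline two-column matrix of coastline vertices (km); treated as
#'   an open polyline (pass a closed ring to treat it as a polygon boundary).
#' @return numeric vector of distances (km).
#' @export
distance_to_coast <- function(pts, coastline) {
  cl <- as.matrix(coastline)
  if (nrow(cl) < 2) stop("coastline must have at least 2 vertices")
  m <- as.matrix(pts)
  if (is.null(dim(m)) || ncol(m) != 2) m <- matrix(m, ncol = 2)
  px <- m[, 1]; py <- m[, 2]
  d2 <- rep(Inf, nrow(m))
  for (i in seq_len(nrow(cl) - 1)) {
    d2 <- pmin(d2, .pt_seg_dist2(px, py, cl[i, 1], cl[i, 2],
                                 cl[i + 1, 1], cl[i + 1, 2]))
  }
  sqrt(d2)
}

# cumulative arc length along a polyline (n x 2); first element 0
.cum_arclength <- function(xy) {
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

# point at arc length s along polyline; s clamped to [0, L]
.point_at_arclength <- function(xy, cs, s) {
  s <- pmin(max(cs), pmax(0, s))
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(i, nrow(xy) - 1)
  seg_len <- cs[i + 1] - cs[i]
  t <- ifelse(seg_len > 0, (s - cs[i]) / seg_len, 0)
  cbind(xy[i, 1] + t * (xy[i + 1, 1] - xy[i, 1]),
        xy[i, 2] + t * (xy[i + 1, 2] - xy[i, 2]))
}

# For each point: (along-track arc length of nearest point on polyline,
# perpendicular distance). Used to place sightings into segments.
.project_onto_polyline <- function(pts, xy) {
  cs <- .cum_arclength(xy)
  m <- as.matrix(pts)
  px <- m[, 1]; py <- m[, 2]
  best_d2 <- rep(Inf, nrow(m))
  best_s <- rep(0, nrow(m))
  for (i in seq_len(nrow(xy) - 1)) {
    ax <- xy[i, 1]; ay <- xy[i, 2]; bx <- xy[i + 1, 1]; by <- xy[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    if (L2 < 1e-300) next
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cs[i] + t[upd] * sqrt(L2)
  }
  list(along = best_s, perp = sqrt(best_d2))
}
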