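#' Construct a gridded raster
#'
#' Rasters are simple row-major grids in projected km coordinates: `values`
#' is an `nrows x ncols` matrix whose first row is the NORTHERNMOST row
#' (ESRI ASCII grid convention). Missing cells are `NA`.
#'
#' @param values numeric matrix (`nrows x ncols`), top row = max y.
#' @param xll,yll coordinates of the lower-left corner of the grid (km).
#' @param cellsize cell side (km).
#' @return object of class `"ascii_grid"`.
#' @export
ascii_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("ascii_grid: %d rows x %d cols, cell %.4g, origin (%.4g, %.4g), %d missing\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a plain-text (ESRI ASCII) grid
#'
#' Header lines `ncols nrows xllcorner yllcorner cellsize [NODATA_value]`
#' followed by `nrows` rows of `ncols` values, northernmost row first.
#'
#' @param path file path.
#' @return an [ascii_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header missing ", key)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  ascii_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write a plain-text (ESRI ASCII) grid
#'
#' @param grid an [ascii_grid()].
#' @param path file path.
#' @param digits significant digits for values.
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  stopifnot(inherits(grid, "ascii_grid"))
  v <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           "NODATA_value -9999")
  v[is.na(v)] <- -9999
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# cell-centre coordinates
.grid_xcenters <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
.grid_ycenters <- function(g) {
  # row 1 is the northernmost row
  g$yll + (nrow(g$values) - seq_len(nrow(g$values)) + 0.5) * g$cellsize
}

#' Raster value at points (containing-cell lookup)
#'
#' @param grid an [ascii_grid()].
#' @param pts two-column matrix of points (km).
#' @return numeric vector; `NA` outside the grid or in missing cells.
#' @export
grid_value_at <- function(grid, pts) {
  m <- as.matrix(pts)
  if (is.null(dim(m)) || ncol(m) != 2) m <- matrix(m, ncol = 2)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((m[, 1] - grid$xll) / grid$cellsize) + 1
  row_from_bottom <- floor((m[, 2] - grid$yll) / grid$cellsize) + 1
  row <- nr - row_from_bottom + 1
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr &
    is.finite(col) & is.finite(row)
  out <- rep(NA_real_, nrow(m))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Mean raster value over a rectangular strip footprint
#'
#' Averages the cells whose centres fall inside the (possibly rotated)
#' rectangle spanned by a segment chord of length `L` and half-width `w`.
#' If no cell centre falls inside (footprint smaller than a cell), the value
#' at the rectangle centre is used.
#'
#' @param grid an [ascii_grid()].
#' @param p0,p1 segment chord endpoints, length-2 numeric (km).
#' @param half_width strip half-width (km).
#' @return scalar mean (NA if all intersecting cells are missing).
#' @export
grid_mean_in_strip <- function(grid, p0, p1, half_width) {
  ctr <- (p0 + p1) / 2
  L <- sqrt(sum((p1 - p0)^2))
  if (L < 1e-12) return(grid_value_at(grid, matrix(ctr, ncol = 2)))
  u <- (p1 - p0) / L                      # along-chord unit vector
  # candidate cells: bounding box of the rectangle
  r <- sqrt((L / 2)^2 + half_width^2)
  xc <- .grid_xcenters(grid); yc <- .grid_ycenters(grid)
  ix <- which(xc >= ctr[1] - r - grid$cellsize & xc <= ctr[1] + r + grid$cellsize)
  iy <- which(yc >= ctr[2] - r - grid$cellsize & yc <= ctr[2] + r + grid$cellsize)
  if (length(ix) && length(iy)) {
    gx <- rep(xc[ix], each = length(iy))
    gy <- rep(yc[iy], times = length(ix))
    dx <- gx - ctr[1]; dy <- gy - ctr[2]
    along <- dx * u[1] + dy * u[2]
    perp <- -dx * u[2] + dy * u[1]
    inside <- abs(along) <= L / 2 & abs(perp) <= half_width
    if (any(inside)) {
      rows <- rep(iy, times = length(ix))[inside]
      cols <- rep(ix, each = length(iy))[inside]
      v <- grid$values[cbind(rows, cols)]
      if (all(is.na(v))) return(NA_real_)
      return(mean(v, na.rm = TRUE))
    }
  }
  grid_value_at(grid, matrix(ctr, ncol = 2))
}
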