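#' Inverse-distance-weighted interpolation surface
#'
#' Fills a rectangular longitude/latitude grid with the distance-weighted
#' average of scattered point values: each cell value is
#' \eqn{\sum_i w_i v_i / \sum_i w_i} with \eqn{w_i = d_i^{-power}}, where
#' \eqn{d_i} is the great-circle distance from the cell centre to point i,
#' so every cell is a convex combination of the data values. All points
#' contribute (no search radius). A cell whose centre coincides with a data
#' point (within 1e-9 degrees) takes that point's value exactly. Great-circle
#' rather than planar-degree distance is used because at continental extents
#' a degree of longitude shrinks with latitude.
#'
#' @param points data frame with `lon`, `lat`, `value`.
#' @param grid list with `lon_min`, `lon_max`, `lat_min`, `lat_max` and
#'   either `cell_deg` (cell size in degrees) or `n_cols`/`n_rows`.
#' @param power IDW exponent (default 2, the common GIS default); must be
#'   positive.
#' @return An object of class `grid_surface`: cell-centre coordinate vectors
#'   `lon` and `lat`, a `values` matrix (rows = latitudes, columns =
#'   longitudes), the `power`, and empty classing fields until
#'   [classify_equal_intervals()] is applied.
#' @export
idw_interpolate <- function(points, grid, power = 2) {
  stopifnot(is.data.frame(points),
            all(c("lon", "lat", "value") %in% names(points)))
  if (!nrow(points)) stop("empty points")
  if (!is.finite(power) || power <= 0) stop("power must be positive")
  if (!is.null(grid$cell_deg)) {
    lon <- seq(grid$lon_min + grid$cell_deg / 2, grid$lon_max,
               by = grid$cell_deg)
    lat <- seq(grid$lat_min + grid$cell_deg / 2, grid$lat_max,
               by = grid$cell_deg)
  } else {
    lon <- seq(grid$lon_min, grid$lon_max, length.out = grid$n_cols)
    lat <- seq(grid$lat_min, grid$lat_max, length.out = grid$n_rows)
  }
  eps <- 1e-9
  cells <- cbind(rep(lon, each = length(lat)), rep(lat, times = length(lon)))
  d <- geosphere::distm(cells, cbind(points$lon, points$lat),
                        fun = geosphere::distCosine)  # cells x points
  w <- d^(-power)
  cell_vals <- as.vector((w %*% points$value) / rowSums(w))
  hit <- abs(outer(cells[, 1], points$lon, "-")) < eps &
    abs(outer(cells[, 2], points$lat, "-")) < eps
  for (r in which(rowSums(hit) > 0))
    cell_vals[r] <- points$value[which(hit[r, ])[1]]
  vals <- matrix(cell_vals, nrow = length(lat), ncol = length(lon))
  structure(list(lon = lon, lat = lat, values = vals, power = power,
                 k = NULL, class_index = NULL),
            class = "grid_surface")
}

#' Divide a surface into equal-interval classes
#'
#' Splits the value range into `k` classes of equal width
#' `(max - min) / k`. Boundaries follow the half-open convention: a value
#' exactly on a boundary belongs to the upper class, except the global
#' maximum which belongs to class `k`.
#'
#' @param surface a `grid_surface`.
#' @param k number of classes (default 10).
#' @return The surface with `class_index` (integer matrix, 1..k) and `k`
#'   filled in.
#' @export
classify_equal_intervals <- function(surface, k = 10) {
  stopifnot(inherits(surface, "grid_surface"), k >= 2)
  v <- surface$values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("zero range: constant surface cannot be classed")
  width <- diff(rng) / k
  idx <- floor((v - rng[1]) / width) + 1L
  idx[v >= rng[2]] <- as.integer(k)
  storage.mode(idx) <- "integer"
  surface$class_index <- idx
  surface$k <- as.integer(k)
  surface
}

#' @export
print.grid_surface <- function(x, ...) {
  cat("grid_surface: ", length(x$lat), " x ", length(x$lon), " cells, lon [",
      min(x$lon), ", ", max(x$lon), "], lat [", min(x$lat), ", ",
      max(x$lat), "], power ", x$power,
      if (!is.null(x$k)) paste0(", ", x$k, " classes"), "\n", sep = "")
  invisible(x)
}

#' Interpolation surface of a published diversity statistic
#'
#' Builds the IDW surface of Ho, He or Fis over one continent's breed
#' sampling sites from the packaged tables, on a grid covering the sites
#' with a margin, classed into `k` equal intervals.
#'
#' @param continent `"Europe"`, `"Africa"` or `"Asia"`.
#' @param statistic `"ho"`, `"he"` or `"fis"`.
#' @param cell_deg grid cell size in degrees (default 1).
#' @param power IDW exponent (default 2).
#' @param margin grid margin around the breed coordinates, degrees.
#' @param k number of equal-interval classes (default 10).
#' @return A classed `grid_surface`.
#' @export
surface_from_fixture <- function(continent, statistic = c("ho", "he", "fis"),
                                 cell_deg = 1, power = 2, margin = 2, k = 10) {
  statistic <- match.arg(statistic)
  tab <- load_goat_tables(continent)$table
  pts <- data.frame(lon = tab$lon, lat = tab$lat, value = tab[[statistic]])
  pts <- pts[is.finite(pts$value), ]
  grid <- list(lon_min = floor(min(pts$lon)) - margin,
               lon_max = ceiling(max(pts$lon)) + margin,
               lat_min = floor(min(pts$lat)) - margin,
               lat_max = ceiling(max(pts$lat)) + margin,
               cell_deg = cell_deg)
  classify_equal_intervals(idw_interpolate(pts, grid, power = power), k = k)
}

#' Value or class of the surface cell containing a point
#'
#' @param surface a `grid_surface`.
#' @param lon,lat point coordinates.
#' @param what `"value"` or `"class"`.
#' @return The cell's interpolated value or class index.
#' @export
surface_cell_at <- function(surface, lon, lat, what = c("value", "class")) {
  what <- match.arg(what)
  i <- which.min(abs(surface$lat - lat))
  j <- which.min(abs(surface$lon - lon))
  if (what == "value") surface$values[i, j] else surface$class_index[i, j]
}
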