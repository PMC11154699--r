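#' Vegetation class vocabulary
#'
#' The eight-class vocabulary used throughout the package: seven vegetated
#' biome classes plus \code{"Other"}, which absorbs water bodies and
#' unclassified land. Parameter tables are keyed by the first seven.
#'
#' @param vegetated_only if \code{TRUE}, drop \code{"Other"}.
#' @return character vector of class labels.
#' @export
#' @examples
#' veg_classes()
veg_classes <- function(vegetated_only = FALSE) {
  cls <- c("Grassland", "Cropland", "Savanna", "Shrubland",
           "DeciduousForest", "EvergreenForest", "MixedForest", "Other")
  if (vegetated_only) cls[cls != "Other"] else cls
}

#' Regular latitude/longitude grid
#'
#' A cell-center-registered regular geographic grid. Cell \code{(i, j)} covers
#' the half-open box \code{[center - res/2, center + res/2)} in both
#' coordinates, which makes nesting of a 0.05-degree grid inside a 0.1-degree
#' grid exact.
#'
#' @param lat_centers cell-center latitudes, degrees north, ascending,
#'   uniformly spaced.
#' @param lon_centers cell-center longitudes, degrees east, ascending,
#'   uniformly spaced with the same spacing as \code{lat_centers}.
#' @return an object of class \code{vprm_grid} with elements \code{lat},
#'   \code{lon} and \code{res} (grid spacing in degrees).
#' @export
#' @examples
#' g <- vprm_grid(seq(20.05, 21.95, by = 0.1), seq(75.05, 76.95, by = 0.1))
#' g$res
vprm_grid <- function(lat_centers, lon_centers) {
  lat <- as.numeric(lat_centers)
  lon <- as.numeric(lon_centers)
  res <- .uniform_spacing(lat, "lat_centers")
  res_lon <- .uniform_spacing(lon, "lon_centers")
  if (abs(res - res_lon) > 1e-9 * max(res, res_lon))
    stop("latitude spacing (", res, ") and longitude spacing (", res_lon,
         ") differ; only square cells are supported")
  structure(list(lat = lat, lon = lon, res = res), class = "vprm_grid")
}

.uniform_spacing <- function(x, what) {
  if (length(x) < 1L) stop(what, " is empty")
  if (length(x) == 1L) stop(what, " needs at least 2 centers to infer spacing")
  d <- diff(x)
  if (any(d <= 0)) stop(what, " must be strictly ascending")
  res <- mean(d)
  if (any(abs(d - res) > 1e-6 * res))
    stop(what, " is not uniformly spaced")
  res
}

#' Construct a grid from its bounding box
#'
#' Convenience constructor: \code{n_lat} x \code{n_lon} cells of size
#' \code{resolution} whose south-west cell corner sits at
#' (\code{lat_min}, \code{lon_min}).
#'
#' @param lat_min,lon_min south-west corner of the domain (cell edge), degrees.
#' @param n_lat,n_lon number of cells in each direction.
#' @param resolution cell size in degrees.
#' @return a \code{\link{vprm_grid}}.
#' @export
grid_from_extent <- function(lat_min, lon_min, n_lat, n_lon, resolution) {
  stopifnot(resolution > 0, n_lat >= 2, n_lon >= 2)
  vprm_grid(lat_min + resolution * (seq_len(n_lat) - 0.5),
            lon_min + resolution * (seq_len(n_lon) - 0.5))
}

#' @export
print.vprm_grid <- function(x, ...) {
  cat(sprintf("<vprm_grid> %d x %d cells at %.4g deg, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              length(x$lat), length(x$lon), x$res,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}

#' Gridded space-time field
#'
#' A variable on a \code{\link{vprm_grid}} with one layer per time step.
#' Missing observations are \code{NA}; masks are never encoded as sentinel
#' numerics.
#'
#' @param values numeric array of dimension \code{(n_time, n_lat, n_lon)}, or
#'   a \code{(n_lat, n_lon)} matrix for a single-layer field.
#' @param grid a \code{\link{vprm_grid}}.
#' @param times \code{Date} vector of layer (composite-period) start dates, or
#'   \code{NULL} for a time-invariant field.
#' @param units unit string (non-empty).
#' @param name variable identifier.
#' @return an object of class \code{gridded_field}.
#' @export
gridded_field <- function(values, grid, times = NULL, units = "1",
                          name = "field") {
  if (!inherits(grid, "vprm_grid")) stop("grid must be a vprm_grid")
  if (is.matrix(values)) values <- array(values, dim = c(1L, dim(values)))
  if (length(dim(values)) != 3L)
    stop("values must be a (time, lat, lon) array or a (lat, lon) matrix")
  d <- dim(values)
  if (d[2] != length(grid$lat) || d[3] != length(grid$lon))
    stop("values dimensions (", d[2], " x ", d[3],
         ") do not match the grid (", length(grid$lat), " x ",
         length(grid$lon), ")")
  if (!is.null(times)) {
    times <- as.Date(times)
    if (length(times) != d[1])
      stop("length(times) = ", length(times),
           " does not match the time dimension (", d[1], ")")
  } else if (d[1] != 1L) {
    stop("a field with ", d[1], " layers needs times")
  }
  if (!nzchar(units)) stop("units must be a non-empty string")
  structure(list(values = values, grid = grid, times = times,
                 units = units, name = name),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %s [%s]: %d time x %d lat x %d lon (%.1f%% missing)\n",
              x$name, x$units, d[1], d[2], d[3],
              100 * mean(is.na(x$values))))
  invisible(x)
}

# rebuild a field with new values but shared metadata
field_like <- function(template, values, units = template$units,
                       name = template$name) {
  gridded_field(values, template$grid, template$times, units, name)
}

check_cogridded <- function(..., .times = TRUE) {
  fs <- list(...)
  ref <- fs[[1]]
  for (f in fs[-1]) {
    if (!same_grid(ref$grid, f$grid))
      stop("fields '", ref$name, "' and '", f$name, "' are not on the same grid")
    if (.times && !identical(dim(ref$values)[1], dim(f$values)[1]))
      stop("fields '", ref$name, "' and '", f$name,
           "' have different numbers of time layers")
  }
  invisible(TRUE)
}

#' Per-cell vegetation class map
#'
#' @param classes character matrix of dimension \code{(n_lat, n_lon)} with
#'   labels from \code{\link{veg_classes}}; every cell must be labelled
#'   (\code{"Other"} absorbs water and unclassified cells).
#' @param grid a \code{\link{vprm_grid}}.
#' @return an object of class \code{veg_map}.
#' @export
veg_map <- function(classes, grid) {
  if (!inherits(grid, "vprm_grid")) stop("grid must be a vprm_grid")
  classes <- as.matrix(classes)
  mode(classes) <- "character"
  if (nrow(classes) != length(grid$lat) || ncol(classes) != length(grid$lon))
    stop("class matrix does not match the grid")
  bad <- setdiff(unique(as.vector(classes)), veg_classes())
  if (anyNA(classes)) stop("every cell must carry a class label")
  if (length(bad))
    stop("unknown vegetation class label(s): ", paste(bad, collapse = ", "))
  structure(list(classes = classes, grid = grid), class = "veg_map")
}

#' @export
print.veg_map <- function(x, ...) {
  tab <- table(x$classes)
  cat("<veg_map> ", nrow(x$classes), " x ", ncol(x$classes), " cells: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Boolean mask for one vegetation class
#'
#' @param vegmap a \code{\link{veg_map}}.
#' @param cls a single label from \code{\link{veg_classes}}.
#' @return logical \code{(n_lat, n_lon)} matrix, \code{TRUE} exactly where the
#'   map equals \code{cls}. Masks over all labels are disjoint and cover the
#'   grid.
#' @export
class_mask <- function(vegmap, cls) {
  stopifnot(inherits(vegmap, "veg_map"), length(cls) == 1L)
  if (!cls %in% veg_classes())
    stop("unknown vegetation class label: ", cls)
  vegmap$classes == cls
}

#' Broadcast class labels over time layers
#'
#' Replicates a vegetation map's class labels into a \code{(time, lat, lon)}
#' character array aligned with a field's values, convenient for per-class
#' subsetting of space-time samples.
#'
#' @param vegmap a \code{\link{veg_map}}.
#' @param ntime number of time layers.
#' @return character array of dimension \code{(ntime, n_lat, n_lon)}.
#' @export
class_array <- function(vegmap, ntime) {
  array(rep(vegmap$classes, each = ntime),
        dim = c(ntime, dim(vegmap$classes)))
}

#' 8-day composite calendar
#'
#' MODIS-convention composite periods: 46 per year, starting at day-of-year
#' 1, 9, 17, ..., 361; the final period is truncated at the year end (5 days,
#' 6 in leap years).
#'
#' @param year calendar year.
#' @return an object of class \code{composite_calendar} with \code{year},
#'   \code{starts} (46 dates) and \code{ends} (inclusive period end dates).
#' @export
#' @examples
#' cal <- composite_calendar(2019)
#' length(cal$starts)  # 46
composite_calendar <- function(year) {
  stopifnot(length(year) == 1L, year == round(year))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dec31 <- as.Date(sprintf("%d-12-31", year))
  starts <- jan1 + seq(0L, by = 8L, length.out = 46L)
  ends <- pmin(starts + 7L, dec31)
  structure(list(year = as.integer(year), starts = starts, ends = ends),
            class = "composite_calendar")
}

#' Block-mean regridding of a fine field onto a coarser nested grid
#'
#' Each coarse cell takes the arithmetic mean of the non-missing fine cells it
#' contains (e.g. 0.05-degree SIF onto the 0.1-degree model grid). The coarse
#' cell is missing only when all its fine cells are missing, so the domain
#' mean is conserved on fully observed grids.
#'
#' @param src a \code{\link{gridded_field}} on the fine grid.
#' @param dst_grid target \code{\link{vprm_grid}}; its resolution must be an
#'   integer multiple of the source resolution and the grids must nest
#'   exactly (coarse cell centers at the mean of the fine centers they cover).
#' @return a \code{\link{gridded_field}} on \code{dst_grid}.
#' @export
regrid_block_mean <- function(src, dst_grid) {
  stopifnot(inherits(src, "gridded_field"), inherits(dst_grid, "vprm_grid"))
  g <- src$grid
  ratio <- dst_grid$res / g$res
  f <- round(ratio)
  if (f < 1 || abs(ratio - f) > 1e-6)
    stop("destination resolution ", dst_grid$res,
         " is not an integer multiple of source resolution ", g$res)
  if (length(g$lat) != f * length(dst_grid$lat) ||
      length(g$lon) != f * length(dst_grid$lon))
    stop("grids do not nest: ", length(g$lat), "x", length(g$lon),
         " fine cells cannot tile ", length(dst_grid$lat), "x",
         length(dst_grid$lon), " coarse cells at factor ", f)
  blk_lat <- rep(seq_along(dst_grid$lat), each = f)
  blk_lon <- rep(seq_along(dst_grid$lon), each = f)
  ok_lat <- tapply(g$lat, blk_lat, mean)
  ok_lon <- tapply(g$lon, blk_lon, mean)
  if (any(abs(ok_lat - dst_grid$lat) > 1e-6) ||
      any(abs(ok_lon - dst_grid$lon) > 1e-6))
    stop("grids do not nest: fine-cell blocks are not centered on coarse ",
         "cells (source ", g$res, " deg vs destination ", dst_grid$res, " deg)")
  nt <- dim(src$values)[1]
  out <- array(NA_real_,
               dim = c(nt, length(dst_grid$lat), length(dst_grid$lon)))
  for (t in seq_len(nt)) {
    slab <- src$values[t, , , drop = TRUE]
    if (is.null(dim(slab))) slab <- matrix(slab, length(g$lat), length(g$lon))
    sums <- rowsum(slab, blk_lat, na.rm = TRUE)
    sums <- t(rowsum(t(sums), blk_lon, na.rm = TRUE))
    cnts <- rowsum(1 - is.na(slab) * 1, blk_lat)
    cnts <- t(rowsum(t(cnts), blk_lon))
    m <- sums / cnts
    m[cnts == 0] <- NA_real_
    out[t, , ] <- m
  }
  gridded_field(out, dst_grid, src$times, src$units, src$name)
}

#' Aggregate daily layers onto the 8-day composite calendar
#'
#' Each composite layer is the mean of the non-missing daily values whose date
#' falls within the period; a composite cell is missing when no daily data
#' contribute.
#'
#' @param daily a \code{\link{gridded_field}} with one layer per day; all
#'   \code{times} must fall within the calendar year.
#' @param cal a \code{\link{composite_calendar}}.
#' @return a \code{\link{gridded_field}} with one layer per composite period,
#'   timed at the period starts.
#' @export
aggregate_to_composites <- function(daily, cal) {
  stopifnot(inherits(daily, "gridded_field"),
            inherits(cal, "composite_calendar"))
  if (is.null(daily$times) || dim(daily$values)[1] == 0L)
    stop("daily input is empty")
  yr <- as.integer(format(daily$times, "%Y"))
  if (any(yr != cal$year))
    stop("daily timestamps fall outside calendar year ", cal$year)
  period <- findInterval(daily$times, cal$starts)
  np <- length(cal$starts)
  d <- dim(daily$values)
  out <- array(NA_real_, dim = c(np, d[2], d[3]))
  for (p in seq_len(np)) {
    sel <- which(period == p)
    if (!length(sel)) next
    slab <- daily$values[sel, , , drop = FALSE]
    cnt <- colSums(!is.na(slab), dims = 1)
    s <- colSums(slab, dims = 1, na.rm = TRUE)
    m <- s / cnt
    m[cnt == 0] <- NA_real_
    out[p, , ] <- m
  }
  gridded_field(out, daily$grid, cal$starts, daily$units, daily$name)
}
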