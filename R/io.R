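#' Write a gridded field to long-format CSV
#'
#' Serialises a \code{\link{gridded_field}} as plain text: a small JSON-like
#' header in \code{#}-comment lines (name, units, grid resolution) followed
#' by one row per (time, lat, lon) sample. Missing cells are written as
#' empty values. The format round-trips through
#' \code{\link{read_field_csv}}.
#'
#' @param field a \code{\link{gridded_field}}.
#' @param path output file path.
#' @param drop_na omit missing cells from the file (they are reconstructed as
#'   masks on read); default \code{TRUE} keeps files small.
#' @return \code{path}, invisibly.
#' @export
write_field_csv <- function(field, path, drop_na = TRUE) {
  stopifnot(inherits(field, "gridded_field"))
  d <- dim(field$values)
  times <- if (is.null(field$times)) rep(NA_character_, d[1])
           else format(field$times, "%Y-%m-%d")
  df <- data.frame(
    time = rep(times, times = d[2] * d[3]),
    lat = rep(rep(field$grid$lat, each = d[1]), times = d[3]),
    lon = rep(field$grid$lon, each = d[1] * d[2]),
    value = as.vector(field$values))
  if (drop_na) df <- df[!is.na(df$value), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# name: ", field$name),
    paste0("# units: ", field$units),
    paste0("# resolution: ", format(field$grid$res, digits = 12)),
    paste0("# lat_range: ", format(min(field$grid$lat), digits = 12), " ",
           format(max(field$grid$lat), digits = 12), " n ", d[2]),
    paste0("# lon_range: ", format(min(field$grid$lon), digits = 12), " ",
           format(max(field$grid$lon), digits = 12), " n ", d[3]),
    paste0("# times: ", paste(unique(times), collapse = " "))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' Counterpart of \code{\link{write_field_csv}}: rebuilds the grid from the
#' header, fills unlisted (time, lat, lon) samples as missing.
#'
#' @param path file written by \code{\link{write_field_csv}}.
#' @return a \code{\link{gridded_field}}.
#' @export
read_field_csv <- function(path) {
  hdr <- readLines(path, n = 6L)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed field CSV: missing header '", key, "'")
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  name <- get_hdr("name")
  units <- get_hdr("units")
  lat_sp <- strsplit(get_hdr("lat_range"), " ")[[1]]
  lon_sp <- strsplit(get_hdr("lon_range"), " ")[[1]]
  n_lat <- as.integer(lat_sp[4])
  n_lon <- as.integer(lon_sp[4])
  grid <- vprm_grid(seq(as.numeric(lat_sp[1]), as.numeric(lat_sp[2]),
                        length.out = n_lat),
                    seq(as.numeric(lon_sp[1]), as.numeric(lon_sp[2]),
                        length.out = n_lon))
  tstr <- strsplit(get_hdr("times"), " ")[[1]]
  has_times <- !all(tstr == "NA")
  times <- if (has_times) as.Date(tstr) else NULL
  nt <- max(length(tstr), 1L)
  df <- utils::read.csv(path, comment.char = "#")
  vals <- array(NA_real_, dim = c(nt, n_lat, n_lon))
  ti <- if (has_times) match(as.Date(df$time), times) else rep(1L, nrow(df))
  li <- round((df$lat - grid$lat[1]) / grid$res) + 1L
  oi <- round((df$lon - grid$lon[1]) / grid$res) + 1L
  vals[cbind(ti, li, oi)] <- df$value
  gridded_field(vals, grid, times, units, name)
}

#' Write a vegetation map to CSV
#'
#' One row per cell with its class label; header comments carry the grid.
#'
#' @param vegmap a \code{\link{veg_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vegmap_csv <- function(vegmap, path) {
  stopifnot(inherits(vegmap, "veg_map"))
  g <- vegmap$grid
  df <- data.frame(
    lat = rep(g$lat, times = length(g$lon)),
    lon = rep(g$lon, each = length(g$lat)),
    class = as.vector(vegmap$classes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# resolution: ", format(g$res, digits = 12)),
    paste0("# lat_range: ", format(min(g$lat), digits = 12), " ",
           format(max(g$lat), digits = 12), " n ", length(g$lat)),
    paste0("# lon_range: ", format(min(g$lon), digits = 12), " ",
           format(max(g$lon), digits = 12), " n ", length(g$lon))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a vegetation map from CSV
#'
#' @param path file written by \code{\link{write_vegmap_csv}}.
#' @return a \code{\link{veg_map}}.
#' @export
read_vegmap_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed vegmap CSV: missing header '", key, "'")
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  lat_sp <- strsplit(get_hdr("lat_range"), " ")[[1]]
  lon_sp <- strsplit(get_hdr("lon_range"), " ")[[1]]
  n_lat <- as.integer(lat_sp[4])
  n_lon <- as.integer(lon_sp[4])
  grid <- vprm_grid(seq(as.numeric(lat_sp[1]), as.numeric(lat_sp[2]),
                        length.out = n_lat),
                    seq(as.numeric(lon_sp[1]), as.numeric(lon_sp[2]),
                        length.out = n_lon))
  df <- utils::read.csv(path, comment.char = "#")
  cls <- matrix(NA_character_, n_lat, n_lon)
  li <- round((df$lat - grid$lat[1]) / grid$res) + 1L
  oi <- round((df$lon - grid$lon[1]) / grid$res) + 1L
  cls[cbind(li, oi)] <- df$class
  veg_map(cls, grid)
}
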