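# small in-code fixtures shared across test files

mk_grid <- function(n_lat = 4, n_lon = 4, res = 0.1, lat0 = 20, lon0 = 75) {
  grid_from_extent(lat0, lon0, n_lat, n_lon, res)
}

# a field holding a constant (or a supplied array) over n_time layers
mk_field <- function(x, grid = mk_grid(), n_time = 1L, year = 2019,
                     units = "1", name = "x") {
  nt <- if (is.array(x) && length(dim(x)) == 3L) dim(x)[1] else n_time
  if (!is.array(x) || length(dim(x)) != 3L)
    x <- array(x, dim = c(nt, length(grid$lat), length(grid$lon)))
  times <- composite_calendar(year)$starts[seq_len(nt)]
  gridded_field(x, grid, times, units, name)
}

uniform_map <- function(cls = "Grassland", grid = mk_grid()) {
  veg_map(matrix(cls, length(grid$lat), length(grid$lon)), grid)
}

# deterministic checkerboard over two classes
checker_map <- function(cls_a = "Grassland", cls_b = "Cropland",
                        grid = mk_grid()) {
  idx <- outer(seq_along(grid$lat), seq_along(grid$lon), `+`) %% 2L
  veg_map(matrix(ifelse(idx == 0, cls_a, cls_b),
                 length(grid$lat), length(grid$lon)), grid)
}

# the small noiseless scene used by several recovery tests
noiseless_scene <- function(seed = 7, n_lat = 8, n_lon = 8) {
  generate_scene(scene_config(n_lat = n_lat, n_lon = n_lon, seed = seed,
                              sif_noise_sd = 0, reco_noise_sd = 0,
                              missing_frac = 0))
}
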