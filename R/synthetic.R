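.default_class_param <- function(x, classes) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(classes)), classes))
  missing_cls <- setdiff(classes, names(x))
  if (length(missing_cls))
    stop("per-class parameter missing for: ", paste(missing_cls, collapse = ", "))
  x[classes]
}

#' Synthetic-scene configuration
#'
#' Describes a fully synthetic study domain with the statistical structure
#' the refinement method assumes: per-biome sinusoidal seasonal cycles for
#' the vegetation indices and SIF (monsoon-like late-season peaks for
#' cropland and deciduous forest), a fine-grid SIF product carrying a known
#' per-class multiplicative offset to its coarse-grid counterpart, seasonal
#' meteorology and soil fields, and reference GPP/respiration built from
#' known truth coefficients so every fitting operation has a recoverable
#' target.
#'
#' Per-class arguments accept either a single number (recycled) or a named
#' vector over the seven vegetated classes.
#'
#' @param lat_min,lon_min south-west corner of the coarse domain, degrees.
#' @param n_lat,n_lon coarse-grid size (cells); the fine SIF grid is 2x
#'   finer.
#' @param resolution coarse cell size, degrees (default 0.1; fine grid at
#'   half of it).
#' @param year calendar year of the 46 composite periods.
#' @param layout \code{"blocks"} (longitude strips cycling through all 8
#'   classes; the default covers every vegetated class),
#'   \code{"checkerboard"}, or \code{"uniform"}.
#' @param uniform_class class used by the uniform layout.
#' @param evi_base,evi_amp,lswi_base,lswi_amp per-class seasonal baseline and
#'   amplitude of EVI and LSWI (dimensionless).
#' @param sif_base,sif_amp per-class SIF baseline/amplitude on the
#'   fine-product scale, mW m⁻² sr⁻¹ nm⁻¹.
#' @param peak_doy per-class day-of-year of peak greenness/SIF.
#' @param s0 per-class true cross-sensor factor (coarse product =
#'   \code{s0} x fine product); defaults to the packaged reference factors.
#' @param sif_noise_sd additive Gaussian noise on the coarse SIF product,
#'   mW m⁻² sr⁻¹ nm⁻¹.
#' @param missing_frac fraction of fine SIF cells randomly masked
#'   (cloud-like gaps).
#' @param tair_range seasonal min/max of 2 m air temperature, °C.
#' @param swdown_max seasonal peak of downward shortwave radiation,
#'   µmol m⁻² s⁻¹.
#' @param sm_range seasonal min/max volumetric soil moisture, m³ m⁻³.
#' @param st_range seasonal min/max soil temperature, K.
#' @param eta0,eps0 per-class truth for the GPP refinement
#'   (\eqn{GPP_{SIF} = \eta_0 GPP_{VPRM} + \epsilon_0}); \code{eta0}
#'   defaults to the packaged TROPOSIF-side reference factors.
#' @param nu0,tau0,kappa0 truth coefficients of the refined respiration
#'   (units as in \code{\link{fit_reco_params}}).
#' @param reco_noise_sd additive Gaussian noise on the reference respiration,
#'   µmol CO2 m⁻² s⁻¹.
#' @param seed integer random seed recorded in the bundle; the same seed
#'   reproduces the scene bit-for-bit.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(lat_min = 20, lon_min = 75, n_lat = 20, n_lon = 20,
                         resolution = 0.1, year = 2019,
                         layout = c("blocks", "checkerboard", "uniform"),
                         uniform_class = "DeciduousForest",
                         evi_base = c(Grassland = 0.15, Cropland = 0.20,
                                      Savanna = 0.18, Shrubland = 0.15,
                                      DeciduousForest = 0.25,
                                      EvergreenForest = 0.45,
                                      MixedForest = 0.35),
                         evi_amp = c(Grassland = 0.25, Cropland = 0.45,
                                     Savanna = 0.30, Shrubland = 0.20,
                                     DeciduousForest = 0.40,
                                     EvergreenForest = 0.15,
                                     MixedForest = 0.25),
                         lswi_base = 0.05, lswi_amp = 0.30,
                         sif_base = 0.05,
                         sif_amp = c(Grassland = 0.40, Cropland = 0.90,
                                     Savanna = 0.50, Shrubland = 0.50,
                                     DeciduousForest = 0.90,
                                     EvergreenForest = 1.10,
                                     MixedForest = 0.90),
                         peak_doy = c(Grassland = 230, Cropland = 250,
                                      Savanna = 240, Shrubland = 230,
                                      DeciduousForest = 250,
                                      EvergreenForest = 200,
                                      MixedForest = 220),
                         s0 = NULL,
                         sif_noise_sd = 0.05,
                         missing_frac = 0,
                         tair_range = c(12, 34),
                         swdown_max = 1500,
                         sm_range = c(0.08, 0.42),
                         st_range = c(286, 308),
                         eta0 = NULL, eps0 = 0.2,
                         nu0 = 5, tau0 = 0.01, kappa0 = 0.9,
                         reco_noise_sd = 0.1,
                         seed = 42L) {
  layout <- match.arg(layout)
  cls <- veg_classes(TRUE)
  if (is.null(s0)) {
    tab <- sif_scaling_table()
    s0 <- stats::setNames(tab$s, tab$class)
  }
  if (is.null(eta0)) {
    tab <- gpp_refinement_table()
    tab <- tab[tab$product == "troposif", ]
    eta0 <- stats::setNames(tab$eta, tab$class)
  }
  stopifnot(sif_noise_sd >= 0, reco_noise_sd >= 0,
            missing_frac >= 0, missing_frac < 1,
            resolution > 0, n_lat >= 2, n_lon >= 2)
  cfg <- list(lat_min = lat_min, lon_min = lon_min, n_lat = n_lat,
              n_lon = n_lon, resolution = resolution, year = year,
              layout = layout, uniform_class = uniform_class,
              evi_base = .default_class_param(evi_base, cls),
              evi_amp = .default_class_param(evi_amp, cls),
              lswi_base = .default_class_param(lswi_base, cls),
              lswi_amp = .default_class_param(lswi_amp, cls),
              sif_base = .default_class_param(sif_base, cls),
              sif_amp = .default_class_param(sif_amp, cls),
              peak_doy = .default_class_param(peak_doy, cls),
              s0 = .default_class_param(s0, cls),
              sif_noise_sd = sif_noise_sd, missing_frac = missing_frac,
              tair_range = tair_range, swdown_max = swdown_max,
              sm_range = sm_range, st_range = st_range,
              eta0 = .default_class_param(eta0, cls),
              eps0 = .default_class_param(eps0, cls),
              nu0 = nu0, tau0 = tau0, kappa0 = kappa0,
              reco_noise_sd = reco_noise_sd, seed = as.integer(seed))
  structure(cfg, class = "scene_config")
}

# class layout matrix on a grid; blocks are longitude strips cycling through
# the full 8-class vocabulary so every vegetated class occurs
.layout_classes <- function(cfg, n_lat, n_lon) {
  all8 <- veg_classes()
  if (cfg$layout == "uniform") {
    if (!cfg$uniform_class %in% all8)
      stop("unknown vegetation class label: ", cfg$uniform_class)
    return(matrix(cfg$uniform_class, n_lat, n_lon))
  }
  if (cfg$layout == "blocks") {
    if (n_lon < length(all8))
      stop("blocks layout needs at least ", length(all8),
           " longitude cells, got ", n_lon)
    strip <- ceiling(seq_len(n_lon) * length(all8) / n_lon)
    return(matrix(all8[strip], n_lat, n_lon, byrow = TRUE))
  }
  # checkerboard over the vocabulary
  idx <- (outer(seq_len(n_lat), seq_len(n_lon), `+`) %% length(all8)) + 1L
  matrix(all8[idx], n_lat, n_lon)
}

# seasonal weight in [0, 1] peaking at `peak` day-of-year
.seasonal <- function(doy, peak) 0.5 * (1 + cos(2 * pi * (doy - peak) / 365.25))

# smooth deterministic spatial texture in [-1, 1]
.texture <- function(grid) {
  outer(sin(grid$lat * 2.1), cos(grid$lon * 1.7))
}

# per-class seasonal field: base + amp * seasonal(doy) + scale * texture
.class_seasonal_field <- function(base, amp, peak, classes, doys, grid,
                                  tex_scale = 0) {
  nt <- length(doys)
  nlat <- nrow(classes)
  nlon <- ncol(classes)
  out <- array(NA_real_, dim = c(nt, nlat, nlon))
  tex <- .texture(grid)
  base_m <- matrix(0, nlat, nlon)
  amp_m <- matrix(0, nlat, nlon)
  peak_m <- matrix(200, nlat, nlon)
  veg <- classes != "Other"
  base_m[veg] <- base[classes[veg]]
  amp_m[veg] <- amp[classes[veg]]
  peak_m[veg] <- peak[classes[veg]]
  for (t in seq_len(nt)) {
    sea <- 0.5 * (1 + cos(2 * pi * (doys[t] - peak_m) / 365.25))
    out[t, , ] <- base_m + amp_m * sea + tex_scale * tex
  }
  out
}

#' Generate a synthetic study scene
#'
#' Builds every input the modelling chain consumes, deterministically from
#' the config seed: surface-reflectance bands whose derived EVI/LSWI follow
#' the configured per-biome seasonal cycles, air temperature and shortwave
#' radiation, soil moisture and soil temperature, a fine-grid SIF product
#' (half the coarse resolution) and a coarse-grid SIF product equal to the
#' per-class factor \code{s0} times the block-mean-regridded fine product
#' plus noise, and reference GPP/respiration fields built from the truth
#' coefficients. The previous RNG state is restored on exit.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @return a list bundle with the coarse \code{grid} and \code{fine_grid},
#'   \code{vegmap} (+\code{vegmap_fine}), the composite \code{calendar},
#'   reflectance bands (\code{red}, \code{nir}, \code{blue}, \code{swir}),
#'   derived \code{evi}/\code{lswi}, meteorology (\code{t_air},
#'   \code{swdown}), soils (\code{sm}, \code{st}), SIF products
#'   (\code{gosif} fine, \code{troposif} coarse), model fields
#'   (\code{gpp_vprm}, \code{reco_vprm}), truth-based references
#'   (\code{gpp_sif_ref}, \code{reco_ref}), a pseudo eddy-covariance
#'   \code{site} (cell indices and class), and the \code{truth} list of
#'   generating coefficients (including the seed).
#' @export
#' @examples
#' scn <- generate_scene(scene_config(n_lat = 8, n_lon = 8, seed = 1))
#' scn$truth$s0[["Grassland"]]
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(cfg$seed)

  grid <- grid_from_extent(cfg$lat_min, cfg$lon_min, cfg$n_lat, cfg$n_lon,
                           cfg$resolution)
  fine_grid <- grid_from_extent(cfg$lat_min, cfg$lon_min, 2 * cfg$n_lat,
                                2 * cfg$n_lon, cfg$resolution / 2)
  cal <- composite_calendar(cfg$year)
  doys <- as.integer(format(cal$starts, "%j")) + 3.5  # period midpoints
  nt <- length(cal$starts)

  classes <- .layout_classes(cfg, cfg$n_lat, cfg$n_lon)
  vegmap <- veg_map(classes, grid)
  # fine map replicates each coarse cell 2x2 so the grids nest thematically
  classes_f <- classes[rep(seq_len(cfg$n_lat), each = 2),
                       rep(seq_len(cfg$n_lon), each = 2)]
  vegmap_fine <- veg_map(classes_f, fine_grid)

  mk <- function(values, units, name, g = grid)
    gridded_field(values, g, cal$starts, units, name)

  # vegetation indices, then reflectances solved back from them so that
  # compute_evi()/compute_lswi() reproduce the configured cycles
  evi_v <- .class_seasonal_field(cfg$evi_base, cfg$evi_amp, cfg$peak_doy,
                                 classes, doys, grid, tex_scale = 0.02)
  evi_v <- pmin(pmax(evi_v, 0.02), 0.95)
  lswi_v <- .class_seasonal_field(cfg$lswi_base, cfg$lswi_amp, cfg$peak_doy,
                                  classes, doys, grid, tex_scale = 0.02)
  lswi_v <- pmin(pmax(lswi_v, 0), 0.6)
  blue_v <- array(0.05, dim = dim(evi_v))
  red_v <- array(0.10, dim = dim(evi_v))
  nir_v <- (2.5 * red_v + evi_v * (6 * red_v - 7.5 * blue_v + 1)) /
    (2.5 - evi_v)
  swir_v <- nir_v * (1 - lswi_v) / (1 + lswi_v)

  tex <- .texture(grid)
  tair_v <- array(NA_real_, dim = dim(evi_v))
  sw_v <- tair_v
  sm_v <- tair_v
  st_v <- tair_v
  for (t in seq_len(nt)) {
    tair_v[t, , ] <- cfg$tair_range[1] +
      diff(cfg$tair_range) * .seasonal(doys[t], 150) + 0.5 * tex
    sw_v[t, , ] <- cfg$swdown_max * .seasonal(doys[t], 140) * (1 + 0.05 * tex)
    sm_v[t, , ] <- cfg$sm_range[1] +
      diff(cfg$sm_range) * .seasonal(doys[t], 250) + 0.01 * tex
    st_v[t, , ] <- cfg$st_range[1] +
      diff(cfg$st_range) * .seasonal(doys[t], 160) + 0.2 * tex
  }
  sw_v <- pmax(sw_v, 0)
  sm_v <- pmin(pmax(sm_v, 0.01), 0.6)

  # fine-grid SIF with the same class seasonality, then the coarse product as
  # s0 x (block mean) + noise
  gosif_v <- .class_seasonal_field(cfg$sif_amp * 0 + cfg$sif_base,
                                   cfg$sif_amp, cfg$peak_doy, classes_f,
                                   doys, fine_grid, tex_scale = 0.02)
  gosif_v <- pmax(gosif_v, 0)
  if (cfg$missing_frac > 0) {
    drop <- stats::runif(length(gosif_v)) < cfg$missing_frac
    gosif_v[drop] <- NA_real_
  }
  gosif <- mk(gosif_v, "mW m-2 sr-1 nm-1", "gosif", g = fine_grid)
  gos_coarse <- regrid_block_mean(gosif, grid)
  s0_m <- matrix(NA_real_, cfg$n_lat, cfg$n_lon)
  veg <- classes != "Other"
  s0_m[veg] <- cfg$s0[classes[veg]]
  tro_v <- array(rep(s0_m, each = nt), dim = dim(gos_coarse$values)) *
    gos_coarse$values
  if (cfg$sif_noise_sd > 0)
    tro_v <- tro_v + stats::rnorm(length(tro_v), sd = cfg$sif_noise_sd)
  troposif <- mk(tro_v, "mW m-2 sr-1 nm-1", "troposif")

  red <- mk(red_v, "1", "red")
  nir <- mk(nir_v, "1", "nir")
  blue <- mk(blue_v, "1", "blue")
  swir <- mk(swir_v, "1", "swir")
  evi <- compute_evi(red, nir, blue)
  lswi <- compute_lswi(nir, swir)
  t_air <- mk(tair_v, "degC", "t_air")
  swdown <- mk(sw_v, "umol m-2 s-1", "swdown")
  sm <- mk(sm_v, "m3 m-3", "sm")
  st <- mk(st_v, "K", "st")

  params <- vprm_param_table("tropical")
  limits <- temperature_limits()
  gpp <- gpp_vprm(evi, t_air, swdown, vegmap, params, limits, lswi = lswi)
  reco <- reco_vprm(t_air, vegmap, params, limits)

  # truth-based reference targets for the fitting operations
  eta_m <- matrix(0, cfg$n_lat, cfg$n_lon)
  eps_m <- eta_m
  eta_m[veg] <- cfg$eta0[classes[veg]]
  eps_m[veg] <- cfg$eps0[classes[veg]]
  gpp_sif_ref_v <- array(rep(eta_m, each = nt), dim = dim(gpp$values)) *
    gpp$values + array(rep(eps_m, each = nt), dim = dim(gpp$values))
  gpp_sif_ref_v[class_array(vegmap, nt) == "Other"] <- 0
  gpp_sif_ref <- mk(gpp_sif_ref_v, "umol CO2 m-2 s-1", "gpp_sif_ref")

  b <- .baseline_term(t_air, vegmap, params, limits)
  reco_ref_v <- cfg$tau0 * st_v + cfg$nu0 * sm_v + cfg$kappa0 * b
  if (cfg$reco_noise_sd > 0)
    reco_ref_v <- reco_ref_v +
      stats::rnorm(length(reco_ref_v), sd = cfg$reco_noise_sd)
  reco_ref_v[class_array(vegmap, nt) == "Other"] <- 0
  reco_ref <- mk(reco_ref_v, "umol CO2 m-2 s-1", "reco_ref")

  # pseudo eddy-covariance site: center of the deciduous strip if present
  site_cells <- which(classes == "DeciduousForest", arr.ind = TRUE)
  if (!nrow(site_cells))
    site_cells <- which(classes != "Other", arr.ind = TRUE)
  site_ij <- site_cells[ceiling(nrow(site_cells) / 2), ]
  site <- list(lat_idx = unname(site_ij[1]), lon_idx = unname(site_ij[2]),
               class = classes[site_ij[1], site_ij[2]])

  list(cfg = cfg, grid = grid, fine_grid = fine_grid, calendar = cal,
       vegmap = vegmap, vegmap_fine = vegmap_fine,
       red = red, nir = nir, blue = blue, swir = swir,
       evi = evi, lswi = lswi, t_air = t_air, swdown = swdown,
       sm = sm, st = st, gosif = gosif, troposif = troposif,
       gpp_vprm = gpp, reco_vprm = reco,
       gpp_sif_ref = gpp_sif_ref, reco_ref = reco_ref, site = site,
       truth = list(s0 = cfg$s0, eta0 = cfg$eta0, eps0 = cfg$eps0,
                    nu0 = cfg$nu0, tau0 = cfg$tau0, kappa0 = cfg$kappa0,
                    seed = cfg$seed))
}

#' Extract a single-cell time series from a field
#'
#' Convenience accessor for pseudo eddy-covariance site comparisons.
#'
#' @param field a \code{\link{gridded_field}}.
#' @param lat_idx,lon_idx cell indices (e.g. from a scene's \code{site}).
#' @return numeric vector, one value per time layer.
#' @export
site_series <- function(field, lat_idx, lon_idx) {
  stopifnot(inherits(field, "gridded_field"))
  field$values[, lat_idx, lon_idx]
}
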