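#' Enhanced Vegetation Index from surface reflectance
#'
#' Standard MODIS-style EVI,
#' \deqn{EVI = 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1),}
#' masked wherever any band is missing or the denominator is non-positive.
#'
#' @param red,nir,blue co-gridded reflectance fields in \[0, 1\].
#' @return a \code{\link{gridded_field}} named \code{"evi"} (dimensionless).
#' @export
compute_evi <- function(red, nir, blue) {
  check_cogridded(red, nir, blue)
  den <- nir$values + 6 * red$values - 7.5 * blue$values + 1
  evi <- 2.5 * (nir$values - red$values) / den
  evi[!is.na(den) & den <= 0] <- NA_real_
  field_like(red, evi, units = "1", name = "evi")
}

#' Land Surface Water Index from surface reflectance
#'
#' Normalized difference of near-infrared and shortwave-infrared
#' reflectance, \eqn{LSWI = (NIR - SWIR)/(NIR + SWIR)}, masked where the sum
#' is zero.
#'
#' @param nir,swir co-gridded reflectance fields in \[0, 1\].
#' @return a \code{\link{gridded_field}} named \code{"lswi"}, in \[-1, 1\].
#' @export
compute_lswi <- function(nir, swir) {
  check_cogridded(nir, swir)
  s <- nir$values + swir$values
  lswi <- (nir$values - swir$values) / s
  lswi[!is.na(s) & s == 0] <- NA_real_
  field_like(nir, lswi, units = "1", name = "lswi")
}

#' Temperature scalar of photosynthesis
#'
#' Dimensionless temperature response
#' \deqn{T_{scale} = \frac{(T - T_{min})(T - T_{max})}
#'       {(T - T_{min})(T - T_{max}) - (T - T_{opt})^2},}
#' equal to 1 at \code{t_opt} and set to 0 at or outside
#' \code{[t_min, t_max]} (photosynthesis is assumed absent beyond the limits;
#' ties at the limits resolve to 0).
#'
#' @param t_air air temperature in °C (numeric vector, matrix or array).
#' @param limits a \code{\link{temperature_limits}}.
#' @return values in \[0, 1\], same shape as \code{t_air}; \code{NA}
#'   propagates.
#' @export
#' @examples
#' t_scale(20)          # 1 at the optimum
#' t_scale(c(-5, 10, 50))
t_scale <- function(t_air, limits = temperature_limits()) {
  stopifnot(inherits(limits, "temperature_limits"))
  num <- (t_air - limits$t_min) * (t_air - limits$t_max)
  den <- num - (t_air - limits$t_opt)^2
  out <- num / den
  out[!is.na(den) & den == 0] <- 1  # only reachable at t_opt
  outside <- !is.na(t_air) & (t_air <= limits$t_min | t_air >= limits$t_max)
  out[outside] <- 0
  out
}

#' Phenology scalar of photosynthesis
#'
#' Leaf-age effect on light-use efficiency: \code{(1 + LSWI)/2} during
#' green-up, forced to 1 at the time of maximum greenness (full leaf
#' expansion) and always 1 for evergreen forest; 0 over \code{"Other"}
#' (water bodies and unclassified cells).
#'
#' @param lswi LSWI values in \[-1, 1\].
#' @param cls vegetation class label(s), recycled against \code{lswi}.
#' @param is_max_greenness logical flag(s): is this a maximum-greenness
#'   composite for the cell?
#' @return values in \[0, 1\], same shape as \code{lswi}.
#' @export
p_scale <- function(lswi, cls, is_max_greenness = FALSE) {
  bad <- setdiff(unique(cls), veg_classes())
  if (length(bad)) stop("unknown vegetation class label(s): ",
                        paste(bad, collapse = ", "))
  out <- (1 + lswi) / 2
  out[is_max_greenness] <- 1
  out[cls == "EvergreenForest"] <- 1
  out[cls == "Other"] <- 0
  attributes(out) <- attributes(lswi)
  out
}

#' Water-stress scalar of photosynthesis
#'
#' \eqn{W_{scale} = (1 + LSWI)/(1 + LSWI_{max})} where \eqn{LSWI_{max}} is
#' the per-cell maximum LSWI of the growing season (here: the calendar year,
#' see \code{\link{lswi_max_by_cell}}).
#'
#' @param lswi LSWI values in \[-1, 1\].
#' @param lswi_max per-cell annual maximum LSWI, recycled/broadcast against
#'   \code{lswi}; values of -1 yield a masked (NA) result.
#' @return non-negative values; 1 where \code{lswi == lswi_max}.
#' @export
w_scale <- function(lswi, lswi_max) {
  out <- (1 + lswi) / (1 + lswi_max)
  out[!is.na(lswi_max) & lswi_max <= -1] <- NA_real_
  out
}

#' Per-cell annual maximum LSWI
#'
#' @param lswi a multi-layer LSWI \code{\link{gridded_field}} (one calendar
#'   year of composites).
#' @return \code{(n_lat, n_lon)} matrix; cells with no non-missing composite
#'   are \code{NA}.
#' @export
lswi_max_by_cell <- function(lswi) {
  stopifnot(inherits(lswi, "gridded_field"))
  m <- apply(lswi$values, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else max(v)
  })
  m
}

#' Maximum-greenness composite mask
#'
#' Flags, per cell, the composites representing full leaf expansion: those
#' whose EVI reaches at least \code{frac} of the cell's annual EVI maximum.
#' Used to force the phenology scalar to 1 at peak greenness.
#'
#' @param evi an EVI \code{\link{gridded_field}} over one year of composites.
#' @param frac fraction of the annual maximum that counts as "maximum
#'   greenness" (default 0.99).
#' @return logical array shaped like \code{evi$values} (\code{FALSE} where
#'   EVI is missing).
#' @export
max_greenness_mask <- function(evi, frac = 0.99) {
  stopifnot(inherits(evi, "gridded_field"), frac > 0, frac <= 1)
  nt <- dim(evi$values)[1]
  mx <- apply(evi$values, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else max(v)
  })
  mx_arr <- array(rep(mx, each = nt), dim = dim(evi$values))
  out <- !is.na(evi$values) & !is.na(mx_arr) & evi$values >= frac * mx_arr
  out
}

# per-class parameter value broadcast over (time, lat, lon)
.class_param_array <- function(vegmap, ntime, lut) {
  vals <- lut[vegmap$classes]
  array(rep(vals, each = ntime), dim = c(ntime, dim(vegmap$classes)))
}

#' VPRM gross primary productivity
#'
#' Light-use-efficiency GPP,
#' \deqn{GPP = |\lambda| \, P_{scale} T_{scale} W_{scale} \,
#'       EVI \cdot SWdown \, / \, (1 + SWdown/SWdown_0),}
#' with EVI standing in for the fraction of radiation absorbed by the
#' photosynthetically active vegetation. \eqn{|\lambda|} is used so that both
#' packaged parameter sets (the European set prints uptake-negative
#' \eqn{\lambda}) yield a positive uptake magnitude. GPP is 0 over
#' \code{"Other"} cells.
#'
#' If \code{lswi} is supplied, the phenology and water-stress scalars are
#' computed from it (with maximum-greenness composites taken from the EVI
#' annual cycle); otherwise both are 1.
#'
#' @param evi EVI \code{\link{gridded_field}}.
#' @param t_air air temperature field, °C.
#' @param swdown downward shortwave radiation field, µmol m⁻² s⁻¹ (same
#'   units as \code{swdown0} in the parameter table).
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param params one parameter set from \code{\link{vprm_param_table}} (or
#'   any data.frame with columns \code{class}, \code{lambda},
#'   \code{swdown0}).
#' @param limits a \code{\link{temperature_limits}}.
#' @param lswi optional co-gridded LSWI field enabling the phenology and
#'   water-stress scalars.
#' @param greenness_frac passed to \code{\link{max_greenness_mask}}.
#' @return GPP \code{\link{gridded_field}} in µmol CO2 m⁻² s⁻¹, non-negative.
#' @export
gpp_vprm <- function(evi, t_air, swdown, vegmap, params,
                     limits = temperature_limits(), lswi = NULL,
                     greenness_frac = 0.99) {
  check_cogridded(evi, t_air, swdown)
  if (!same_grid(evi$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  nt <- dim(evi$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  lam <- abs(param_lookup(params, need, "lambda", "VPRM parameters"))
  sw0 <- param_lookup(params, need, "swdown0", "VPRM parameters")
  lam["Other"] <- 0
  sw0["Other"] <- 1  # unused; avoids 0/0 over Other
  lam_a <- .class_param_array(vegmap, nt, lam)
  sw0_a <- .class_param_array(vegmap, nt, sw0)
  tsc <- t_scale(t_air$values, limits)
  if (!is.null(lswi)) {
    check_cogridded(evi, lswi)
    cls_a <- class_array(vegmap, nt)
    psc <- p_scale(lswi$values, cls_a, max_greenness_mask(evi, greenness_frac))
    wsc <- w_scale(lswi$values,
                   array(rep(lswi_max_by_cell(lswi), each = nt),
                         dim = dim(lswi$values)))
  } else {
    psc <- 1
    wsc <- 1
  }
  gpp <- lam_a * psc * tsc * wsc * evi$values *
    swdown$values / (1 + swdown$values / sw0_a)
  gpp <- pmax(gpp, 0)
  gpp[class_array(vegmap, nt) == "Other"] <- 0
  field_like(evi, gpp, units = "umol CO2 m-2 s-1", name = "gpp_vprm")
}

#' VPRM ecosystem respiration
#'
#' Linear air-temperature respiration \eqn{R_{eco} = \alpha T_{air} + \beta}
#' per vegetation class, with \eqn{T_{air}} clamped from below at the
#' threshold temperature so winter respiration stays at its baseline. 0 over
#' \code{"Other"} cells.
#'
#' @param t_air air temperature field, °C.
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param params one parameter set from \code{\link{vprm_param_table}}
#'   (columns \code{class}, \code{alpha}, \code{beta}).
#' @param limits a \code{\link{temperature_limits}} (supplies
#'   \code{t_thresh}).
#' @return respiration \code{\link{gridded_field}} in µmol CO2 m⁻² s⁻¹.
#' @export
reco_vprm <- function(t_air, vegmap, params, limits = temperature_limits()) {
  stopifnot(inherits(t_air, "gridded_field"))
  if (!same_grid(t_air$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  nt <- dim(t_air$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  alpha <- param_lookup(params, need, "alpha", "VPRM parameters")
  beta <- param_lookup(params, need, "beta", "VPRM parameters")
  alpha["Other"] <- 0
  beta["Other"] <- 0
  a <- .class_param_array(vegmap, nt, alpha)
  b <- .class_param_array(vegmap, nt, beta)
  reco <- a * pmax(t_air$values, limits$t_thresh) + b
  reco[class_array(vegmap, nt) == "Other"] <- 0
  field_like(t_air, reco, units = "umol CO2 m-2 s-1", name = "reco_vprm")
}
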