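#' GPP from SIF by biome-specific linear conversion
#'
#' Converts a SIF field to GPP with the per-class linear relationship
#' \eqn{GPP = \gamma \cdot SIF + C}, floored at 0 (SIF noise can drive the
#' line negative; GPP is a magnitude). Cells of class \code{"Other"} are
#' masked.
#'
#' The coefficient table carries a \code{product} tag (\code{"gosif"} or
#' \code{"troposif"}); if \code{product} is supplied it must match the
#' table's tag, guarding against converting a TROPOSIF field with GOSIF-side
#' coefficients.
#'
#' @param sif SIF \code{\link{gridded_field}} (mW m⁻² sr⁻¹ nm⁻¹).
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param coeffs data.frame with columns \code{class}, \code{product},
#'   \code{gamma}, \code{c}; see \code{\link{sif_gpp_coeff_table}}.
#' @param product optional product tag of \code{sif} for the consistency
#'   check.
#' @return GPP \code{\link{gridded_field}} in µmol CO2 m⁻² s⁻¹.
#' @export
gpp_from_sif <- function(sif, vegmap, coeffs, product = NULL) {
  stopifnot(inherits(sif, "gridded_field"))
  if (!same_grid(sif$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  tag <- unique(coeffs$product)
  if (length(tag) != 1L)
    stop("coefficient table mixes products: ", paste(tag, collapse = ", "))
  if (!is.null(product) && !identical(tolower(product), tolower(tag)))
    stop("SIF product '", product, "' does not match coefficient product '",
         tag, "'")
  nt <- dim(sif$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  gam <- param_lookup(coeffs, need, "gamma", "SIF-GPP coefficients")
  cc <- param_lookup(coeffs, need, "c", "SIF-GPP coefficients")
  gam["Other"] <- NA_real_
  cc["Other"] <- NA_real_
  gpp <- .class_param_array(vegmap, nt, gam) * sif$values +
    .class_param_array(vegmap, nt, cc)
  gpp <- pmax(gpp, 0)
  field_like(sif, gpp, units = "umol CO2 m-2 s-1",
             name = paste0("gpp_", tolower(tag)))
}

#' Transfer SIF-to-GPP coefficients between products
#'
#' Given GOSIF-side conversion coefficients and the per-class cross-sensor
#' factors S, derives the TROPOSIF-side coefficients:
#' \eqn{\gamma_{TROPOSIF} = \gamma_{GOSIF}/S} and
#' \eqn{C_{TROPOSIF} = C_{GOSIF}/S}. Together with the scaling relation
#' \eqn{TROPOSIF = S \cdot GOSIF}, this makes the two conversion routes agree
#' exactly on proportional data.
#'
#' @param gosif_coeffs GOSIF-side coefficient table (columns \code{class},
#'   \code{product == "gosif"}, \code{gamma}, \code{c}).
#' @param scaling data.frame with columns \code{class} and \code{s}; every
#'   class in \code{gosif_coeffs} must be present with \code{s > 0}.
#' @return TROPOSIF-side coefficient table in the same layout.
#' @export
#' @examples
#' transfer_coeffs(sif_gpp_coeff_table("gosif"), sif_scaling_table())
transfer_coeffs <- function(gosif_coeffs, scaling) {
  if (!all(tolower(gosif_coeffs$product) == "gosif"))
    stop("gosif_coeffs must be GOSIF-side coefficients")
  s <- param_lookup(scaling, gosif_coeffs$class, "s", "SIF scaling factor")
  s <- s[gosif_coeffs$class]
  if (any(s <= 0)) stop("scaling factors must be positive")
  data.frame(class = gosif_coeffs$class,
             product = "troposif",
             gamma = gosif_coeffs$gamma / s,
             c = gosif_coeffs$c / s,
             row.names = NULL)
}
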