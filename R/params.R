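.extdata <- function(file) {
  path <- system.file("extdata", file, package = "vprmsif", mustWork = FALSE)
  if (!nzchar(path)) {
    # during load_all() / tests from a source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged table not found: ", file)
  path
}

#' Packaged VPRM parameter sets
#'
#' Per-class light-use-efficiency and respiration parameters
#' (\eqn{\lambda}, SWdown0, \eqn{\alpha}, \eqn{\beta}) for the two packaged
#' calibrations: \code{"tropical"} (Amazonian tropical biomes) and
#' \code{"european"} (European biomes, printed with the uptake-negative
#' \eqn{\lambda} sign convention). Units: \eqn{\lambda} in µmol CO2 m⁻² s⁻¹
#' per µmol SWdown m⁻² s⁻¹; SWdown0 in µmol m⁻² s⁻¹; \eqn{\alpha} in
#' µmol CO2 m⁻² s⁻¹ per °C; \eqn{\beta} in µmol CO2 m⁻² s⁻¹.
#'
#' @param set \code{"tropical"}, \code{"european"}, or \code{"all"} for both.
#' @return data.frame with columns \code{class}, \code{set}, \code{lambda},
#'   \code{swdown0}, \code{alpha}, \code{beta}.
#' @export
#' @examples
#' vprm_param_table("tropical")
vprm_param_table <- function(set = c("tropical", "european", "all")) {
  set <- match.arg(set)
  tab <- utils::read.csv(.extdata("vprm_params.csv"), stringsAsFactors = FALSE)
  if (set != "all") tab <- tab[tab$set == set, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Packaged cross-sensor SIF scaling factors
#'
#' Per-class multiplicative factors S mapping the OCO-2-derived SIF product
#' (GOSIF) onto the TROPOMI product (TROPOSIF), with the squared correlations
#' of the matched 8-day pairs reported alongside. These are reference
#' constants derived from the real satellite archive; use
#' \code{\link{fit_sif_scaling}} to estimate factors from data.
#'
#' @return data.frame with columns \code{class}, \code{s} and the reported
#'   squared correlations.
#' @export
sif_scaling_table <- function() {
  utils::read.csv(.extdata("sif_scaling.csv"), stringsAsFactors = FALSE)
}

#' Packaged biome-specific SIF-to-GPP conversion coefficients
#'
#' Linear coefficients \eqn{GPP = \gamma \cdot SIF + C} per vegetation class
#' and SIF product. \eqn{\gamma} in (µmol m⁻² s⁻¹)/(mW m⁻² sr⁻¹ nm⁻¹),
#' \eqn{C} in µmol m⁻² s⁻¹. The TROPOSIF-side values equal the GOSIF-side
#' values divided by the cross-sensor factor (see
#' \code{\link{transfer_coeffs}}).
#'
#' @param product \code{"gosif"}, \code{"troposif"}, or \code{"all"}.
#' @return data.frame with columns \code{class}, \code{product},
#'   \code{gamma}, \code{c}.
#' @export
sif_gpp_coeff_table <- function(product = c("gosif", "troposif", "all")) {
  product <- match.arg(product)
  tab <- utils::read.csv(.extdata("sif_gpp_coeffs.csv"), stringsAsFactors = FALSE)
  if (product != "all") tab <- tab[tab$product == product, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Packaged GPP refinement scaling factors
#'
#' Reference per-class refinement factors \eqn{\eta} mapping standard VPRM GPP
#' onto SIF-based GPP, one set per SIF product. Reference constants from the
#' real-data calibration; use \code{\link{fit_eta}} to estimate from data.
#'
#' @return data.frame with columns \code{class}, \code{product}, \code{eta}.
#' @export
gpp_refinement_table <- function() {
  utils::read.csv(.extdata("gpp_refinement.csv"), stringsAsFactors = FALSE)
}

#' Packaged refined-respiration parameters
#'
#' Reference per-class coefficients (\eqn{\nu} on soil moisture, \eqn{\tau} on
#' soil temperature, \eqn{\kappa} on the air-temperature baseline) for the
#' three refinement experiments, adjusted against FLUXNET-upscaled fluxes.
#' Units: \eqn{\nu} in µmol CO2 m⁻² s⁻¹ per m³ m⁻³; \eqn{\tau} in
#' µmol CO2 m⁻² s⁻¹ K⁻¹; \eqn{\kappa} dimensionless. Reference constants;
#' use \code{\link{fit_reco_params}} to estimate from data.
#'
#' @param experiment \code{"SM"}, \code{"ST"}, \code{"SMST"}, or \code{"all"}.
#' @return data.frame with columns \code{class}, \code{experiment},
#'   \code{nu}, \code{tau}, \code{kappa}, \code{reference_source}.
#' @export
reco_refinement_table <- function(experiment = c("all", "SM", "ST", "SMST")) {
  experiment <- match.arg(experiment)
  tab <- utils::read.csv(.extdata("reco_refinement.csv"), stringsAsFactors = FALSE)
  if (experiment != "all")
    tab <- tab[tab$experiment == experiment, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' All packaged reference tables
#'
#' Convenience bundle of every packaged per-class constant table, handy for
#' worked examples and desk checks.
#'
#' @return named list of data.frames: \code{vprm_params},
#'   \code{sif_scaling}, \code{sif_gpp_coeffs}, \code{gpp_refinement},
#'   \code{reco_refinement}.
#' @export
reference_tables <- function() {
  list(vprm_params = vprm_param_table("all"),
       sif_scaling = sif_scaling_table(),
       sif_gpp_coeffs = sif_gpp_coeff_table("all"),
       gpp_refinement = gpp_refinement_table(),
       reco_refinement = reco_refinement_table("all"))
}

#' Photosynthesis temperature limits
#'
#' Limits for the temperature scalar: photosynthesis is active only between
#' \code{t_min} and \code{t_max} and peaks at \code{t_opt}. \code{t_thresh}
#' is the lower clamp applied to air temperature in the respiration baseline
#' so that winter respiration does not go negative. Defaults are the values
#' used for all vegetation classes in the packaged configuration
#' (0 / 20 / 45 °C, threshold 0 °C).
#'
#' @param t_opt,t_max,t_min optimal / maximum / minimum temperatures, °C;
#'   must satisfy \code{t_min < t_opt < t_max}.
#' @param t_thresh respiration clamp temperature, °C.
#' @return an object of class \code{temperature_limits}.
#' @export
temperature_limits <- function(t_opt = 20, t_max = 45, t_min = 0,
                               t_thresh = 0) {
  stopifnot(is.numeric(t_opt), is.numeric(t_max), is.numeric(t_min))
  if (!(t_min < t_opt && t_opt < t_max))
    stop("temperature limits must satisfy t_min < t_opt < t_max (got ",
         t_min, ", ", t_opt, ", ", t_max, ")")
  structure(list(t_opt = t_opt, t_max = t_max, t_min = t_min,
                 t_thresh = t_thresh),
            class = "temperature_limits")
}

# lookup of one per-class parameter column as a named vector; errors name
# the missing class
param_lookup <- function(tab, classes_needed, col, what = "parameter") {
  missing_cls <- setdiff(classes_needed, tab$class)
  if (length(missing_cls))
    stop("no ", what, " for vegetation class(es): ",
         paste(missing_cls, collapse = ", "))
  stats::setNames(tab[[col]], tab$class)
}
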