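#' Fit per-biome GPP refinement scalars
#'
#' Calibrates, per vegetation class, the affine refinement
#' \eqn{GPP_{refined} = \eta \, GPP_{VPRM} + \epsilon} that maps standard
#' VPRM GPP onto SIF-based GPP over matched non-missing samples.
#'
#' Two estimators for \eqn{\eta} are provided. \code{"literal"} (default)
#' computes the ratio
#' \deqn{\eta = \sum GPP_{SIF} \cdot GPP_{VPRM} \, / \, \sum GPP_{VPRM},}
#' i.e. a VPRM-GPP-weighted mean of the SIF-based GPP. \code{"slope"}
#' computes the least-squares slope on mean-centered pairs (the conventional
#' dimensionless regression slope), which recovers \eqn{a} and \eqn{b}
#' exactly on noiseless data with \eqn{GPP_{SIF} = a\,GPP_{VPRM} + b}. In
#' both cases \eqn{\epsilon} is the mean residual
#' \eqn{\overline{GPP_{SIF} - \eta\,GPP_{VPRM}}}, so the refined field's
#' class mean equals the SIF-based class mean on the fitting sample.
#'
#' @param gpp_sif,gpp_vprm co-gridded GPP fields (µmol CO2 m⁻² s⁻¹).
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param estimator \code{"literal"} or \code{"slope"}.
#' @return data.frame with one row per fitted class: \code{class},
#'   \code{eta}, \code{epsilon}, \code{n}. Classes with a zero denominator
#'   are omitted with a warning.
#' @export
fit_eta <- function(gpp_sif, gpp_vprm, vegmap,
                    estimator = c("literal", "slope")) {
  estimator <- match.arg(estimator)
  pairs <- .class_pairs(gpp_vprm, gpp_sif, vegmap)
  pairs <- pairs[names(pairs) != "Other"]
  rows <- lapply(names(pairs), function(cl) {
    v <- pairs[[cl]]$x   # VPRM GPP
    s <- pairs[[cl]]$y   # SIF-based GPP
    if (!length(v)) return(NULL)
    eta <- if (estimator == "literal") {
      if (sum(v) == 0) {
        warning("class ", cl, " omitted: zero VPRM GPP sum")
        return(NULL)
      }
      sum(s * v) / sum(v)
    } else {
      ssv <- sum((v - mean(v))^2)
      if (ssv == 0) {
        warning("class ", cl, " omitted: VPRM GPP is constant")
        return(NULL)
      }
      sum((v - mean(v)) * (s - mean(s))) / ssv
    }
    data.frame(class = cl, eta = eta,
               epsilon = mean(s - eta * v), n = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no class had usable matched pairs")
  rownames(out) <- NULL
  out
}

#' Apply per-biome GPP refinement
#'
#' Evaluates \eqn{\eta \, GPP_{VPRM} + \epsilon} per cell with its class's
#' scalars, floored at 0. Cells of class \code{"Other"} stay 0; a mapped
#' class missing from \code{scalars} is an error.
#'
#' @param gpp_vprm GPP \code{\link{gridded_field}}.
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param scalars data.frame with columns \code{class}, \code{eta},
#'   \code{epsilon} (e.g. from \code{\link{fit_eta}}; \code{epsilon} defaults
#'   to 0 if absent, so \code{\link{gpp_refinement_table}} works directly).
#' @return refined GPP \code{\link{gridded_field}}.
#' @export
apply_refinement <- function(gpp_vprm, vegmap, scalars) {
  stopifnot(inherits(gpp_vprm, "gridded_field"))
  if (!same_grid(gpp_vprm$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  if (is.null(scalars$epsilon)) scalars$epsilon <- 0
  nt <- dim(gpp_vprm$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  eta <- param_lookup(scalars, need, "eta", "refinement scalars")
  eps <- param_lookup(scalars, need, "epsilon", "refinement scalars")
  eta["Other"] <- 0
  eps["Other"] <- 0
  out <- .class_param_array(vegmap, nt, eta) * gpp_vprm$values +
    .class_param_array(vegmap, nt, eps)
  out <- pmax(out, 0)
  out[class_array(vegmap, nt) == "Other"] <- 0
  field_like(gpp_vprm, out, name = "gpp_vprm_sif")
}
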