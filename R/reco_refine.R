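# canonical experiment labels and the predictors each one uses
.reco_experiments <- list(SM = c("sm"), ST = c("st"), SMST = c("st", "sm"))

.match_experiment <- function(experiment) {
  ex <- toupper(experiment)
  if (!ex %in% names(.reco_experiments))
    stop("unknown experiment '", experiment, "'; use SM, ST or SMST")
  ex
}

# the air-temperature baseline term B = alpha * max(Tair, Ttshld) + beta,
# as a (time, lat, lon) array; 0 over Other
.baseline_term <- function(t_air, vegmap, params, limits) {
  nt <- dim(t_air$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  alpha <- param_lookup(params, need, "alpha", "VPRM parameters")
  beta <- param_lookup(params, need, "beta", "VPRM parameters")
  alpha["Other"] <- 0
  beta["Other"] <- 0
  b <- .class_param_array(vegmap, nt, alpha) *
    pmax(t_air$values, limits$t_thresh) +
    .class_param_array(vegmap, nt, beta)
  b[class_array(vegmap, nt) == "Other"] <- 0
  b
}

#' Fit refined-respiration parameters against reference fluxes
#'
#' Calibrates, per vegetation class, the refined respiration model of the
#' chosen experiment against an observation-based reference flux field
#' (FLUXNET- or FLUXCOM-like):
#' \itemize{
#'   \item SM: \eqn{R_{eco} = \nu \, SM + \kappa B}
#'   \item ST: \eqn{R_{eco} = \tau \, ST + \kappa B}
#'   \item SMST: \eqn{R_{eco} = \tau \, ST + \nu \, SM + \kappa B}
#' }
#' where \eqn{B = \alpha \max(T_{air}, T_{thresh}) + \beta} is the standard
#' air-temperature respiration baseline. Coefficients are estimated jointly
#' by ordinary least squares with no free intercept (\eqn{\kappa} absorbs the
#' baseline's intercept \eqn{\beta}).
#'
#' @param experiment \code{"SM"}, \code{"ST"} or \code{"SMST"}
#'   (case-insensitive).
#' @param sm volumetric soil-moisture field, m³ m⁻³ (may be \code{NULL} for
#'   the ST experiment).
#' @param st soil-temperature field, K (may be \code{NULL} for the SM
#'   experiment).
#' @param t_air air-temperature field, °C.
#' @param reco_ref reference respiration field, µmol CO2 m⁻² s⁻¹.
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param params VPRM parameter set supplying \eqn{\alpha}, \eqn{\beta} (see
#'   \code{\link{vprm_param_table}}).
#' @param limits a \code{\link{temperature_limits}}.
#' @return data.frame with one row per fitted class: \code{class},
#'   \code{experiment}, \code{nu}, \code{tau}, \code{kappa} (\code{NA} for
#'   predictors the experiment does not use) and \code{n}. Classes with too
#'   few samples or a rank-deficient (collinear) design are omitted with a
#'   warning naming the collinear predictors.
#' @export
fit_reco_params <- function(experiment, sm = NULL, st = NULL, t_air,
                            reco_ref, vegmap, params,
                            limits = temperature_limits()) {
  ex <- .match_experiment(experiment)
  preds <- .reco_experiments[[ex]]
  if ("sm" %in% preds && is.null(sm)) stop("experiment ", ex, " needs sm")
  if ("st" %in% preds && is.null(st)) stop("experiment ", ex, " needs st")
  check_cogridded(t_air, reco_ref)
  if (!is.null(sm) && "sm" %in% preds) check_cogridded(t_air, sm)
  if (!is.null(st) && "st" %in% preds) check_cogridded(t_air, st)
  if (!same_grid(t_air$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")

  nt <- dim(t_air$values)[1]
  cls <- class_array(vegmap, nt)
  b <- .baseline_term(t_air, vegmap, params, limits)
  cols <- list()
  if ("st" %in% preds) cols$st <- st$values
  if ("sm" %in% preds) cols$sm <- sm$values
  cols$baseline <- b

  classes <- setdiff(sort(unique(as.vector(vegmap$classes))), "Other")
  rows <- lapply(classes, function(cl) {
    in_cls <- cls == cl
    y <- reco_ref$values[in_cls]
    X <- vapply(cols, function(v) v[in_cls], numeric(sum(in_cls)))
    keep <- stats::complete.cases(X) & !is.na(y)
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
    if (nrow(X) < ncol(X)) {
      warning("class ", cl, " omitted: only ", nrow(X),
              " samples for ", ncol(X), " coefficients")
      return(NULL)
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      warning("class ", cl, " omitted: rank-deficient design (collinear: ",
              paste(dropped, collapse = ", "), ")")
      return(NULL)
    }
    beta_hat <- qr.coef(qrX, y)
    data.frame(class = cl, experiment = ex,
               nu = if ("sm" %in% preds) beta_hat[["sm"]] else NA_real_,
               tau = if ("st" %in% preds) beta_hat[["st"]] else NA_real_,
               kappa = beta_hat[["baseline"]],
               n = length(y))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no class could be fitted")
  rownames(out) <- NULL
  out
}

#' Predict refined ecosystem respiration
#'
#' Evaluates the refined respiration model of the chosen experiment with
#' per-class coefficients, floored at 0; cells of class \code{"Other"} stay
#' 0.
#'
#' @inheritParams fit_reco_params
#' @param refine_params data.frame from \code{\link{fit_reco_params}} or
#'   \code{\link{reco_refinement_table}}; its \code{experiment} column must
#'   match \code{experiment}.
#' @param vprm_params VPRM parameter set supplying \eqn{\alpha}, \eqn{\beta}.
#' @return refined respiration \code{\link{gridded_field}} in
#'   µmol CO2 m⁻² s⁻¹.
#' @export
predict_reco <- function(experiment, refine_params, sm = NULL, st = NULL,
                         t_air, vegmap, vprm_params,
                         limits = temperature_limits()) {
  ex <- .match_experiment(experiment)
  preds <- .reco_experiments[[ex]]
  tab <- refine_params
  if (!is.null(tab$experiment)) {
    tab <- tab[toupper(tab$experiment) == ex, , drop = FALSE]
    if (!nrow(tab))
      stop("refine_params carries no rows for experiment ", ex)
  }
  if ("sm" %in% preds && is.null(sm)) stop("experiment ", ex, " needs sm")
  if ("st" %in% preds && is.null(st)) stop("experiment ", ex, " needs st")
  stopifnot(inherits(t_air, "gridded_field"))
  if (!same_grid(t_air$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")

  nt <- dim(t_air$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  b <- .baseline_term(t_air, vegmap, vprm_params, limits)
  kap <- param_lookup(tab, need, "kappa", "respiration refinement")
  kap["Other"] <- 0
  out <- .class_param_array(vegmap, nt, kap) * b
  if ("st" %in% preds) {
    check_cogridded(t_air, st)
    tau <- param_lookup(tab, need, "tau", "respiration refinement")
    if (anyNA(tau)) stop("tau missing for experiment ", ex)
    tau["Other"] <- 0
    out <- out + .class_param_array(vegmap, nt, tau) * st$values
  }
  if ("sm" %in% preds) {
    check_cogridded(t_air, sm)
    nu <- param_lookup(tab, need, "nu", "respiration refinement")
    if (anyNA(nu)) stop("nu missing for experiment ", ex)
    nu["Other"] <- 0
    out <- out + .class_param_array(vegmap, nt, nu) * sm$values
  }
  out <- pmax(out, 0)
  out[class_array(vegmap, nt) == "Other"] <- 0
  field_like(t_air, out, units = "umol CO2 m-2 s-1",
             name = paste0("reco_vprm_", tolower(ex)))
}
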