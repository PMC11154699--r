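#' Model-reference comparison metrics
#'
#' Squared Pearson correlation (R²), root-mean-square error and mean bias
#' error over matched non-missing pairs. The bias sign convention is model
#' minus reference, so a model that under-predicts has negative MBE. These
#' satisfy the identity \eqn{RMSE^2 = MBE^2 + Var(model - reference)} (with
#' the population variance).
#'
#' @param model,reference numeric vectors or \code{\link{gridded_field}}s of
#'   equal shape; at least 2 matched non-missing pairs are required.
#' @return a one-row data.frame with \code{r2} (\code{NA} when either series
#'   has zero variance), \code{rmse}, \code{mbe} and \code{n}.
#' @export
#' @examples
#' flux_metrics(c(1, 3, 5), c(2, 2, 6))
flux_metrics <- function(model, reference) {
  m <- if (inherits(model, "gridded_field")) as.vector(model$values) else as.numeric(model)
  o <- if (inherits(reference, "gridded_field")) as.vector(reference$values) else as.numeric(reference)
  if (length(m) != length(o))
    stop("model and reference have different lengths")
  ok <- !is.na(m) & !is.na(o)
  m <- m[ok]
  o <- o[ok]
  if (length(m) < 2L) stop("need at least 2 matched non-missing pairs")
  d <- m - o
  r2 <- if (stats::sd(m) == 0 || stats::sd(o) == 0) NA_real_
        else stats::cor(m, o)^2
  data.frame(r2 = r2, rmse = sqrt(mean(d^2)), mbe = mean(d), n = length(m))
}

#' Metric table for several model variants
#'
#' Compares each model in a named list against the same reference and stacks
#' the metrics into one table (the layout used to report refined-model
#' validation: one row per variant with R², RMSE and MBE).
#'
#' @param models named list of numeric vectors or
#'   \code{\link{gridded_field}}s.
#' @param reference the common reference series/field.
#' @return data.frame with columns \code{variant}, \code{r2}, \code{rmse},
#'   \code{mbe}, \code{n}.
#' @export
metrics_table <- function(models, reference) {
  stopifnot(is.list(models), length(names(models)) == length(models))
  out <- do.call(rbind, lapply(names(models), function(nm) {
    cbind(variant = nm, flux_metrics(models[[nm]], reference))
  }))
  rownames(out) <- NULL
  out
}

#' Calendar-month means of a composite series
#'
#' Averages 8-day composite values into calendar months. A composite that
#' straddles a month boundary is apportioned to both months in proportion to
#' the number of its days falling in each, so the monthly mean is a
#' day-weighted mean of the overlapping composites. Months with no
#' contributing data are returned as \code{NA}.
#'
#' @param values numeric composite values (one per period).
#' @param starts \code{Date} vector of composite start dates.
#' @param ends optional \code{Date} vector of inclusive composite end dates;
#'   defaults to \code{starts + 7} truncated at each year's end (the 8-day
#'   composite convention).
#' @return named numeric vector of monthly means, names \code{"YYYY-MM"},
#'   covering every month touched by the composites.
#' @export
#' @examples
#' cal <- composite_calendar(2019)
#' monthly_means(rep(2, 46), cal$starts)
monthly_means <- function(values, starts, ends = NULL) {
  starts <- as.Date(starts)
  if (length(values) != length(starts))
    stop("values and starts differ in length")
  if (is.null(ends)) {
    yr_end <- as.Date(sprintf("%s-12-31", format(starts, "%Y")))
    ends <- pmin(starts + 7L, yr_end)
  } else {
    ends <- as.Date(ends)
  }
  if (any(ends < starts)) stop("composite ends before it starts")
  months <- sort(unique(format(c(starts, ends), "%Y-%m")))
  out <- stats::setNames(rep(NA_real_, length(months)), months)
  for (mo in months) {
    m_first <- as.Date(paste0(mo, "-01"))
    m_last <- seq(m_first, by = "1 month", length.out = 2)[2] - 1L
    w <- as.numeric(pmin(ends, m_last) - pmax(starts, m_first) + 1L)
    w <- pmax(w, 0)
    use <- w > 0 & !is.na(values)
    if (any(use)) out[mo] <- sum(w[use] * values[use]) / sum(w[use])
  }
  out
}
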