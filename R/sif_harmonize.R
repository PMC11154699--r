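# matched per-class (x, y) pairs across all (time, lat, lon) samples
.class_pairs <- function(x, y, vegmap) {
  check_cogridded(x, y)
  if (!same_grid(x$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  nt <- dim(x$values)[1]
  cls <- class_array(vegmap, nt)
  ok <- !is.na(x$values) & !is.na(y$values)
  split(data.frame(x = x$values[ok], y = y$values[ok]), cls[ok])
}

#' Fit per-biome cross-sensor SIF scaling factors
#'
#' Estimates, for each vegetation class, the multiplicative factor S that
#' maps the coarse-gridded OCO-2-derived product (GOSIF) onto the TROPOMI
#' product (TROPOSIF): \eqn{TROPOSIF = S \cdot GOSIF}. The default estimator
#' is the ratio of per-class sums over matched 8-day pairs, which makes the
#' per-class sums of the scaled product match exactly; a least-squares
#' slope-through-origin variant is available.
#'
#' @param troposif,gosif co-gridded 8-day SIF fields (same grid and
#'   composite times); pairs with either side missing are dropped.
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param estimator \code{"ratio"} (sum of TROPOSIF / sum of GOSIF) or
#'   \code{"slope0"} (least-squares slope through the origin).
#' @param min_pairs classes with fewer matched pairs are omitted.
#' @return data.frame with one row per fitted class: \code{class}, \code{s},
#'   \code{r2} (squared Pearson correlation of the pairs; \code{NA} if either
#'   side is constant) and \code{n}. Classes with a zero GOSIF sum are
#'   omitted with a warning.
#' @export
fit_sif_scaling <- function(troposif, gosif, vegmap,
                            estimator = c("ratio", "slope0"),
                            min_pairs = 2L) {
  estimator <- match.arg(estimator)
  pairs <- .class_pairs(gosif, troposif, vegmap)
  pairs <- pairs[names(pairs) != "Other"]
  rows <- lapply(names(pairs), function(cl) {
    g <- pairs[[cl]]$x
    t <- pairs[[cl]]$y
    if (length(g) < min_pairs) return(NULL)
    denom <- if (estimator == "ratio") sum(g) else sum(g^2)
    if (denom == 0) {
      warning("class ", cl, " omitted: zero GOSIF sum over matched pairs")
      return(NULL)
    }
    s <- if (estimator == "ratio") sum(t) / denom else sum(t * g) / denom
    r2 <- if (stats::sd(g) == 0 || stats::sd(t) == 0) NA_real_
          else stats::cor(g, t)^2
    data.frame(class = cl, s = s, r2 = r2, n = length(g))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no class had enough matched pairs to fit")
  rownames(out) <- NULL
  out
}

#' Apply cross-sensor SIF scaling
#'
#' Multiplies each cell of a GOSIF-like field by its vegetation class's
#' scaling factor, putting it on the TROPOSIF radiometric scale. Cells of
#' class \code{"Other"} are masked (no factor is defined for them); a mapped
#' class missing from \code{scaling} is an error.
#'
#' @param gosif SIF \code{\link{gridded_field}}.
#' @param vegmap a \code{\link{veg_map}} on the same grid.
#' @param scaling data.frame with columns \code{class} and \code{s}, e.g.
#'   from \code{\link{fit_sif_scaling}} or \code{\link{sif_scaling_table}}.
#' @return the scaled \code{\link{gridded_field}}.
#' @export
apply_sif_scaling <- function(gosif, vegmap, scaling) {
  stopifnot(inherits(gosif, "gridded_field"))
  if (!same_grid(gosif$grid, vegmap$grid))
    stop("vegetation map is not on the field grid")
  nt <- dim(gosif$values)[1]
  need <- setdiff(unique(as.vector(vegmap$classes)), "Other")
  s <- param_lookup(scaling, need, "s", "SIF scaling factor")
  s["Other"] <- NA_real_
  out <- .class_param_array(vegmap, nt, s) * gosif$values
  field_like(gosif, out, name = paste0(gosif$name, "_scaled"))
}
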