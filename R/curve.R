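# The dynamic control function (DCF): population attrition-index-by-age
# statistics, min-max normalised to the unit square, are fitted with a cubic
# polynomial u(t) that converts a linear morph parameter grid into a
# nonlinear, age-realistic wear schedule.

#' Average attrition index of the lower first molar by age
#'
#' The reference population table used for the default nonlinear schedule:
#' mean clinical attrition index (0-4 ordinal scale) of the lower first molar
#' at the midpoints of eight age groups, anchored at eruption (index 0) and
#' at the life-expectancy endpoint (index 4).
#'
#' @return data frame with columns `age` (years) and `index`.
#' @export
attrition_table_lower_molar <- function() {
  data.frame(age = c(8, 23, 30, 40, 50, 60, 66, 78),
             index = c(0, 0.88, 1.23, 1.43, 1.74, 1.99, 2.11, 4))
}

#' Construct an attrition series
#'
#' @param ages strictly increasing ages (years).
#' @param indices attrition index values (0-4 scale).
#' @return a list of class `AttritionSeries`.
#' @export
attrition_series <- function(ages, indices) {
  ages <- as.numeric(ages)
  indices <- as.numeric(indices)
  if (length(ages) != length(indices))
    stop("ages and indices must have equal length")
  if (length(ages) < 4) stop("an attrition series needs at least 4 points")
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing")
  structure(list(ages = ages, indices = indices), class = "AttritionSeries")
}

#' Min-max normalisation of an attrition series
#'
#' Each column is mapped by \eqn{(v - \min v) / (\max v - \min v)}, so the
#' first age maps to X = 0, the last to X = 1, and likewise for the index
#' column.
#'
#' @param series an `AttritionSeries` (or data frame with columns
#'   `age`/`index`).
#' @return a list of class `NormalizedSeries` with fields `X`, `Y` and the
#'   normalisation bounds.
#' @export
normalize_minmax <- function(series) {
  if (is.data.frame(series))
    series <- attrition_series(series$age, series$index)
  x <- series$ages
  y <- series$indices
  if (max(x) == min(x) || max(y) == min(y))
    stop("constant column cannot be min-max normalised")
  structure(list(X = (x - min(x)) / (max(x) - min(x)),
                 Y = (y - min(y)) / (max(y) - min(y)),
                 age_range = range(x), index_range = range(y)),
            class = "NormalizedSeries")
}

#' Fit the dynamic control function
#'
#' Ordinary least-squares polynomial fit of the normalised attrition index Y
#' on normalised age X (cubic by default).
#'
#' @param series a `NormalizedSeries`, or anything [normalize_minmax()]
#'   accepts (normalised first).
#' @param degree polynomial degree (default 3; needs `degree + 1` points).
#' @param clamp clamp evaluations of the fitted polynomial into `[0, 1]`
#'   (default), since a least-squares cubic need not pass exactly through
#'   the endpoints.
#' @return an object of class `DynamicControlFunction`: `coefficients`
#'   (highest power first), `clamp`, `residuals` and the input series.
#' @export
fit_dcf <- function(series, degree = 3L, clamp = TRUE) {
  if (!inherits(series, "NormalizedSeries")) series <- normalize_minmax(series)
  degree <- as.integer(degree)
  n <- length(series$X)
  if (n < degree + 1L)
    stop("need at least ", degree + 1L, " points for a degree-", degree,
         " fit")
  if (anyDuplicated(series$X))
    stop("duplicate X values make the design ill-conditioned")
  fit <- lm(series$Y ~ poly(series$X, degree, raw = TRUE))
  cf <- rev(unname(coef(fit)))  # highest power first
  structure(list(coefficients = cf, degree = degree, clamp = clamp,
                 residuals = unname(stats::residuals(fit)),
                 series = series),
            class = "DynamicControlFunction")
}

#' @export
print.DynamicControlFunction <- function(x, ...) {
  terms <- paste0(signif(x$coefficients, 4), "*t^",
                  seq(x$degree, 0))
  cat("DynamicControlFunction: u(t) =", paste(terms, collapse = " + "), "\n")
  cat("  clamped to [0,1]:", x$clamp,
      " RMS residual:", signif(sqrt(mean(x$residuals^2)), 3), "\n")
  invisible(x)
}

#' @export
coef.DynamicControlFunction <- function(object, ...) object$coefficients

#' Evaluate the dynamic control function
#'
#' Horner evaluation of the fitted polynomial; values are clamped into
#' `[0, 1]` when the DCF's clamp flag is set (the fitted cubic may slightly
#' undershoot 0 at t = 0 and undershoot 1 at t = 1).
#'
#' @param dcf a `DynamicControlFunction`.
#' @param t evaluation points in `[0, 1]`.
#' @param clamp override the DCF's clamp flag.
#' @return numeric vector u(t).
#' @export
evaluate_dcf <- function(dcf, t, clamp = dcf$clamp) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  u <- rep(0, length(t))
  for (c_k in dcf$coefficients) u <- u * t + c_k
  if (clamp) u <- pmin(pmax(u, 0), 1)
  u
}

#' @export
predict.DynamicControlFunction <- function(object, t = seq(0, 1, 0.01), ...) {
  evaluate_dcf(object, t)
}

#' Nonlinear frame schedule from a DCF
#'
#' Samples t uniformly on `[0, 1]` and evaluates the DCF; the resulting u
#' values are made non-decreasing by a cumulative maximum (a message is
#' logged if any adjustment occurs — the reference cubic is already monotone
#' on the unit interval, but user-supplied tables need not be).
#'
#' @param dcf a `DynamicControlFunction`.
#' @param n_frames number of frames (>= 2).
#' @return numeric vector of `n_frames` u values.
#' @export
nonlinear_schedule <- function(dcf, n_frames) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("a schedule needs at least 2 frames")
  t <- seq(0, 1, length.out = n_frames)
  u <- evaluate_dcf(dcf, t)
  mono <- cummax(u)
  if (any(mono != u))
    message("schedule monotonized by cumulative max (",
            sum(mono != u), " values adjusted)")
  mono
}
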