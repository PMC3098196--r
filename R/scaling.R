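#' Logarithmic binning along x
#'
#' Bins (x, y) pairs into geometric bins along the x axis and reports, per
#' non-empty bin, the within-bin geometric mean of x (the bin abscissa),
#' the arithmetic mean of y, its standard deviation and the point count.
#' Zeros in y are retained -- bin means can legitimately fall below 1, for
#' example when binning byproduct counts of pathways most of which have
#' none -- but x must be strictly positive.
#'
#' @param x,y Numeric vectors of equal length; `x > 0`, `y >= 0`.
#' @param bins_per_decade Number of bins per factor of 10 (default 10).
#' @return An object of class `binned_series`: data frame with columns
#'   `center`, `mean_y`, `sd_y`, `n`.
#' @export
log_bin <- function(x, y, bins_per_decade = 10) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive and finite")
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be non-negative")
  lx <- log10(x)
  w <- 1 / bins_per_decade
  edges <- seq(floor(min(lx) / w) * w, ceiling(max(lx) / w) * w + 1e-12,
               by = w)
  bi <- findInterval(lx, edges, rightmost.closed = TRUE)
  f <- factor(bi, levels = sort(unique(bi)))
  out <- data.frame(
    center = 10^tapply(lx, f, mean),           # within-bin geometric mean
    mean_y = as.numeric(tapply(y, f, mean)),
    sd_y = as.numeric(tapply(y, f, stats::sd)),
    n = as.integer(tapply(y, f, length))
  )
  rownames(out) <- NULL
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Power-law fit to a binned series
#'
#' Least-squares fit of `log10(mean_y)` against `log10(center)` over the
#' non-empty bins with positive mean. By default bins are weighted by their
#' point counts, the appropriate weighting for bin means whose standard
#' errors scale as \eqn{1/\sqrt{n}}; `weighting = "none"` gives each bin
#' equal weight.
#'
#' @param binned A `binned_series` from [log_bin()], or a data frame with
#'   columns `center`, `mean_y`, `n`.
#' @param weighting `"count"` (default) or `"none"`.
#' @return An object of class `power_law_fit`: list with `alpha` (the
#'   exponent), `alpha_se`, `prefactor`, `n_bins`, `n_points`.
#' @examples
#' b <- log_bin(10^seq(0, 3, 0.1), 3 * (10^seq(0, 3, 0.1))^2)
#' fit_power_law(b)$alpha  # 2
#' @export
fit_power_law <- function(binned, weighting = c("count", "none")) {
  weighting <- match.arg(weighting)
  b <- binned[binned$mean_y > 0, , drop = FALSE]
  if (nrow(b) < 3) stop("need at least 3 non-empty bins with positive mean")
  w <- if (weighting == "count") b$n else rep(1, nrow(b))
  fit <- stats::lm(log10(mean_y) ~ log10(center), data = b, weights = w)
  cf <- stats::coef(fit)
  # summary.lm warns on exact fits; a zero stderr is a valid answer here
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(
    list(
      alpha = unname(cf[2]),
      alpha_se = se,
      prefactor = unname(10^cf[1]),
      n_bins = nrow(b),
      n_points = sum(b$n),
      weighting = weighting
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> y = %.4g * x^%.4g  (alpha se %.3g; %d bins, %d points)\n",
    x$prefactor, x$alpha, x$alpha_se, x$n_bins, x$n_points
  ))
  invisible(x)
}

#' Ensemble power-law fit over realizations
#'
#' Fits each realization separately and reports the mean and standard
#' deviation of the exponent across realizations, alongside the pooled fit
#' of all points together. Mirrors the error analysis of repeating a model
#' run several times and quoting exponent +/- spread.
#'
#' @param xy_list List of data frames, each with the x and y columns named
#'   by `x` and `y`.
#' @param x,y Column names (default `"N_M"`, `"N_L"`).
#' @param bins_per_decade Passed to [log_bin()].
#' @param weighting Passed to [fit_power_law()].
#' @return A list with `alpha_mean`, `alpha_sd`, `pooled`
#'   (a `power_law_fit` of the pooled points), and `fits`.
#' @export
fit_power_law_ensemble <- function(xy_list, x = "N_M", y = "N_L",
                                   bins_per_decade = 10,
                                   weighting = "count") {
  fits <- lapply(xy_list, function(d) {
    fit_power_law(log_bin(d[[x]], d[[y]], bins_per_decade), weighting)
  })
  alphas <- vapply(fits, `[[`, 0, "alpha")
  pooled_x <- unlist(lapply(xy_list, `[[`, x))
  pooled_y <- unlist(lapply(xy_list, `[[`, y))
  pooled <- fit_power_law(log_bin(pooled_x, pooled_y, bins_per_decade),
                          weighting)
  list(alpha_mean = mean(alphas), alpha_sd = stats::sd(alphas),
       pooled = pooled, fits = fits)
}
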