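#' Caliper tumor volume
#'
#' `volume = length x width x short x (3.14 / 6)`, where `short` is the
#' smaller of length and width and stands in for the unmeasured height.  The
#' constant is kept as the literal 3.14 for reproducibility of the printed
#' formula; set `exact_pi = TRUE` to use pi.
#'
#' @param length,width caliper measurements, mm (vectorised).
#' @param exact_pi use pi instead of 3.14.
#' @return volume in mm^3.
#' @examples
#' tumor_volume(6, 4)  # 50.24
#' @export
tumor_volume <- function(length, width, exact_pi = FALSE) {
  if (any(length <= 0) || any(width <= 0))
    stop("caliper measurements must be positive")
  short <- pmin(length, width)
  length * width * short * (if (exact_pi) pi else 3.14) / 6
}

#' Tumor growth series
#'
#' Time course of the diameter difference between the tumor and non-tumor
#' leg (mm) measured every other day by caliper.
#'
#' @param times measurement days, strictly increasing.
#' @param diameters positive diameters (mm).
#' @return an object of class `growth_series`.
#' @export
growth_series <- function(times, diameters) {
  times <- as.numeric(times); diameters <- as.numeric(diameters)
  if (length(times) != length(diameters)) stop("`times` and `diameters` differ in length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(diameters <= 0)) stop("diameters must be positive for exponential fitting")
  structure(data.frame(time = times, diameter = diameters), class = c("growth_series", "data.frame"))
}

#' Fit an exponential tumor growth rate
#'
#' Nonlinear least squares for `D(t) = y0 * exp(k * t)` (matching Prism's
#' exponential-growth fit), initialised from the log-linear regression of
#' `log D` on `t`.  The sign of `k` classifies the tumor: `k < 0` regressor,
#' `k >= 0` non-regressor.
#'
#' @param series a [growth_series] (or a data.frame with `time` and
#'   `diameter` columns); at least 3 observations.
#' @return an object of class `growth_fit` with components `k` (per day),
#'   `y0` (mm), `rss`, `classification`, `converged`, plus `fit` (the `nls`
#'   object) and the data.  Has `print`, `coef`, `predict`, `residuals` and
#'   `plot` methods.
#' @examples
#' s <- generate_growth_series(y0 = 2, k = 0.1, times = 0:20)
#' fit <- fit_growth_rate(s)
#' coef(fit)
#' @export
fit_growth_rate <- function(series) {
  df <- as.data.frame(series)
  if (!all(c("time", "diameter") %in% names(df)))
    stop("`series` needs `time` and `diameter` columns")
  if (nrow(df) < 3L) stop("need at least 3 observations to fit a growth rate")
  if (any(df$diameter <= 0)) stop("diameters must be positive")
  ll <- stats::lm(log(diameter) ~ time, data = df)
  start <- list(y0 = exp(unname(stats::coef(ll)[1])), k = unname(stats::coef(ll)[2]))
  fit <- tryCatch(
    stats::nls(diameter ~ y0 * exp(k * time), data = df, start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stop("growth fit did not converge: ", conditionMessage(e)))
  co <- stats::coef(fit)
  k <- unname(co["k"])
  structure(list(
    k = k,
    y0 = unname(co["y0"]),
    rss = stats::deviance(fit),
    classification = if (k < 0) "regressor" else "non-regressor",
    converged = fit$convInfo$isConv,
    iterations = fit$convInfo$finIter,
    fit = fit,
    data = df
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit: D(t) = y0 * exp(k * t)\n")
  cat(sprintf("  k  = %.6f per day\n", x$k))
  cat(sprintf("  y0 = %.6f mm\n", x$y0))
  cat(sprintf("  RSS %.6g over %d observations -> %s\n",
              x$rss, nrow(x$data), x$classification))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(y0 = object$y0, k = object$k)

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
  object$y0 * exp(object$k * t)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$data$diameter - predict(object)
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$diameter, xlab = "day",
                 ylab = "diameter difference (mm)", ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 100)
  graphics::lines(tt, x$y0 * exp(x$k * tt))
  invisible(x)
}

#' Simulate a caliper growth series
#'
#' `D(t) = y0 * exp(k * t) * (1 + e_t)` with `e_t ~ N(0, noise_sigma_frac)`,
#' deterministic at a fixed seed; the default sampling grid is every other
#' day, the cadence of caliper monitoring.
#'
#' @param y0 baseline diameter, mm.
#' @param k growth rate, per day.
#' @param noise_sigma_frac multiplicative Gaussian noise fraction (>= 0).
#' @param days last day of monitoring (used when `times` is NULL).
#' @param times explicit measurement days.
#' @param seed optional RNG seed.
#' @return a [growth_series].
#' @export
generate_growth_series <- function(y0, k, noise_sigma_frac = 0, days = 20,
                                   times = NULL, seed = NULL) {
  if (y0 <= 0) stop("`y0` must be positive")
  if (noise_sigma_frac < 0) stop("`noise_sigma_frac` must be non-negative")
  if (is.null(times)) times <- seq(0, days, by = 2)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sigma_frac > 0) stats::rnorm(length(times), 0, noise_sigma_frac) else 0
  d <- y0 * exp(k * times) * (1 + eps)
  if (any(d <= 0)) d <- pmax(d, .Machine$double.eps)
  growth_series(times, d)
}
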