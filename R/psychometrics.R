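# Weibull psychometric function: evaluation, bounded least-squares
# fitting with multi-start, and goodness of fit.

#' Weibull psychometric-function parameters
#'
#' `Psi(x) = gamma + (1 - gamma - lambda) * (1 - exp(-(x / alpha)^beta))`,
#' relating a stimulus covariate `x` (here the formant-frequency scale
#' factor, in percent) to proportion correct. `gamma` is the guess rate
#' (lower asymptote), `lambda` the lapse rate (1 minus the upper
#' asymptote), `alpha` the point of inflection in covariate units, and
#' `beta` the slope.
#'
#' @param gamma guess rate in `[0, 1)`.
#' @param lam lapse rate in `[0, 1)`; `gamma + lam < 1`.
#' @param alpha inflection point (> 0), in covariate units.
#' @param beta slope (> 0), dimensionless.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(gamma, lam, alpha, beta) {
  stopifnot(is.numeric(gamma), is.numeric(lam), is.numeric(alpha),
            is.numeric(beta))
  if (gamma < 0 || gamma >= 1 || lam < 0 || lam >= 1 || gamma + lam >= 1)
    stop("need gamma, lam in [0, 1) with gamma + lam < 1", call. = FALSE)
  if (alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive", call. = FALSE)
  structure(list(gamma = gamma, lam = lam, alpha = alpha, beta = beta),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf(
    "<weibull_params: gamma=%.3f lambda=%.3f alpha=%.3f beta=%.3f>\n",
    x$gamma, x$lam, x$alpha, x$beta))
  invisible(x)
}

#' Evaluate the Weibull psychometric function
#'
#' @param x covariate values (>= 0), e.g. scale factors in percent.
#' @param params a [weibull_params()].
#' @return Proportions in `[gamma, 1 - lambda]`.
#' @export
#' @examples
#' p <- weibull_params(0, 0, alpha = 33, beta = 1.5)
#' weibull_eval(33, p)  # 1 - exp(-1)
weibull_eval <- function(x, params) {
  stopifnot(inherits(params, "weibull_params"))
  x <- as.numeric(x)
  if (any(x < 0)) stop("covariate must be >= 0", call. = FALSE)
  params$gamma + (1 - params$gamma - params$lam) *
    (1 - exp(-(x / params$alpha)^params$beta))
}

#' Coefficient of determination
#'
#' `r^2 = 1 - SS_res / SS_tot` between observed and fitted values.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2);
#'   `observed` must not be constant.
#' @return r-squared value.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("r-squared is undefined for a constant observed vector",
         call. = FALSE)
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Fit a Weibull psychometric function
#'
#' Bounded least squares on mean proportions: `gamma, lambda` in
#' `[0, 0.5]`, `alpha` in `(0, 2 * max(x)]`, `beta` in `[0.1, 10]`.
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) is run from a fixed grid
#' of starting values over `(alpha, beta)` to avoid local minima, and the
#' best-converged fit is returned. When per-point trial counts are
#' supplied the residuals are weighted by them (approximate binomial
#' weighting); by default the fit is unweighted, matching a curve fit to
#' condition means.
#'
#' @param xs covariate values (>= 4 distinct).
#' @param ys observed mean proportions in `[0, 1]`.
#' @param n_per_point optional trial counts per point, used as weights.
#' @return A list with elements `params` (a [weibull_params()]),
#'   `r_squared`, and `sse`.
#' @export
fit_weibull <- function(xs, ys, n_per_point = NULL) {
  xs <- as.numeric(xs)
  ys <- as.numeric(ys)
  stopifnot(length(xs) == length(ys))
  if (length(unique(xs)) < 4L)
    stop("need at least 4 distinct covariate values", call. = FALSE)
  if (any(ys < 0) || any(ys > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (!is.null(n_per_point))
    stopifnot(length(n_per_point) == length(xs), all(n_per_point > 0))
  xmax <- max(xs)
  lower <- c(gamma = 0, lam = 0, alpha = 1e-6, beta = 0.1)
  upper <- c(gamma = 0.5, lam = 0.5, alpha = 2 * xmax, beta = 10)
  gamma0 <- min(max(min(ys), 0), 0.45)
  lam0 <- min(max(1 - max(ys), 0), 0.45)
  df <- data.frame(x = xs, y = ys)
  w <- if (is.null(n_per_point)) rep(1, length(xs)) else n_per_point
  best <- NULL
  for (alpha0 in unique(pmax(xmax * c(0.15, 0.3, 0.5, 0.8), 1e-3))) {
    for (beta0 in c(0.5, 1, 1.5, 2.5, 4)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ gamma + (1 - gamma - lam) * (1 - exp(-(x / alpha)^beta)),
          data = df, weights = w,
          start = list(gamma = gamma0, lam = lam0, alpha = alpha0,
                       beta = beta0),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-12,
                                               ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("Weibull fit failed to converge from any starting point",
         call. = FALSE)
  cf <- stats::coef(best$fit)
  params <- weibull_params(cf[["gamma"]], cf[["lam"]], cf[["alpha"]],
                           cf[["beta"]])
  fitted_y <- weibull_eval(xs, params)
  list(params = params,
       r_squared = r_squared(ys, fitted_y),
       sse = best$sse)
}
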