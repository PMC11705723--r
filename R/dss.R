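#' Drug sensitivity score (normalized area under the inhibition curve)
#'
#' DSS summarizes a fitted dose-response curve as the area of fitted percent
#' inhibition \eqn{I(x) = 100 - V(x)} in excess of an activity threshold `t`,
#' integrated over the tested log10-molar window and normalized to the
#' maximal achievable area. The integral is evaluated by the closed-form
#' antiderivative of the log-logistic (no numerical quadrature): writing
#' \eqn{u = \log_{10} x}, \eqn{k = b \ln 10} and
#' \eqn{f(u) = 1/(1 + e^{k(u - u_e)})},
#' \deqn{\int I\, du = (100 - c)\,u - (d - c)\left[u - \tfrac{1}{k}
#'   \ln(1 + e^{k(u - u_e)})\right] + C.}
#' The integration region starts where inhibition first exceeds `t` (the
#' closed-form `t`-crossing of [ic_p()]) and runs to the top of the window.
#'
#' Three normalizations are provided:
#' * variant 1: `100 * A / ((100 - t) * (x_max - x_min))` — area fraction of
#'   the maximal box;
#' * variant 2 (default): variant 1 divided by `log10(Rmax)`, `Rmax` the
#'   fitted maximal percent inhibition within the window — discounts curves
#'   that never reach deep inhibition;
#' * variant 3: variant 2 scaled by the responsive fraction of the window,
#'   `(x_max - x_t) / (x_max - x_min)`.
#'
#' Scores are clamped to `[0, 100]`; the score is exactly 0 whenever the
#' fitted maximal inhibition over the window does not exceed `t`.
#'
#' @param fit an [`ll4_fit`][fit_ll4] object.
#' @param x_min,x_max integration window in log10 molar; defaults to the
#'   tested dose range of the fit.
#' @param t activity threshold, percent inhibition (default 10).
#' @param variant DSS normalization variant, 1, 2 or 3 (default 2).
#' @param force score a non-converged fit anyway (default `FALSE`, error).
#' @return object of class `dss_result`: list with `dss`, `variant`, `t`,
#'   `x_min`, `x_max`, `area` (raw integrated excess inhibition,
#'   %*log10-decades) and `max_inhibition`.
#' @examples
#' x <- 10^seq(-8, -5, length.out = 8)
#' fit <- fit_ll4(x, ll4(x, 1, 0, 100, 10^-6.5))
#' dss(fit, variant = 1)$dss
#' @export
dss <- function(fit, x_min = NULL, x_max = NULL, t = 10,
                variant = 2, force = FALSE) {
  stopifnot(inherits(fit, "ll4_fit"), t >= 0, t < 100,
            variant %in% 1:3)
  if (!isTRUE(fit$converged) && !force) {
    stop("dss: fit did not converge (use force = TRUE to override)")
  }
  if (is.null(x_min)) x_min <- log10(fit$dose_min)
  if (is.null(x_max)) x_max <- log10(fit$dose_max)
  stopifnot(x_min < x_max)

  b <- fit$b; cc <- fit$c; d <- fit$d; e <- fit$e
  k <- b * log(10)
  ue <- log10(e)
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  # antiderivative of percent inhibition I(u) in u = log10(x)
  F_inh <- function(u) {
    (100 - cc) * u - (d - cc) * (u - softplus(k * (u - ue)) / k)
  }
  inh <- function(u) 100 - ll4(10^u, b, cc, d, e)

  max_inh <- inh(x_max)
  res <- list(dss = 0, variant = variant, t = t,
              x_min = x_min, x_max = x_max, area = 0,
              max_inhibition = max_inh)
  class(res) <- "dss_result"
  if (!is.finite(max_inh) || max_inh <= t) return(res)

  u_t <- if (inh(x_min) >= t) {
    x_min
  } else {
    # crossing exists: solve V = 100 - t in closed form
    log10(e * ((d - cc) / (100 - t - cc) - 1)^(1 / b))
  }
  area <- (F_inh(x_max) - F_inh(u_t)) - t * (x_max - u_t)
  score <- 100 * area / ((100 - t) * (x_max - x_min))
  if (variant >= 2) {
    score <- if (max_inh > 1) score / log10(max_inh) else 0
  }
  if (variant == 3) score <- score * (x_max - u_t) / (x_max - x_min)

  res$area <- area
  res$dss <- min(100, max(0, score))
  res
}

#' @export
print.dss_result <- function(x, ...) {
  cat(sprintf(
    "DSS (variant %d, t = %g%%): %.2f  [window %.2f..%.2f log10 M]\n",
    x$variant, x$t, x$dss, x$x_min, x$x_max))
  invisible(x)
}
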