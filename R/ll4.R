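#' Four-parameter log-logistic dose-response model
#'
#' The viability model used throughout the package is the four-parameter
#' log-logistic (4PL/LL4) curve
#' \deqn{V(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}}}
#' with slope `b > 0` (viability decreases with dose), lower asymptote `c`
#' (fixed at 0 by default, matching normalization where a full kill reads 0%),
#' upper asymptote `d` (% viability at vanishing dose) and midpoint
#' concentration `e` (molar), the dose at which viability is halfway between
#' the asymptotes.
#'
#' @param x dose vector, molar.
#' @param b,c,d,e LL4 parameters.
#' @return predicted percent viability at `x`.
#' @seealso [fit_ll4()], [ic_p()], [dss()]
#' @export
ll4 <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit a four-parameter log-logistic curve to viability data
#'
#' Least-squares fit of the LL4 model by bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]), with the lower asymptote fixed at zero by default.
#' The decreasing-viability parameterization is enforced through the bound
#' `b > 0`. Starting values are `d0 = max(viability)`, `e0` the dose whose
#' observed viability is nearest `d0/2`, `b0 = 1`; on failure up to five
#' restarts with log-jittered starts are attempted before the fit is flagged
#' non-converged (no error is thrown for solver failure).
#'
#' @param dose molar dose vector (strictly positive).
#' @param viability percent viability, same length as `dose`.
#' @param fix_lower_at_zero fix `c = 0` (default `TRUE`). At least 3 distinct
#'   doses are required when fixed, 4 when free.
#' @param n_restarts number of jittered restarts after the initial attempt.
#' @return an object of class `ll4_fit`: list with parameters `b`, `c`, `d`,
#'   `e`, `residual_sd`, `converged`, `n_points`, `outliers_removed`,
#'   `nonresponder` (fitted maximal inhibition over the tested window below
#'   10%), and the tested dose range.
#' @examples
#' x <- 10^seq(-8, -5, length.out = 8)
#' fit <- fit_ll4(x, ll4(x, b = 1, c = 0, d = 100, e = 1e-6))
#' fit$e
#' @export
fit_ll4 <- function(dose, viability, fix_lower_at_zero = TRUE,
                    n_restarts = 5) {
  stopifnot(length(dose) == length(viability))
  keep <- is.finite(dose) & is.finite(viability) & dose > 0
  dose <- dose[keep]; viability <- viability[keep]
  n_distinct <- length(unique(dose))
  min_doses <- if (fix_lower_at_zero) 3L else 4L
  if (n_distinct < min_doses) {
    stop("fit_ll4: need >= ", min_doses, " distinct positive doses, got ",
         n_distinct)
  }

  dat <- data.frame(x = dose, y = viability)
  d0 <- max(viability)
  e0 <- dose[which.min(abs(viability - d0 / 2))]
  b0 <- 1

  fit1 <- function(start) {
    if (fix_lower_at_zero) {
      try(minpack.lm::nlsLM(
        y ~ d / (1 + exp(b * (log(x) - log(e)))),
        data = dat, start = start[c("b", "d", "e")],
        lower = c(b = 1e-3, d = 0, e = 1e-30),
        upper = c(b = 50, d = 1e4, e = 1e6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e)))),
        data = dat, start = start,
        lower = c(b = 1e-3, c = -1e3, d = 0, e = 1e-30),
        upper = c(b = 50, c = 1e4, d = 1e4, e = 1e6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    }
  }

  start <- list(b = b0, c = min(viability), d = d0, e = e0)
  fit <- fit1(start)
  tries <- 0
  while (inherits(fit, "try-error") && tries < n_restarts) {
    tries <- tries + 1
    start$e <- e0 * exp(stats::runif(1, -2, 2))
    start$b <- b0 * exp(stats::runif(1, -1, 1))
    fit <- fit1(start)
  }

  converged <- !inherits(fit, "try-error")
  if (converged) {
    cf <- stats::coef(fit)
    b <- unname(cf["b"]); e <- unname(cf["e"]); d <- unname(cf["d"])
    cc <- if (fix_lower_at_zero) 0 else unname(cf["c"])
    rsd <- sqrt(sum(stats::resid(fit)^2) / max(1, length(dose) - length(cf)))
  } else {
    b <- NA_real_; e <- NA_real_; d <- NA_real_; cc <- NA_real_
    rsd <- NA_real_
  }

  x_rng <- range(dose)
  nonresp <- if (converged) {
    max_inh <- 100 - ll4(x_rng[2], b, cc, d, e)
    is.finite(max_inh) && max_inh < 10
  } else NA

  structure(list(
    b = b, c = cc, d = d, e = e,
    residual_sd = rsd, converged = converged,
    n_points = length(dose), outliers_removed = 0L,
    nonresponder = nonresp,
    dose_min = x_rng[1], dose_max = x_rng[2],
    data = dat
  ), class = "ll4_fit")
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat("LL4 fit:", if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  b = %.4g  c = %.4g  d = %.4g  e = %.4g M\n",
              x$b, x$c, x$d, x$e))
  cat(sprintf("  residual SD = %.3g, n = %d, outliers removed = %d\n",
              x$residual_sd, x$n_points, x$outliers_removed))
  if (isTRUE(x$nonresponder)) cat("  flagged non-responder\n")
  invisible(x)
}

#' @export
predict.ll4_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  ll4(x, object$b, object$c, object$d, object$e)
}

#' Inhibitory concentration at p percent inhibition
#'
#' Closed-form inversion of the fitted LL4 curve. The default convention is
#' absolute inhibition on the normalized 0-100 viability scale: `ic_p(fit, 50)`
#' is the dose at which fitted viability equals 50%, regardless of the
#' asymptotes. With `type = "relative"` the target is `p`% of the fitted
#' asymptote span, i.e. viability `d - p/100 (d - c)`.
#'
#' @param fit an [`ll4_fit`][fit_ll4] object (must have converged).
#' @param p target percent inhibition in (0, 100).
#' @param type `"absolute"` (default) or `"relative"`.
#' @return molar concentration producing `p`% inhibition.
#' @examples
#' x <- 10^seq(-8, -5, length.out = 8)
#' fit <- fit_ll4(x, ll4(x, 1, 0, 100, 1e-6))
#' ic_p(fit, 50)  # equals the midpoint e
#' @export
ic_p <- function(fit, p, type = c("absolute", "relative")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "ll4_fit"), p > 0, p < 100)
  if (!isTRUE(fit$converged)) stop("ic_p: fit did not converge")
  y <- if (type == "absolute") 100 - p else fit$d - (p / 100) * (fit$d - fit$c)
  if (!(y > fit$c && y < fit$d)) {
    stop(sprintf(
      "ICp not reached within model range: target viability %.3g not in (c=%.3g, d=%.3g)",
      y, fit$c, fit$d))
  }
  fit$e * ((fit$d - fit$c) / (y - fit$c) - 1)^(1 / fit$b)
}

#' Outlier-robust refit of a dose-response curve
#'
#' Single-pass outlier rejection: an initial LL4 fit is computed, points whose
#' absolute studentized residual (residual / residual SD) exceeds `cutoff` are
#' dropped (at most 20% of points, largest residuals first), and the model is
#' refit once. If removal would leave fewer than 4 distinct doses (or the
#' initial fit fails), all points are kept and the fit is flagged.
#'
#' @param dose,viability as in [fit_ll4()]; at least 6 points required.
#' @param cutoff studentized-residual threshold (default 3).
#' @param ... passed to [fit_ll4()].
#' @return an [`ll4_fit`][fit_ll4] with `outliers_removed` set, plus
#'   `outlier_index` (indices into the input) and `removal_skipped` flag.
#' @export
remove_outliers_and_refit <- function(dose, viability, cutoff = 3, ...) {
  stopifnot(length(dose) == length(viability), length(dose) >= 6)
  fit0 <- fit_ll4(dose, viability, ...)
  if (!fit0$converged || !is.finite(fit0$residual_sd) ||
      fit0$residual_sd == 0) {
    fit0$removal_skipped <- !fit0$converged
    fit0$outlier_index <- integer(0)
    return(fit0)
  }
  res <- abs(viability - ll4(dose, fit0$b, fit0$c, fit0$d, fit0$e)) /
    fit0$residual_sd
  cand <- which(res > cutoff)
  max_rm <- floor(0.2 * length(dose))
  if (length(cand) > max_rm) {
    cand <- cand[order(res[cand], decreasing = TRUE)][seq_len(max_rm)]
  }
  if (length(cand) == 0) {
    fit0$removal_skipped <- FALSE
    fit0$outlier_index <- integer(0)
    return(fit0)
  }
  keep <- setdiff(seq_along(dose), cand)
  if (length(unique(dose[keep])) < 4) {
    fit0$removal_skipped <- TRUE
    fit0$outlier_index <- integer(0)
    return(fit0)
  }
  fit <- fit_ll4(dose[keep], viability[keep], ...)
  fit$outliers_removed <- length(cand)
  fit$outlier_index <- cand
  fit$removal_skipped <- FALSE
  fit
}
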