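# increasing logistic on the inhibition-fraction scale, baseline m -> 1
fit_direction <- function(x, y, m0, b0 = 1, e0 = stats::median(x)) {
  dat <- data.frame(x = x, y = y)
  starts <- list(
    list(m = m0, b = b0, e = e0),
    list(m = max(-0.9, min(0.9, min(y))), b = 1, e = stats::median(x)),
    list(m = m0, b = 2, e = exp(mean(log(x)))))
  for (s in starts) {
    fit <- try(minpack.lm::nlsLM(
      y ~ m + (1 - m) / (1 + (e / x)^b),
      data = dat, start = s,
      lower = c(m = -1, b = 1e-3, e = 1e-30),
      upper = c(m = 1, b = 50, e = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-13, ptol = 1e-13)
    ), silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit)
  }
  NULL
}

predict_direction <- function(fit, x) {
  cf <- stats::coef(fit)
  unname(cf["m"] + (1 - cf["m"]) / (1 + (cf["e"] / x)^cf["b"]))
}

#' ZIP synergy deltas for a combination grid
#'
#' Scores departure from the zero-interaction-potency null. On the
#' inhibition-fraction scale the zero-interaction expectation at a dose pair
#' is the Bliss form `y_zip = y1 + y2 - y1 y2` built from the fitted
#' monotherapy marginals. The observed combination response is taken from
#' directional logistic refits: at each fixed dose of one drug, the response
#' along the other drug is refit as a logistic running from a free baseline
#' to full inhibition; in a factorial design the two directions are averaged,
#' in an anchored design (one priming dose) the single available direction is
#' used, with the priming drug's marginal taken from its monotherapy fit.
#' `delta = (observed - y_zip) * 100` per dose pair (percent scale), defined
#' only where both doses are positive; the summary is the mean delta.
#'
#' @param grid a [`combination_grid`][generate_combination_grid] or
#'   compatible list (`concA`, `concB`, `viability` % matrix, `design`).
#' @param fitA,fitB optional [`ll4_fit`][fit_ll4] monotherapy fits for drug
#'   A / B. When absent they are fit from the grid's zero-dose marginals;
#'   an anchored design requires `fitA` (the priming drug has a single
#'   positive dose) unless `baselineA` is supplied.
#' @param baselineA optional priming-drug inhibition fraction at its fixed
#'   dose, overriding `fitA` in anchored designs.
#' @return object of class `zip_result`: `delta` matrix (rows = positive
#'   `concA`, columns = positive `concB`; one row for anchored grids),
#'   `summary` (mean delta, % scale), `design`, `excluded_directions`.
#' @export
zip_delta <- function(grid, fitA = NULL, fitB = NULL, baselineA = NULL) {
  cA <- grid$concA; cB <- grid$concB
  V <- grid$viability
  design <- if (!is.null(grid$design)) grid$design else "factorial"
  iA <- which(cA > 0); iB <- which(cB > 0)
  if (length(iB) < 3) stop("zip_delta: need >= 3 positive doses of drug B")
  Y <- 1 - V / 100
  xA <- cA[iA]; xB <- cB[iB]

  # trivial all-zero response grid
  if (max(abs(Y)) < 1e-9) {
    delta <- matrix(0, length(iA), length(iB))
    return(structure(list(delta = delta, summary = 0, design = design,
                          fitA = fitA, fitB = fitB,
                          excluded_directions = character(0)),
                     class = "zip_result"))
  }

  inh_from_fit <- function(fit, x) 1 - ll4(x, fit$b, fit$c, fit$d, fit$e) / 100

  zeroB <- which(cB == 0); zeroA <- which(cA == 0)
  if (is.null(fitB)) {
    if (length(zeroA) == 0) {
      stop("zip_delta: no zero-dose marginal for drug B and no fitB supplied")
    }
    fitB <- fit_ll4(xB, V[zeroA[1], iB])
  }
  yB <- inh_from_fit(fitB, xB)

  if (design == "anchored" || length(iA) == 1) {
    if (length(iA) != 1) stop("zip_delta: anchored grid must have one priming dose")
    yA <- if (!is.null(baselineA)) baselineA
    else if (!is.null(fitA)) inh_from_fit(fitA, xA)
    else if (length(zeroB) == 1) Y[iA, zeroB]  # observed fallback
    else stop("zip_delta: anchored design needs fitA or baselineA for the priming drug")
    y_obs <- Y[iA, iB]
    dfit <- fit_direction(xB, y_obs, m0 = max(-0.9, min(0.9, yA)),
                          b0 = fitB$b, e0 = fitB$e)
    excl <- character(0)
    if (is.null(dfit)) {
      obs <- y_obs  # unfittable direction: fall back to observed response
      excl <- "B|A=priming"
    } else {
      obs <- predict_direction(dfit, xB)
    }
    yz <- yA + yB - yA * yB
    delta <- matrix((obs - yz) * 100, nrow = 1,
                    dimnames = list(format(xA), format(xB)))
    return(structure(list(delta = delta, summary = mean(delta),
                          design = "anchored", fitA = fitA, fitB = fitB,
                          excluded_directions = excl),
                     class = "zip_result"))
  }

  if (length(iA) < 3) stop("zip_delta: need >= 3 positive doses of drug A")
  if (is.null(fitA)) {
    if (length(zeroB) == 0) {
      stop("zip_delta: no zero-dose marginal for drug A and no fitA supplied")
    }
    fitA <- fit_ll4(xA, V[iA, zeroB[1]])
  }
  yA <- inh_from_fit(fitA, xA)
  yz <- outer(yA, yB, function(a, b) a + b - a * b)

  excluded <- character(0)
  # direction 1: titrate A at each fixed positive B
  O1 <- matrix(NA_real_, length(iA), length(iB))
  for (j in seq_along(iB)) {
    dfit <- fit_direction(xA, Y[iA, iB[j]],
                          m0 = max(-0.9, min(0.9, yB[j])),
                          b0 = fitA$b, e0 = fitA$e)
    if (is.null(dfit)) {
      excluded <- c(excluded, sprintf("A|B=%g", xB[j]))
    } else O1[, j] <- predict_direction(dfit, xA)
  }
  # direction 2: titrate B at each fixed positive A
  O2 <- matrix(NA_real_, length(iA), length(iB))
  for (i in seq_along(iA)) {
    dfit <- fit_direction(xB, Y[iA[i], iB],
                          m0 = max(-0.9, min(0.9, yA[i])),
                          b0 = fitB$b, e0 = fitB$e)
    if (is.null(dfit)) {
      excluded <- c(excluded, sprintf("B|A=%g", xA[i]))
    } else O2[i, ] <- predict_direction(dfit, xB)
  }
  if (all(is.na(O1)) && all(is.na(O2))) {
    stop("zip_delta: both directional refits failed")
  }
  obs <- matrix(rowMeans(cbind(as.vector(O1), as.vector(O2)), na.rm = TRUE),
                length(iA), length(iB))
  # cells with no usable directional fit (e.g. saturated rows where the
  # logistic is unidentifiable) fall back to the observed response
  miss <- !is.finite(obs)
  obs[miss] <- Y[iA, iB][miss]
  delta <- (obs - yz) * 100
  dimnames(delta) <- list(format(xA), format(xB))
  structure(list(delta = delta, summary = mean(delta), design = "factorial",
                 fitA = fitA, fitB = fitB,
                 excluded_directions = excluded),
            class = "zip_result")
}

#' @export
print.zip_result <- function(x, ...) {
  cat(sprintf("ZIP (%s design): summary delta = %.3f%% over %d dose pairs\n",
              x$design, x$summary, length(x$delta)))
  if (length(x$excluded_directions)) {
    cat("  excluded directions:",
        paste(x$excluded_directions, collapse = ", "), "\n")
  }
  invisible(x)
}
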