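test_that("noiseless LL4 data are recovered to high relative accuracy", {
  x <- half_log_grid(1e-8, 8)
  truth <- list(b = 1.3, d = 95, e = 4e-7)
  fit <- fit_ll4(x, ll4(x, truth$b, 0, truth$d, truth$e))
  expect_true(fit$converged)
  expect_lt(abs(fit$b / truth$b - 1), 1e-6)
  expect_lt(abs(fit$d / truth$d - 1), 1e-6)
  expect_lt(abs(fit$e / truth$e - 1), 1e-6)
  expect_equal(fit$c, 0)
})

test_that("free-lower-asymptote fits recover a nonzero floor", {
  x <- half_log_grid(1e-8, 10)
  v <- ll4(x, 1.5, 20, 100, 1e-6)
  fit <- fit_ll4(x, v, fix_lower_at_zero = FALSE)
  expect_lt(abs(fit$c - 20), 1e-3)
})

test_that("flat viability is flagged non-responder and scores zero", {
  x <- half_log_grid(1e-8, 8)
  fit <- fit_ll4(x, rep(100, 8) + c(-.1, .1, 0, 0, -.1, .1, 0, 0))
  expect_true(fit$converged)
  expect_true(fit$nonresponder)
  expect_equal(dss(fit)$dss, 0)
})

test_that("too few distinct doses fail", {
  expect_error(fit_ll4(c(1e-7, 1e-7, 1e-6), c(90, 91, 50)), "distinct")
})

test_that("ic_p inverts the fitted curve in closed form", {
  x <- half_log_grid(1e-8, 8)
  fit <- fit_ll4(x, ll4(x, 1, 0, 100, 1e-6))
  expect_equal(ic_p(fit, 50), 1e-6, tolerance = 1e-6)
  # p = 20, b = 1: x = e (100/80 - 1) = e/4; cross-check by root finding
  expect_equal(ic_p(fit, 20), 2.5e-7, tolerance = 1e-6)
  root <- stats::uniroot(function(z) ll4(z, fit$b, fit$c, fit$d, fit$e) - 80,
                         c(1e-10, 1e-3), tol = 1e-16)$root
  expect_equal(ic_p(fit, 20), root, tolerance = 1e-8)
  # forward/inverse identity over a sweep of p
  for (p in c(5, 20, 35, 50, 65, 80, 95)) {
    expect_lt(abs(ll4(ic_p(fit, p), fit$b, fit$c, fit$d, fit$e) -
                    (100 - p)), 1e-9)
  }
})

test_that("ic_p refuses targets outside the model range", {
  x <- half_log_grid(1e-8, 10)
  # viability floor at 50%: 90% inhibition is never reached
  fit <- fit_ll4(x, ll4(x, 1, 50, 100, 1e-6), fix_lower_at_zero = FALSE)
  expect_error(ic_p(fit, 90), "not reached")
})

test_that("relative-to-asymptote ICp mode uses the asymptote span", {
  x <- half_log_grid(1e-8, 8)
  fit <- fit_ll4(x, ll4(x, 1, 0, 80, 1e-6))
  # relative IC50 is the midpoint e regardless of d
  expect_equal(ic_p(fit, 50, type = "relative"), fit$e, tolerance = 1e-9)
  # with d = 80 the absolute 50%-viability target (above the relative
  # midpoint of 40%) is crossed at a lower dose
  expect_lt(ic_p(fit, 50, type = "absolute"),
            ic_p(fit, 50, type = "relative"))
})

test_that("closed-form DSS agrees with a dense trapezoid oracle", {
  set.seed(31)
  for (i in 1:50) {
    b <- stats::runif(1, 0.5, 3)
    d <- stats::runif(1, 20, 100)
    e <- 10^stats::runif(1, -8, -4)
    x <- half_log_grid(1e-9, 10)
    fit <- fit_ll4(x, ll4(x, b, 0, d, e))
    t <- 10
    r <- dss(fit, t = t, variant = 1)
    u <- seq(log10(min(x)), log10(max(x)), length.out = 10001)
    inh <- pmax(0, (100 - ll4(10^u, b, 0, d, e)) - t)
    A <- sum((inh[-1] + inh[-length(inh)]) / 2 * diff(u))
    ref <- 100 * A / ((100 - t) * (log10(max(x)) - log10(min(x))))
    if (ref > 1e-6) expect_lt(abs(r$dss - ref) / ref, 1e-4)
    else expect_lt(abs(r$dss - ref), 1e-6)
  }
})

test_that("DSS boundary cases: inert and fully active curves", {
  x <- half_log_grid(1e-8, 8)
  # maximal inhibition below threshold -> empty integration region
  weak <- fit_ll4(x, ll4(x, 1, 0, 100, 1))  # e far above window
  expect_equal(dss(weak, t = 10)$dss, 0)
  # inhibition ~ 100 across the whole window -> variant 1 saturates at 100
  strong <- structure(list(b = 5, c = 0, d = 100, e = 1e-14,
                           converged = TRUE, dose_min = 1e-8,
                           dose_max = 1e-5), class = "ll4_fit")
  expect_equal(dss(strong, t = 10, variant = 1)$dss, 100, tolerance = 1e-6)
})

test_that("DSS is monotone non-decreasing in drug efficacy", {
  # efficacy = maximal inhibition; raising it lowers the viability floor
  effs <- seq(20, 100, by = 10)
  for (variant in 1:3) {
    scores <- vapply(effs, function(d_eff) {
      fit <- structure(list(b = 1.2, c = 100 - d_eff, d = 100, e = 1e-6,
                            converged = TRUE, dose_min = 1e-8,
                            dose_max = 10^-4.5), class = "ll4_fit")
      dss(fit, t = 10, variant = variant)$dss
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-9))
  }
})

test_that("DSS is invariant under consistent relabeling of dose units", {
  fit_m <- structure(list(b = 1.2, c = 0, d = 90, e = 1e-6,
                          converged = TRUE, dose_min = 1e-8,
                          dose_max = 1e-4), class = "ll4_fit")
  fit_um <- fit_m
  fit_um$e <- fit_m$e * 1e6   # molar -> micromolar
  fit_um$dose_min <- fit_m$dose_min * 1e6
  fit_um$dose_max <- fit_m$dose_max * 1e6
  for (variant in 1:3) {
    expect_equal(dss(fit_m, variant = variant)$dss,
                 dss(fit_um, variant = variant)$dss, tolerance = 1e-10)
  }
})

test_that("DSS variants apply the extra normalizations in order", {
  fit <- structure(list(b = 1.2, c = 0, d = 90, e = 1e-6, converged = TRUE,
                        dose_min = 1e-8, dose_max = 1e-4),
                   class = "ll4_fit")
  s1 <- dss(fit, variant = 1); s2 <- dss(fit, variant = 2)
  s3 <- dss(fit, variant = 3)
  expect_equal(s2$dss, s1$dss / log10(s1$max_inhibition), tolerance = 1e-10)
  expect_lte(s3$dss, s2$dss)
  expect_error(dss(fit, x_min = -4, x_max = -8))
})

test_that("a displaced point is removed and the fit restored", {
  x <- rep(half_log_grid(1e-8, 8), each = 3)
  # noiseless clean data: nothing removed, fit identical
  v0 <- ll4(x, 1.2, 0, 100, 3e-7)
  fit0 <- remove_outliers_and_refit(x, v0)
  expect_equal(fit0$outliers_removed, 0L)
  expect_lt(abs(fit0$e / 3e-7 - 1), 1e-6)
  # one grossly displaced point: removed, midpoint restored within 2%
  v_sp <- v0
  v_sp[5] <- v0[5] + 30
  fit_sp <- remove_outliers_and_refit(x, v_sp)
  expect_gte(fit_sp$outliers_removed, 1L)
  expect_true(5 %in% fit_sp$outlier_index)
  expect_lt(abs(fit_sp$e / 3e-7 - 1), 0.02)
})

test_that("outlier pass is unbiased on clean data across seeds", {
  set.seed(12)
  ratios <- replicate(50, {
    x <- rep(half_log_grid(1e-8, 8), each = 2)
    v <- ll4(x, 1, 0, 100, 1e-6) * exp(stats::rnorm(length(x), 0, 0.05))
    f <- remove_outliers_and_refit(x, v)
    f$e / 1e-6
  })
  expect_lt(abs(stats::median(ratios) - 1), 0.05)
})

test_that("removal that would leave too few doses keeps all points", {
  x <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-8, 1e-7)
  v <- ll4(x, 1, 0, 100, 5e-7) + c(0, 0, 0, 30, -1, 1)
  fit <- remove_outliers_and_refit(x, v)
  expect_true(fit$removal_skipped || fit$outliers_removed == 0L)
  expect_equal(fit$n_points, 6L)
})
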