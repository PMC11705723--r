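test_that("noiseless wells reproduce the true curve, incl. the 50% midpoint", {
  grid <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4)  # includes the midpoint e = 1e-6
  cfg <- small_config(noise_cv = 0, grid = grid,
                      replicates_technical = 1L, replicates_biological = 1L)
  tr <- manual_truth(cfg, b = 1, d = 100, e = 1e-6)
  w <- generate_screen(cfg, tr, bio_e_cv = 0)
  mid <- w[w$role == "treatment" & w$conc1_M == 1e-6 &
             w$condition == "media", ]
  expect_equal(mid$expected_viability_pct, 50)
  # RFU at the midpoint is exactly half the plate's full-viability signal
  expect_equal(mid$rfu / mid$plate_gain, 0.5)
  # full curve reproduced exactly at every grid point
  tre <- w[w$role == "treatment" & w$condition == "media", ]
  expect_lt(max(abs(tre$expected_viability_pct -
                      ll4(tre$conc1_M, 1, 0, 100, 1e-6))), 1e-9)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 42L)
  tr <- truth_set(cfg)
  w1 <- generate_screen(cfg, tr)
  w2 <- generate_screen(cfg, tr)
  expect_identical(w1, w2)
  g1 <- generate_combination_grid(tr, "CL1", "media", "drugX", "drugX",
                                  concA = half_log_grid(1e-7),
                                  concB = half_log_grid(1e-7),
                                  noise_cv = 0.05, seed = 42L)
  g2 <- generate_combination_grid(tr, "CL1", "media", "drugX", "drugX",
                                  concA = half_log_grid(1e-7),
                                  concB = half_log_grid(1e-7),
                                  noise_cv = 0.05, seed = 42L)
  expect_identical(g1$viability, g2$viability)
})

test_that("multiplicative noise model yields the configured CV per dose", {
  cfg <- small_config(seed = 9L, noise_cv = 0.05,
                      replicates_technical = 6L, replicates_biological = 1L,
                      grid = half_log_grid(1e-8, 8))
  tr <- manual_truth(cfg, b = 1, d = 100, e = 1e-5)
  w <- generate_screen(cfg, tr, bio_e_cv = 0)
  tre <- w[w$role == "treatment", ]
  cvs <- tapply(tre$rfu, list(tre$plate_id, tre$conc1_M),
                function(v) stats::sd(v) / mean(v))
  cvs <- cvs[is.finite(cvs)]
  expect_gte(mean(cvs >= 0.02 & cvs <= 0.08), 0.9)
})

test_that("well counts match the combinatorial product of the design", {
  cfg <- screen_config(seed = 3L)
  tr <- truth_set(cfg)
  w <- generate_screen(cfg, tr)
  n_plates <- length(cfg$cell_lines) * length(cfg$media_conditions) *
    cfg$replicates_biological
  n_treat_per_plate <- sum(lengths(cfg$grids)) * cfg$replicates_technical
  expect_equal(sum(w$role == "treatment"), n_plates * n_treat_per_plate)
  expect_equal(nrow(w),
               n_plates * (n_treat_per_plate + sum(cfg$control_counts)))
  expect_equal(length(unique(w$plate_id)), n_plates)
})

test_that("doubling the resistance shift doubles the 50%-crossing dose", {
  cfg <- small_config(noise_cv = 0)
  tr1 <- manual_truth(cfg, b = 1.3, d = 100, e = 2e-7,
                      resistance_shift = 2, efficacy_loss = 0)
  tr2 <- manual_truth(cfg, b = 1.3, d = 100, e = 2e-7,
                      resistance_shift = 4, efficacy_loss = 0)
  cross <- function(tr) {
    p <- truth_params(tr, "CL1", "drugX", "AAF1")
    stats::uniroot(function(x) expected_viability(p, x) - 50,
                   c(1e-12, 1), tol = 1e-15)$root
  }
  expect_equal(cross(tr2) / cross(tr1), 2, tolerance = 1e-6)
})

test_that("missing truth entries fail with a descriptive message", {
  cfg <- small_config()
  tr <- truth_set(cfg)
  expect_error(truth_params(tr, "CL1", "nosuchdrug", "media"), "nosuchdrug")
  cfg2 <- small_config(drug = "otherdrug")
  expect_error(generate_screen(cfg2, tr), "otherdrug")
})

test_that("combination grids implement the Bliss-plus-epsilon surface", {
  cfg <- small_config(noise_cv = 0)
  tr <- manual_truth(cfg, b = 1, d = 100, e = 1e-6,
                     resistance_shift = 1, efficacy_loss = 0)
  # doses giving marginal inhibition exactly 0.3 and 0.4 when b=1, d=100
  xA <- 1e-6 * (100 / 70 - 1)   # y1 = 0.3
  xB <- 1e-6 * (100 / 60 - 1)   # y2 = 0.4
  g <- generate_combination_grid(
    tr, "CL1", "media", "drugX", "drugX",
    concA = c(xA, 10 * xA), concB = c(xB, 10 * xB),
    design = "factorial", epsilon = 0.1)
  # zero-dose corner: indicator off, inhibition 0
  expect_equal(g$expected[1, 1], 100)
  # y1 + y2 - y1*y2 + eps = 0.3 + 0.4 - 0.12 + 0.1 = 0.68
  expect_equal(unname(g$expected[2, 2]), 100 * (1 - 0.68),
               tolerance = 1e-12)
  # epsilon = 0 case: pure Bliss independence, 0.5 + 0.5 case
  x50 <- 1e-6
  g2 <- generate_combination_grid(
    tr, "CL1", "media", "drugX", "drugX",
    concA = c(x50, 10 * x50), concB = c(x50, 10 * x50),
    design = "factorial", epsilon = 0)
  expect_equal(unname(g2$expected[2, 2]), 100 * (1 - 0.75),
               tolerance = 1e-12)
})

test_that("anchored grids require exactly one priming dose", {
  cfg <- small_config()
  tr <- manual_truth(cfg)
  expect_error(
    generate_combination_grid(tr, "CL1", "media", "drugX", "drugX",
                              concA = c(1e-7, 1e-6),
                              concB = half_log_grid(1e-7),
                              design = "anchored"),
    "priming")
})

test_that("marker tables recover target correlations at large n", {
  ct <- data.frame(marker_i = "STAT3_pY705", marker_j = "STAT5_pY694",
                   rho = 0.88)
  mt <- marker_truth(cor_targets = ct, seed = 4L)
  tab <- generate_marker_table(mt, 500)
  fc <- normalize_markers(tab)
  r <- stats::cor(fc$STAT3_pY705[-1], fc$STAT5_pY694[-1])
  expect_lt(abs(r - 0.88), 0.05)
})

test_that("independent markers show no spurious correlation at large n", {
  mt <- marker_truth(seed = 5L)
  tab <- generate_marker_table(mt, 1000)
  fc <- normalize_markers(tab)[-1, 1:10]
  r <- stats::cor(fc)
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)
})

test_that("tiny marker tables are flagged, infeasible targets refused", {
  mt <- marker_truth(seed = 6L)
  expect_warning(tab <- generate_marker_table(mt, 3), "unreliable")
  expect_true(attr(tab, "correlation_unreliable"))
  expect_equal(nrow(tab), 4)  # control + 3 stimulations
  bad <- data.frame(
    marker_i = c("STAT3_pY705", "STAT5_pY694", "STAT3_pY705"),
    marker_j = c("STAT5_pY694", "STAT1_pY701", "STAT1_pY701"),
    rho = c(0.95, 0.95, -0.95))
  mtb <- marker_truth(cor_targets = bad, seed = 6L)
  expect_error(generate_marker_table(mtb, 100), "positive semi-definite")
})

test_that("plate CSV round-trips and config reads from YAML", {
  cfg <- small_config(seed = 2L)
  tr <- truth_set(cfg)
  w <- generate_screen(cfg, tr)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(w, f)
  w2 <- read_plate_csv(f)
  expect_equal(nrow(w2), nrow(w))
  expect_equal(w2$rfu, w$rfu, tolerance = 1e-12)
  expect_identical(w2$role, w$role)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cell_lines: [CL1, CL2]",
    "media_conditions: [media, AAF1]",
    "drugs:",
    "  - {name: drugX, role: novel}",
    "grids:",
    "  drugX: [1.0e-8, 1.0e-7, 1.0e-6]",
    "replicates_technical: 2",
    "replicates_biological: 1",
    "noise_cv: 0.1",
    "seed: 7"), yml)
  cfg2 <- read_screen_config(yml)
  expect_s3_class(cfg2, "screen_config")
  expect_equal(cfg2$grids$drugX, c(1e-8, 1e-7, 1e-6))
  expect_equal(cfg2$noise_cv, 0.1)
})
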