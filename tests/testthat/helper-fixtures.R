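# shared fixtures: all synthetic, built in code

# minimal screen: 1 cell line, media + 1 AAF, 1 drug
small_config <- function(seed = 1L, noise_cv = 0.05,
                         replicates_technical = 3L,
                         replicates_biological = 2L,
                         drug = "drugX", grid = half_log_grid(1e-7)) {
  screen_config(
    cell_lines = "CL1",
    media_conditions = c("media", "AAF1"),
    drugs = data.frame(name = drug, role = "novel"),
    grids = stats::setNames(list(grid), drug),
    replicates_technical = replicates_technical,
    replicates_biological = replicates_biological,
    noise_cv = noise_cv, seed = seed)
}

# truth set with hand-picked curve parameters
manual_truth <- function(config, b = 1, d = 100, e = 1e-6,
                         resistance_shift = 2, efficacy_loss = 10,
                         epsilon = 0) {
  tr <- truth_set(config, epsilon = epsilon)
  tr$curves$b <- b
  tr$curves$d <- d
  tr$curves$e <- e
  aaf <- tr$shifts$condition != config$media_conditions[1]
  tr$shifts$resistance_shift[aaf] <- resistance_shift
  tr$shifts$efficacy_loss[aaf] <- efficacy_loss
  tr
}

# noiseless factorial grid from explicit marginal curves, with moderate
# (sub-saturating) responses so the interaction term is not clipped away
bliss_grid <- function(b1 = 1.2, e1 = NULL, b2 = 0.9, e2 = NULL,
                       d1 = 100, d2 = 100,
                       conc = half_log_grid(1e-7), epsilon = 0) {
  if (is.null(e1)) e1 <- max(conc)
  if (is.null(e2)) e2 <- max(conc) / 3
  y1 <- 1 - ll4(conc, b1, 0, d1, e1) / 100
  y2 <- 1 - ll4(conc, b2, 0, d2, e2) / 100
  yz <- outer(y1, y2, function(a, b) a + b - a * b)
  n <- length(conc)
  V <- matrix(100, n + 1, n + 1)
  V[-1, 1] <- 100 * (1 - y1)
  V[1, -1] <- 100 * (1 - y2)
  V[-1, -1] <- 100 * (1 - pmin(1, pmax(0, yz + epsilon)))
  list(concA = c(0, conc), concB = c(0, conc), viability = V,
       design = "factorial", epsilon = epsilon)
}

# brute-force Holm step-down: adj p_(i) = max_{j <= i} min(1, (m-j+1) p_(j))
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    padj[o[i]] <- running
  }
  padj
}

# brute-force Ward-D2 agglomeration: greedy merges minimizing
# sqrt(2 nA nB / (nA + nB)) * ||centroid_A - centroid_B||
ward_d2_brute <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        h <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ca - cb)^2))
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]],
                                           clusters[[best[2]]]))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  list(heights = heights, merges = merges)
}
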