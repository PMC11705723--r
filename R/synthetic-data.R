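#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default half-log concentration grid
#'
#' Eight points at half-log (sqrt(10)) spacing starting at `from` molar. The
#' single-agent default starts at 1 uM; combination titrations are shifted
#' one decade down to accommodate the more potent combined effects.
#'
#' @param from lowest concentration, molar.
#' @param n number of points.
#' @return strictly increasing molar vector.
#' @export
half_log_grid <- function(from = 1e-6, n = 8) {
  from * 10^(0.5 * (seq_len(n) - 1))
}

#' Screen configuration
#'
#' Describes a viability screen: cell lines, culture conditions (plain media
#' plus AAF stimulations), the drug panel with per-drug concentration grids
#' and roles, replicate structure, the multiplicative noise level and control
#' well counts. The defaults emulate the study design: 5 ovarian cancer cell
#' lines x (media + 5 AAFs) = 30 conditions, 11 drugs (2 standard-of-care +
#' 9 repurposed) on 8-point half-log titrations from 1 uM, 3 technical x 2
#' biological replicates.
#'
#' @param cell_lines character vector of cell line labels.
#' @param media_conditions character vector; the first entry is plain media,
#'   the rest AAF labels.
#' @param drugs data frame with columns `name`, `role`
#'   (`standard_of_care`/`novel`); per-drug grids in `grids` (named list of
#'   molar vectors, strictly positive and increasing).
#' @param grids named list of concentration grids, one per drug.
#' @param replicates_technical,replicates_biological replicate counts (>= 1).
#' @param noise_cv multiplicative coefficient of variation of the raw signal
#'   (>= 0); the log-normal sigma is `sqrt(log(1 + cv^2))`.
#' @param control_counts named vector of wells per plate for roles
#'   `neg_control`, `pos_control`, `vehicle_high`, `vehicle_low`.
#' @param nominal_rfu plate-reader signal of a fully viable well at unit gain.
#' @param seed integer seed; a fixed seed makes generation byte-identical.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(
    cell_lines = c("SKOV3", "OVCAR3", "OVCAR5", "OVCAR8", "NCI"),
    media_conditions = c("media", "A1", "A9", "A16", "A18", "A19"),
    drugs = data.frame(
      name = c("carboplatin", "paclitaxel", "rapamycin", "niclosamide",
               "fludarabine", "ruxolitinib", "acetylcysteine", "idelalisib",
               "trametinib", "nilotinib", "WP1066"),
      role = c("standard_of_care", "standard_of_care",
               rep("novel", 9))),
    grids = NULL,
    replicates_technical = 3,
    replicates_biological = 2,
    noise_cv = 0.05,
    control_counts = c(neg_control = 16, pos_control = 16,
                       vehicle_high = 8, vehicle_low = 8),
    nominal_rfu = 1e4,
    seed = 1L) {
  if (is.null(grids)) {
    grids <- stats::setNames(
      replicate(nrow(drugs), half_log_grid(), simplify = FALSE), drugs$name)
  }
  stopifnot(
    replicates_technical >= 1, replicates_biological >= 1, noise_cv >= 0,
    all(drugs$name %in% names(grids)))
  for (g in grids) {
    stopifnot(all(g > 0), all(diff(g) > 0))
  }
  structure(list(
    cell_lines = cell_lines, media_conditions = media_conditions,
    drugs = drugs, grids = grids,
    replicates_technical = as.integer(replicates_technical),
    replicates_biological = as.integer(replicates_biological),
    noise_cv = noise_cv, control_counts = control_counts,
    nominal_rfu = nominal_rfu, seed = as.integer(seed)
  ), class = "screen_config")
}

#' Read a screen configuration from a YAML file
#'
#' Schema: top-level keys matching the arguments of [screen_config()];
#' `drugs` as a list of `{name, role}` records, `grids` as a map from drug
#' name to a numeric vector of molar concentrations.
#'
#' @param path YAML file path.
#' @return a [screen_config()] object.
#' @export
read_screen_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_screen_config requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$drugs)) {
    cfg$drugs <- do.call(rbind, lapply(cfg$drugs, as.data.frame))
  }
  if (!is.null(cfg$grids)) cfg$grids <- lapply(cfg$grids, as.numeric)
  if (!is.null(cfg$control_counts)) {
    cfg$control_counts <- unlist(cfg$control_counts)
  }
  do.call(screen_config, cfg)
}

#' Synthetic ground truth for a screen
#'
#' Draws true LL4 parameters per (cell line, drug), AAF-induced resistance
#' per (cell line, AAF condition), and optional pairwise interaction terms.
#' The true `d` is the drug's maximal percent inhibition (efficacy; see
#' [expected_viability()]). Resistance acts phenomenologically at the curve
#' level: the midpoint is multiplied by `resistance_shift` and the efficacy
#' reduced by `efficacy_loss` (floored at 0), which raises the high-dose
#' viability floor. The magnitudes of AAF-induced shifts are free parameters
#' of the generator, drawn from the ranges given here.
#'
#' @param config a [screen_config()].
#' @param e_quantile_range midpoints are drawn log-uniformly between these
#'   quantiles of each drug's grid span.
#' @param b_range,d_range uniform ranges for true slope and maximal percent
#'   inhibition.
#' @param resistance_shift_range log-uniform range of the AAF midpoint
#'   multiplier (>= 1 shifts toward resistance).
#' @param efficacy_loss_range uniform range of the AAF top-asymptote
#'   reduction, percentage points.
#' @param epsilon constant Bliss-interaction term on the [0,1] inhibition
#'   scale applied to every drug pair (default 0 = independence); must lie in
#'   [-1, 1].
#' @param seed integer; defaults to `config$seed`.
#' @return object of class `truth_set`: list with `curves` (cell_line, drug,
#'   b, c, d, e), `shifts` (cell_line, condition, resistance_shift,
#'   efficacy_loss; media rows are identity), `epsilon`, `seed`.
#' @export
truth_set <- function(config,
                      e_quantile_range = c(0.25, 0.75),
                      b_range = c(0.8, 2),
                      d_range = c(85, 100),
                      resistance_shift_range = c(1, 4),
                      efficacy_loss_range = c(0, 20),
                      epsilon = 0,
                      seed = config$seed) {
  stopifnot(inherits(config, "screen_config"),
            epsilon >= -1, epsilon <= 1)
  with_seed(seed, {
    curves <- expand.grid(cell_line = config$cell_lines,
                          drug = config$drugs$name,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    lo <- vapply(config$grids[curves$drug], function(g) {
      stats::quantile(log10(g), e_quantile_range[1])
    }, numeric(1))
    hi <- vapply(config$grids[curves$drug], function(g) {
      stats::quantile(log10(g), e_quantile_range[2])
    }, numeric(1))
    n <- nrow(curves)
    curves$b <- stats::runif(n, b_range[1], b_range[2])
    curves$c <- 0
    curves$d <- stats::runif(n, d_range[1], d_range[2])
    curves$e <- 10^stats::runif(n, lo, hi)

    aafs <- setdiff(config$media_conditions, config$media_conditions[1])
    shifts <- expand.grid(cell_line = config$cell_lines,
                          condition = aafs,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    m <- nrow(shifts)
    shifts$resistance_shift <-
      10^stats::runif(m, log10(resistance_shift_range[1]),
                      log10(resistance_shift_range[2]))
    shifts$efficacy_loss <- stats::runif(m, efficacy_loss_range[1],
                                         efficacy_loss_range[2])
    media <- data.frame(cell_line = config$cell_lines,
                        condition = config$media_conditions[1],
                        resistance_shift = 1, efficacy_loss = 0)
    shifts <- rbind(media, shifts)

    structure(list(curves = curves, shifts = shifts,
                   epsilon = epsilon, seed = as.integer(seed)),
              class = "truth_set")
  })
}

#' Inject a resistance scenario into a truth set
#'
#' Overrides the resistance entries of one condition across all cell lines —
#' used to emulate an ascites sample that induces near-complete
#' chemoresistance (large midpoint shift plus top-asymptote loss).
#'
#' @param truth a [truth_set()].
#' @param condition condition label to override.
#' @param resistance_shift,efficacy_loss values to set.
#' @return the modified truth set.
#' @export
set_condition_resistance <- function(truth, condition,
                                     resistance_shift, efficacy_loss) {
  i <- truth$shifts$condition == condition
  if (!any(i)) stop("set_condition_resistance: unknown condition ", condition)
  truth$shifts$resistance_shift[i] <- resistance_shift
  truth$shifts$efficacy_loss[i] <- efficacy_loss
  truth
}

#' Look up condition-adjusted true curve parameters
#'
#' @param truth a [truth_set()].
#' @param cell_line,drug,condition labels.
#' @return list with `b`, `c`, `d` (maximal percent inhibition), `e` after
#'   applying the condition's resistance shift and efficacy loss.
#' @export
truth_params <- function(truth, cell_line, drug, condition) {
  cv <- truth$curves[truth$curves$cell_line == cell_line &
                       truth$curves$drug == drug, ]
  if (nrow(cv) != 1) {
    stop("truth_params: no truth entry for cell line '", cell_line,
         "' and drug '", drug, "'")
  }
  sh <- truth$shifts[truth$shifts$cell_line == cell_line &
                       truth$shifts$condition == condition, ]
  if (nrow(sh) != 1) {
    stop("truth_params: no resistance entry for cell line '", cell_line,
         "' and condition '", condition, "'")
  }
  list(b = cv$b, c = cv$c,
       d = max(0, cv$d - sh$efficacy_loss),
       e = cv$e * sh$resistance_shift)
}

#' Expected percent viability under true curve parameters
#'
#' The generator's truth is parameterized by drug efficacy: `d` is the
#' maximal percent inhibition the drug can reach (the high-dose viability
#' floor is `100 - d`), `e` the midpoint dose of the inhibition rise and `b`
#' its slope. Untreated cells are fully viable, so expected viability is
#' `100 - d / (1 + (e/x)^b)` for dose `x > 0` and `100` at zero dose —
#' an LL4 viability curve with upper asymptote 100 and lower asymptote
#' `100 - d`. AAF-induced efficacy loss subtracts from `d`, raising the
#' floor: the "consistent viability at high drug dose" resistance pattern.
#'
#' @param pars list with `b`, `c`, `d`, `e` (from [truth_params()]).
#' @param conc molar dose vector (zero allowed).
#' @return expected percent viability.
#' @export
expected_viability <- function(pars, conc) {
  ifelse(conc > 0,
         ll4(conc, pars$b, 100 - (pars$d - pars$c), 100, pars$e),
         100)
}

#' Generate a synthetic viability screen
#'
#' Lays out one 384-well plate per (cell line, condition, biological
#' replicate): every drug's titration in `replicates_technical` technical
#' replicates plus negative controls (untreated, full viability), positive
#' controls (full kill), and vehicle-gradient wells at the high and low DMSO
#' percentages. The raw signal model is
#' `rfu = plate_gain * viability_fraction * exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + noise_cv^2))`; the plate gain is drawn once per
#' plate, uniform in `[0.8, 1.2]` times the nominal signal. Biological
#' replicates perturb the true midpoint by an independent 5%-CV log-normal
#' factor (passage effects); technical replicates share the truth. The exact
#' expected percent viability of every well (noise-free, after perturbation)
#' is returned alongside the raw signal.
#'
#' @param config a [screen_config()].
#' @param truth a matching [truth_set()].
#' @param bio_e_cv CV of the per-biological-replicate midpoint perturbation
#'   (default 0.05; set 0 to disable).
#' @return data frame of wells: `plate_id`, `well`, `row`, `col`,
#'   `cell_line`, `condition`, `drug1`, `conc1_M`, `drug2`, `conc2_M`,
#'   `role`, `rfu`, `bio_rep`, `tech_rep`, `expected_viability_pct`,
#'   `plate_gain`.
#' @export
generate_screen <- function(config, truth, bio_e_cv = 0.05) {
  stopifnot(inherits(config, "screen_config"), inherits(truth, "truth_set"))
  missing_drugs <- setdiff(config$drugs$name, unique(truth$curves$drug))
  missing_cl <- setdiff(config$cell_lines, unique(truth$curves$cell_line))
  if (length(missing_drugs) || length(missing_cl)) {
    stop("generate_screen: truth set lacks entries for ",
         paste(c(missing_drugs, missing_cl), collapse = ", "))
  }
  sigma <- sqrt(log(1 + config$noise_cv^2))
  with_seed(config$seed, {
    plates <- expand.grid(cell_line = config$cell_lines,
                          condition = config$media_conditions,
                          bio_rep = seq_len(config$replicates_biological),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    out <- vector("list", nrow(plates))
    for (i in seq_len(nrow(plates))) {
      cl <- plates$cell_line[i]; cond <- plates$condition[i]
      br <- plates$bio_rep[i]
      plate_id <- sprintf("P_%s_%s_b%d", cl, cond, br)
      gain <- config$nominal_rfu * stats::runif(1, 0.8, 1.2)

      rows <- list()
      for (dg in config$drugs$name) {
        pars <- truth_params(truth, cl, dg, cond)
        if (bio_e_cv > 0) {
          pars$e <- pars$e * exp(stats::rnorm(
            1, 0, sqrt(log(1 + bio_e_cv^2))))
        }
        grid <- config$grids[[dg]]
        for (tr in seq_len(config$replicates_technical)) {
          ev <- expected_viability(pars, grid)
          rows[[length(rows) + 1]] <- data.frame(
            cell_line = cl, condition = cond,
            drug1 = dg, conc1_M = grid,
            drug2 = "", conc2_M = 0,
            role = "treatment", bio_rep = br, tech_rep = tr,
            expected_viability_pct = ev)
        }
      }
      ctrl <- config$control_counts
      ctrl_v <- c(neg_control = 100, pos_control = 0,
                  vehicle_high = 100, vehicle_low = 100)
      for (role in names(ctrl)) {
        if (ctrl[[role]] < 1) next
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = cl, condition = cond,
          drug1 = "", conc1_M = 0, drug2 = "", conc2_M = 0,
          role = role, bio_rep = br,
          tech_rep = seq_len(ctrl[[role]]),
          expected_viability_pct = ctrl_v[[role]])
      }
      w <- do.call(rbind, rows)
      w$plate_id <- plate_id
      w$plate_gain <- gain
      n <- nrow(w)
      if (n > 384) stop("generate_screen: plate layout exceeds 384 wells")
      w$row <- LETTERS[(seq_len(n) - 1) %/% 24 + 1]
      w$col <- (seq_len(n) - 1) %% 24 + 1
      w$well <- paste0(w$row, sprintf("%02d", w$col))
      noise <- if (sigma > 0) exp(stats::rnorm(n, 0, sigma)) else rep(1, n)
      w$rfu <- gain * (w$expected_viability_pct / 100) * noise
      out[[i]] <- w
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    cols <- c("plate_id", "well", "row", "col", "cell_line", "condition",
              "drug1", "conc1_M", "drug2", "conc2_M", "role", "rfu",
              "bio_rep", "tech_rep", "expected_viability_pct", "plate_gain")
    res[, cols]
  })
}

#' Generate a synthetic drug-combination grid
#'
#' Builds a dose-pair viability matrix with known interaction. The noiseless
#' expected inhibition fraction at dose pair `(x1, x2)` is the Bliss form
#' `y1 + y2 - y1 y2 + epsilon * [x1 > 0 & x2 > 0]`, clipped to `[0, 1]`,
#' where `y1`, `y2` are the condition-adjusted true monotherapy inhibition
#' fractions; `epsilon` is constant over the positive-dose region. A
#' `factorial` design crosses two full titrations (each with a zero-dose
#' level); an `anchored` design holds drug A at a single positive priming
#' dose and titrates drug B.
#'
#' @param truth a [truth_set()].
#' @param cell_line,condition labels present in the truth set.
#' @param drugA,drugB drug labels; in anchored designs drug A is the priming
#'   drug.
#' @param concA,concB molar dose vectors (zero levels added if absent; an
#'   anchored design requires exactly one positive `concA`).
#' @param design `"factorial"` or `"anchored"`.
#' @param epsilon interaction term on the inhibition-fraction scale; defaults
#'   to the truth set's.
#' @param noise_cv multiplicative CV applied to the viability signal
#'   (default 0 = noiseless).
#' @param n_replicates replicate grids averaged into the viability matrix.
#' @param seed integer seed for the noise draws.
#' @return object of class `combination_grid`: list with `drugA`, `drugB`,
#'   `concA`, `concB` (including zero), `viability` (% matrix, concA rows x
#'   concB columns, mean over replicates), `expected` (noise-free % matrix),
#'   `design`, `epsilon`, `marginalA`/`marginalB` true parameter lists.
#' @export
generate_combination_grid <- function(truth, cell_line, condition,
                                      drugA, drugB, concA, concB,
                                      design = c("factorial", "anchored"),
                                      epsilon = truth$epsilon,
                                      noise_cv = 0, n_replicates = 1,
                                      seed = truth$seed) {
  design <- match.arg(design)
  parsA <- truth_params(truth, cell_line, drugA, condition)
  parsB <- truth_params(truth, cell_line, drugB, condition)
  concA <- sort(unique(c(0, concA)))
  concB <- sort(unique(c(0, concB)))
  if (design == "anchored" && sum(concA > 0) != 1) {
    stop("generate_combination_grid: anchored design needs exactly one ",
         "positive priming dose for drug A")
  }
  if (design == "factorial" && (sum(concA > 0) < 2 || sum(concB > 0) < 2)) {
    stop("generate_combination_grid: factorial design needs >= 2 positive ",
         "levels per drug")
  }
  inh <- function(pars, x) {
    ifelse(x > 0, 1 - expected_viability(pars, x) / 100, 0)
  }
  y1 <- inh(parsA, concA)
  y2 <- inh(parsB, concB)
  yz <- outer(y1, y2, function(a, b) a + b - a * b)
  on_region <- outer(concA > 0, concB > 0, "&")
  y_exp <- matrix(pmin(1, pmax(0, yz + epsilon * on_region)),
                  nrow = length(concA))
  expected <- 100 * (1 - y_exp)
  sigma <- sqrt(log(1 + noise_cv^2))
  viab <- with_seed(seed, {
    reps <- replicate(n_replicates, {
      if (sigma > 0) {
        expected * exp(matrix(stats::rnorm(length(expected), 0, sigma),
                              nrow = nrow(expected)))
      } else expected
    }, simplify = FALSE)
    Reduce(`+`, reps) / n_replicates
  })
  dimnames(viab) <- dimnames(expected) <-
    list(format(concA, digits = 6), format(concB, digits = 6))
  structure(list(
    drugA = drugA, drugB = drugB, concA = concA, concB = concB,
    viability = viab, expected = expected, design = design,
    epsilon = epsilon, cell_line = cell_line, condition = condition,
    marginalA = parsA, marginalB = parsB,
    n_replicates = n_replicates, noise_cv = noise_cv
  ), class = "combination_grid")
}

#' Default phospho-marker panel (31 targets)
#' @return character vector of marker labels.
#' @export
default_markers <- function() {
  c("STAT3_pY705", "STAT1_pY701", "STAT1_pS727", "STAT5_pY694",
    "STAT6_pY641", "JAK2_pY1007", "S6RP_pS235_236", "AKT_pT308",
    "AKT_pS473", "NFkB_pS529", "NFkB_pS536", "MAPKAPK2_pT334",
    "p38MAPK_pT180_Y182", "SAPK_JNK_pT183_Y185", "ATF2_pT71",
    "MEK1_pS298", "ERK1_2_pT202_Y204", "CDC2_pT161", "HistoneH3_pS10",
    "VAV_pY174", "GSK3A_pS21", "GSK3B_pS9", "RB_pS807_811",
    "mTOR_pS2448", "PLCg2_pY759", "SRC_pY418", "CREB_pS133",
    "RSK_pS380", "BTK_pY223", "PTEN_pS380", "WNK1_pT60")
}

#' Ground truth for a phospho-marker table
#'
#' @param markers marker labels (default the 31-target panel).
#' @param mean_fc named numeric: true mean log2 fold-change vs the
#'   unstimulated control per marker (unnamed markers default to 0).
#' @param sd per-marker SD of the log2 fold-change (recycled).
#' @param cor_targets data frame `(marker_i, marker_j, rho)` of target
#'   pairwise Pearson correlations (|rho| <= 1); unspecified pairs are
#'   uncorrelated. The implied correlation matrix must be positive
#'   semi-definite.
#' @param igg_base median fluorescence of the IgG control.
#' @param seed integer.
#' @return object of class `marker_truth`.
#' @export
marker_truth <- function(markers = default_markers(),
                         mean_fc = NULL, sd = 0.5,
                         cor_targets = NULL, igg_base = 100, seed = 1L) {
  fc <- stats::setNames(rep(0, length(markers)), markers)
  if (!is.null(mean_fc)) fc[names(mean_fc)] <- mean_fc
  sd <- stats::setNames(rep_len(sd, length(markers)), markers)
  if (!is.null(cor_targets)) {
    stopifnot(all(abs(cor_targets$rho) <= 1),
              all(cor_targets$marker_i %in% markers),
              all(cor_targets$marker_j %in% markers))
  }
  structure(list(markers = markers, mean_fc = fc, sd = sd,
                 cor_targets = cor_targets, igg_base = igg_base,
                 seed = as.integer(seed)),
            class = "marker_truth")
}

# correlation matrix implied by the targets, zero-filled; errors when the
# zero-completion is not positive semi-definite
marker_sigma <- function(mtruth) {
  p <- length(mtruth$markers)
  R <- diag(p)
  dimnames(R) <- list(mtruth$markers, mtruth$markers)
  ct <- mtruth$cor_targets
  if (!is.null(ct)) {
    for (k in seq_len(nrow(ct))) {
      R[ct$marker_i[k], ct$marker_j[k]] <- ct$rho[k]
      R[ct$marker_j[k], ct$marker_i[k]] <- ct$rho[k]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("marker_truth: correlation targets are infeasible ",
         "(zero-completed matrix is not positive semi-definite)")
  }
  R
}

#' Generate a synthetic phospho-marker median-fluorescence table
#'
#' Draws `n_samples` stimulation rows of per-marker median fluorescence whose
#' log2 fold-changes vs the IgG control follow a multivariate normal with the
#' truth's means, SDs and pairwise correlation targets; sample correlations
#' converge to the targets as `n_samples` grows. The table carries an IgG
#' control column and an unstimulated control row (zero fold-change). Tables
#' with fewer than 10 samples are flagged (attribute
#' `correlation_unreliable`) since correlation recovery is then unstable.
#'
#' @param mtruth a [marker_truth()].
#' @param n_samples number of stimulation rows (>= 3).
#' @return data frame, rows = `control` plus stimulations, columns = markers
#'   plus `IgG`, values = median fluorescence.
#' @export
generate_marker_table <- function(mtruth, n_samples) {
  stopifnot(inherits(mtruth, "marker_truth"), n_samples >= 3)
  R <- marker_sigma(mtruth)  # errors before any sampling when infeasible
  p <- length(mtruth$markers)
  with_seed(mtruth$seed, {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(0, ev$values)), p)
    Z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% t(L)
    fc <- sweep(sweep(Z, 2, mtruth$sd, `*`), 2, mtruth$mean_fc, `+`)
    igg <- mtruth$igg_base * exp(stats::rnorm(n_samples + 1, 0, 0.02))
    med <- igg[-1] * 2^fc
    # control row first: unstimulated, zero fold-change by construction
    tab <- rbind(igg[1], as.data.frame(med))
    tab <- stats::setNames(tab, mtruth$markers)
    tab$IgG <- igg
    rownames(tab) <- c("control", paste0("AAF_", seq_len(n_samples)))
    if (n_samples < 10) {
      warning("generate_marker_table: fewer than 10 samples; ",
              "correlation recovery is unreliable")
      attr(tab, "correlation_unreliable") <- TRUE
    } else {
      attr(tab, "correlation_unreliable") <- FALSE
    }
    tab
  })
}

#' Write / read the long-format plate CSV
#'
#' The on-disk schema is the exchange format of the pipeline: columns
#' `plate_id, well, row, col, cell_line, condition, drug1, conc1_M, drug2,
#' conc2_M, role, rfu`. Extra columns (ground truth, replicate ids) are
#' written by [write_truth_csv()] instead.
#'
#' @param wells data frame from [generate_screen()] (or matching schema).
#' @param path file path.
#' @return `path`, invisibly (`read_plate_csv` returns the data frame).
#' @export
write_plate_csv <- function(wells, path) {
  cols <- c("plate_id", "well", "row", "col", "cell_line", "condition",
            "drug1", "conc1_M", "drug2", "conc2_M", "role", "rfu")
  utils::write.csv(wells[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(conc1_M = "numeric", conc2_M = "numeric",
                                 rfu = "numeric"))
}

#' @rdname write_plate_csv
#' @export
write_truth_csv <- function(wells, path) {
  cols <- c("plate_id", "well", "cell_line", "condition", "drug1", "conc1_M",
            "bio_rep", "tech_rep", "expected_viability_pct", "plate_gain")
  utils::write.csv(wells[, intersect(cols, names(wells))], path,
                   row.names = FALSE)
  invisible(path)
}
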