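#' Combination Ratio
#'
#' Compares a combination's drug sensitivity score to the monotherapy score
#' of its comparator (the priming standard-of-care drug in the same
#' condition): `CR = (DSS_combo + 100) / (DSS_mono + 100)`. Both scores are
#' augmented by 100 so the ratio stays defined and finite when either score
#' is zero; with DSS in [0, 100] the CR is bounded in [0.5, 2]. CR > 1 means
#' the combination improves on the monotherapy.
#'
#' @param dss_combo,dss_mono DSS values in [0, 100] (or [dss()] results).
#' @param condition,combo,mono optional labels carried into the record.
#' @return data frame with `condition`, `combo`, `mono`, `dss_combo`,
#'   `dss_mono`, `cr`.
#' @examples
#' combination_ratio(50, 0)$cr  # 1.5
#' @export
combination_ratio <- function(dss_combo, dss_mono, condition = NA_character_,
                              combo = NA_character_, mono = NA_character_) {
  if (inherits(dss_combo, "dss_result")) dss_combo <- dss_combo$dss
  if (inherits(dss_mono, "dss_result")) dss_mono <- dss_mono$dss
  stopifnot(all(dss_combo >= 0 & dss_combo <= 100),
            all(dss_mono >= 0 & dss_mono <= 100))
  data.frame(condition = condition, combo = combo, mono = mono,
             dss_combo = dss_combo, dss_mono = dss_mono,
             cr = (dss_combo + 100) / (dss_mono + 100))
}

# composite trapezoid rule
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Volume-under-the-surface score (100 - VUS)
#'
#' Summarizes a dose-pair viability surface as the complement of its
#' normalized volume. The surface is integrated by the iterated trapezoid
#' rule along the two log10-molar dose axes (positive doses only; the log of
#' a zero dose is undefined, so zero-dose rows/columns anchor the marginals
#' but not the integration bounds) and divided by the volume of the enclosing
#' cube, `100 x` the product of the axis spans. High viability gives a large
#' VUS, so the reported score `100 - VUS` reads as efficacy: 0 for a fully
#' viable surface, 100 for a complete kill. Anchored grids, which have a
#' single positive level of the priming drug, are scored by the 1D AUC
#' analogue along the titrated drug.
#'
#' @param grid a [`combination_grid`][generate_combination_grid], or any list
#'   with `concA`, `concB`, `viability`, `design`.
#' @return object of class `vus_result`: list with `vus`, `score`
#'   (`= 100 - vus`, clamped to [0, 100]) and `design`.
#' @export
vus <- function(grid) {
  cA <- grid$concA; cB <- grid$concB
  V <- grid$viability
  iA <- which(cA > 0); iB <- which(cB > 0)
  uB <- log10(cB[iB])
  if (length(iB) < 2) stop("vus: need >= 2 positive levels of drug B")
  if (identical(grid$design, "anchored") || length(iA) == 1) {
    if (length(iA) != 1) {
      stop("vus: anchored scoring expects exactly one positive priming dose")
    }
    v <- V[iA, iB]
    vol <- trapz(uB, v) / (100 * diff(range(uB)))
  } else {
    if (length(iA) < 2) {
      stop("vus: factorial scoring needs >= 2 positive levels per axis; ",
           "use the anchored (1D) mode")
    }
    uA <- log10(cA[iA])
    rowint <- vapply(iA, function(i) trapz(uB, V[i, iB]), numeric(1))
    vol <- trapz(uA, rowint) /
      (100 * diff(range(uA)) * diff(range(uB)))
  }
  score <- 100 * (1 - vol)
  structure(list(vus = 100 * vol,
                 score = min(100, max(0, score)),
                 design = grid$design),
            class = "vus_result")
}

#' Synergy and improvement calls for combination screens
#'
#' Applies the two decision rules used to annotate combination heatmaps:
#' a combination is called synergistic when its ZIP summary delta exceeds the
#' empirical 95th percentile of all ZIP summaries in its reference population
#' (all combinations sharing a standard-of-care backbone, across every
#' ascites/cell-line condition), and flagged as a non-improvement when its
#' Combination Ratio falls strictly below 0.75.
#'
#' @param scores data frame with columns `population` (reference drug),
#'   `id` (combination/condition identifier), `zip` (summary delta) and
#'   optionally `cr`.
#' @param probs percentile defining synergy (default 0.95); quantiles use
#'   linear interpolation between order statistics (type 7).
#' @param cr_cutoff non-improvement threshold on CR (default 0.75, strict).
#' @param min_n populations smaller than this get `threshold_unstable = TRUE`
#'   (default 20).
#' @return `scores` with `threshold`, `synergistic`, `improvement_flag`
#'   (`FALSE` when `cr < cr_cutoff`) and `threshold_unstable` appended.
#' @export
synergy_call <- function(scores, probs = 0.95, cr_cutoff = 0.75,
                         min_n = 20) {
  stopifnot(all(c("population", "zip") %in% names(scores)),
            nrow(scores) > 0)
  out <- lapply(split(scores, scores$population), function(s) {
    thr <- stats::quantile(s$zip, probs, type = 7, names = FALSE)
    s$threshold <- thr
    s$synergistic <- s$zip > thr
    s$threshold_unstable <- nrow(s) < min_n
    s
  })
  out <- do.call(rbind, out)
  if ("cr" %in% names(out)) {
    out$improvement_flag <- !(out$cr < cr_cutoff)
  }
  rownames(out) <- NULL
  out
}

#' Rank treatments within a condition
#'
#' Descending sort on the chosen criterion (CR for combinations, DSS for
#' monotherapies) with deterministic tie-breaks: (1) higher DSS, (2) fewer
#' drugs in the treatment, (3) lexicographic treatment label. The rank-1
#' entry per condition is the nominated best treatment.
#'
#' @param scores data frame with columns `condition`, `treatment`, the
#'   criterion column, and optionally `dss` and `n_drugs` for tie-breaks.
#' @param criterion name of the criterion column, `"cr"` or `"dss"`.
#' @return `scores` with `rank` appended, ordered by condition then rank.
#' @export
rank_treatments <- function(scores, criterion = c("cr", "dss")) {
  criterion <- match.arg(criterion)
  stopifnot(all(c("condition", "treatment", criterion) %in% names(scores)))
  dss_tb <- if ("dss" %in% names(scores)) scores$dss else rep(0, nrow(scores))
  nd_tb <- if ("n_drugs" %in% names(scores)) scores$n_drugs else
    rep(1L, nrow(scores))
  out <- lapply(split(seq_len(nrow(scores)), scores$condition), function(ix) {
    o <- ix[order(-scores[[criterion]][ix], -dss_tb[ix], nd_tb[ix],
                  scores$treatment[ix])]
    s <- scores[o, , drop = FALSE]
    s$rank <- seq_along(o)
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Best-treatment table
#'
#' The rank-1 treatment per condition from [rank_treatments()].
#'
#' @inheritParams rank_treatments
#' @return one row per condition: `condition`, `treatment`, criterion value.
#' @export
best_treatments <- function(scores, criterion = c("cr", "dss")) {
  ranked <- rank_treatments(scores, criterion)
  out <- ranked[ranked$rank == 1,
                c("condition", "treatment", match.arg(criterion))]
  rownames(out) <- NULL
  out
}
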