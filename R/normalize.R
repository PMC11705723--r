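#' Control-based normalization of raw signal to percent viability
#'
#' Per plate, raw luminescence is mapped to relative percent viability by the
#' negative (untreated, 100%) and positive (full kill, 0%) control wells:
#' `viability_pct = 100 (rfu - mu_pos) / (mu_neg - mu_pos)`. The mapping is
#' affine, so any plate-wide gain rescaling cancels. Values are not clipped by
#' default: over-100% or negative readings carry information for curve
#' fitting, whose lower bound is imposed by the model instead. An optional
#' guard clips to `[0, 150]` and flags clipped wells as gross outliers.
#'
#' @param wells long-format well table with columns `plate_id`, `role`, `rfu`
#'   plus treatment annotation columns, which are carried through.
#' @param clip apply the `[0, 150]` guard (default `FALSE`).
#' @return the treatment rows of `wells` with columns `viability_pct` (and
#'   `clipped` when `clip = TRUE`) appended.
#' @export
normalize_controls <- function(wells, clip = FALSE) {
  stopifnot(all(c("plate_id", "role", "rfu") %in% names(wells)))
  out <- lapply(unique(wells$plate_id), function(p) {
    w <- wells[wells$plate_id == p, ]
    neg <- w$rfu[w$role == "neg_control"]
    pos <- w$rfu[w$role == "pos_control"]
    if (length(neg) < 1 || length(pos) < 1) {
      stop("normalize_controls: plate ", p, " is missing a control role")
    }
    mu_n <- mean(neg); mu_p <- mean(pos)
    if (mu_n == mu_p) stop("normalize_controls: degenerate controls on plate ", p)
    tr <- w[w$role == "treatment", , drop = FALSE]
    tr$viability_pct <- 100 * (tr$rfu - mu_p) / (mu_n - mu_p)
    tr
  })
  out <- do.call(rbind, out)
  if (clip) {
    out$clipped <- out$viability_pct < 0 | out$viability_pct > 150
    out$viability_pct <- pmin(150, pmax(0, out$viability_pct))
  }
  rownames(out) <- NULL
  out
}

#' Vehicle-based normalization of raw signal to percent viability
#'
#' For DMSO-dissolved drugs the zero-dose ("0 M") reference of a plate is
#' built from the vehicle gradient wells. Two readings of the reference are
#' supported: `"mean_of_means"` (default) averages the mean RFU of the
#' high-DMSO wells and the mean RFU of the low-DMSO wells;
#' `"grand_mean"` pools all vehicle wells. Each well's relative viability is
#' `100 * rfu / reference`. Water-solvent drugs carry no vehicle gradient and
#' their reference ratio is 1 (100% viability at zero dose); for these the
#' negative-control mean is used as the reference signal.
#'
#' @param wells long-format well table; roles `vehicle_high` / `vehicle_low`
#'   define the reference (or `neg_control` for water-solvent plates).
#' @param reference `"mean_of_means"` or `"grand_mean"`.
#' @param water_solvent treat the plate's drug as water-dissolved: no vehicle
#'   wells required (default `FALSE`).
#' @return treatment rows with `viability_pct` appended.
#' @export
normalize_vehicle <- function(wells,
                              reference = c("mean_of_means", "grand_mean"),
                              water_solvent = FALSE) {
  reference <- match.arg(reference)
  stopifnot(all(c("plate_id", "role", "rfu") %in% names(wells)))
  out <- lapply(unique(wells$plate_id), function(p) {
    w <- wells[wells$plate_id == p, ]
    hi <- w$rfu[w$role == "vehicle_high"]
    lo <- w$rfu[w$role == "vehicle_low"]
    ref <- if (water_solvent) {
      neg <- w$rfu[w$role %in% c("neg_control", "vehicle_high", "vehicle_low")]
      if (length(neg) < 1) {
        stop("normalize_vehicle: plate ", p, " has no untreated wells")
      }
      mean(neg)
    } else if (length(hi) >= 1 && length(lo) >= 1) {
      if (reference == "mean_of_means") mean(c(mean(hi), mean(lo)))
      else mean(c(hi, lo))
    } else {
      stop("normalize_vehicle: plate ", p,
           " lacks vehicle_high/vehicle_low wells for a DMSO-dissolved drug")
    }
    tr <- w[w$role == "treatment", , drop = FALSE]
    tr$viability_pct <- 100 * tr$rfu / ref
    tr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate replicate viability points
#'
#' Mean viability per (cell line, condition, drug pair, dose pair) with the
#' replicate SD and count attached; single replicates pass through with
#' `n = 1` and `sd = NA`.
#'
#' @param points data frame with `viability_pct` and the grouping columns
#'   (any of `cell_line`, `condition`, `drug1`, `drug2`, `conc1_M`, `conc2_M`
#'   that are present are used).
#' @return aggregated data frame with `viability_pct`, `sd`, `n`.
#' @export
aggregate_replicates <- function(points) {
  keys <- intersect(
    c("cell_line", "condition", "drug1", "drug2", "conc1_M", "conc2_M"),
    names(points))
  stopifnot("viability_pct" %in% names(points), length(keys) > 0)
  agg <- stats::aggregate(
    points["viability_pct"], by = points[keys],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  m <- agg$viability_pct
  agg$viability_pct <- m[, "mean"]
  agg$sd <- m[, "sd"]
  agg$n <- as.integer(m[, "n"])
  agg[order(do.call(paste, agg[keys])), , drop = FALSE]
}
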