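#' Fit curves and score DSS for every (cell line, condition, drug)
#'
#' End-to-end monotherapy analysis of a long-format well table: per-plate
#' control normalization, replicate aggregation, LL4 fitting (lower
#' asymptote fixed at zero) and DSS scoring over each drug's tested window.
#'
#' @param wells long-format well table (see [generate_screen()]).
#' @param t DSS activity threshold (% inhibition).
#' @param variant DSS variant (default 2).
#' @param outlier_removal apply [remove_outliers_and_refit()] when enough
#'   points are available (default `TRUE`).
#' @return data frame: `cell_line`, `condition`, `drug`, LL4 parameters,
#'   `ic20`, `ic50` (NA when not reached), `dss`, `converged`,
#'   `nonresponder`, `outliers_removed`.
#' @export
screen_dss <- function(wells, t = 10, variant = 2, outlier_removal = TRUE) {
  pts <- normalize_controls(wells)
  agg <- aggregate_replicates(
    pts[c("cell_line", "condition", "drug1", "conc1_M", "viability_pct")])
  groups <- unique(agg[c("cell_line", "condition", "drug1")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- agg[agg$cell_line == g$cell_line & agg$condition == g$condition &
                 agg$drug1 == g$drug1, ]
    fit <- if (outlier_removal && nrow(sub) >= 6) {
      remove_outliers_and_refit(sub$conc1_M, sub$viability_pct)
    } else {
      fit_ll4(sub$conc1_M, sub$viability_pct)
    }
    ic <- function(p) {
      if (!fit$converged) return(NA_real_)
      tryCatch(ic_p(fit, p), error = function(e) NA_real_)
    }
    sc <- if (fit$converged) dss(fit, t = t, variant = variant)$dss
    else NA_real_
    data.frame(cell_line = g$cell_line, condition = g$condition,
               drug = g$drug1, b = fit$b, c = fit$c, d = fit$d, e = fit$e,
               ic20 = ic(20), ic50 = ic(50), dss = sc,
               converged = fit$converged,
               nonresponder = isTRUE(fit$nonresponder),
               outliers_removed = fit$outliers_removed)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Heatmap-ready wide DSS matrix
#'
#' @param dss_df output of [screen_dss()].
#' @return matrix, rows = `cellline.condition`, columns = drugs.
#' @export
dss_wide <- function(dss_df) {
  rowid <- paste(dss_df$cell_line, dss_df$condition, sep = ".")
  drugs <- unique(dss_df$drug)
  rows <- unique(rowid)
  m <- matrix(NA_real_, length(rows), length(drugs),
              dimnames = list(rows, drugs))
  m[cbind(match(rowid, rows), match(dss_df$drug, drugs))] <- dss_df$dss
  m
}

#' Average IC20 priming dose per (cell line, drug)
#'
#' The anchored combination design holds the standard-of-care priming drug
#' at one fixed dose per cell line: the mean of its per-condition IC20
#' estimates across media and all AAF conditions (conditions where the IC20
#' is not reached are dropped from the mean).
#'
#' @param dss_df output of [screen_dss()] containing `ic20`.
#' @param drug priming drug label.
#' @return named numeric vector of priming doses, one per cell line.
#' @export
priming_ic20 <- function(dss_df, drug) {
  sub <- dss_df[dss_df$drug == drug & is.finite(dss_df$ic20), ]
  if (nrow(sub) == 0) stop("priming_ic20: no finite IC20 for drug ", drug)
  tapply(sub$ic20, sub$cell_line, mean)
}
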