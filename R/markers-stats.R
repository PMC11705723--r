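#' Normalize a phospho-marker table to its IgG control
#'
#' Converts per-sample median fluorescence to fold change over the IgG
#' control of the same sample. The default is the log2 ratio
#' `log2(median / median_IgG)`; an inverse-hyperbolic-sine alternative,
#' `asinh(median / cofactor) - asinh(median_IgG / cofactor)`, is provided
#' for flow-style data where a linear-near-zero transform is preferred. The
#' unstimulated control row is retained for contrasts.
#'
#' @param table data frame, rows = samples (including a control row),
#'   columns = markers plus an `IgG` column of strictly positive medians.
#' @param method `"log2_ratio"` (default) or `"arcsinh"`.
#' @param cofactor arcsinh cofactor (default 5, the usual mass/flow choice).
#' @return data frame of fold changes, same rows, marker columns only.
#' @export
normalize_markers <- function(table, method = c("log2_ratio", "arcsinh"),
                              cofactor = 5) {
  method <- match.arg(method)
  stopifnot("IgG" %in% names(table))
  markers <- setdiff(names(table), "IgG")
  vals <- as.matrix(table[markers])
  igg <- table$IgG
  if (method == "log2_ratio") {
    bad <- which(vals <= 0, arr.ind = TRUE)
    if (any(igg <= 0) || nrow(bad) > 0) {
      cells <- c(
        if (any(igg <= 0)) paste0("IgG row ", which(igg <= 0)),
        if (nrow(bad) > 0) {
          paste0(markers[bad[, 2]], " row ", bad[, 1])
        })
      stop("normalize_markers: nonpositive medians in: ",
           paste(utils::head(cells, 10), collapse = "; "))
    }
    out <- log2(sweep(vals, 1, igg, `/`))
  } else {
    out <- asinh(vals / cofactor) - asinh(igg / cofactor)
  }
  out <- as.data.frame(out)
  rownames(out) <- rownames(table)
  out
}

#' Per-marker tests against the unstimulated control
#'
#' For each marker, a two-sided one-sample t test of the stimulated fold
#' changes against the control row's value (or a paired t test when a matched
#' second table is given), with Holm step-down correction across the marker
#' panel.
#'
#' @param fc fold-change table from [normalize_markers()].
#' @param control_row name or index of the unstimulated control row
#'   (default `"control"`).
#' @param paired optional second fold-change table with matching rows; when
#'   supplied, paired t tests of `fc` vs `paired` are performed instead.
#' @return data frame: `marker`, `mean_diff`, `t`, `df`, `p`, `p_holm`,
#'   `degenerate` (zero-variance flag; such markers report the limit p of 0
#'   for a nonzero mean difference, 1 otherwise).
#' @export
marker_tests <- function(fc, control_row = "control", paired = NULL) {
  if (is.character(control_row)) {
    control_row <- match(control_row, rownames(fc))
  }
  stim <- fc[-control_row, , drop = FALSE]
  if (nrow(stim) < 3) stop("marker_tests: need >= 3 stimulated samples")
  res <- lapply(names(fc), function(mk) {
    x <- stim[[mk]]
    if (!is.null(paired)) {
      y <- paired[-control_row, ][[mk]]
      d <- x - y
    } else {
      d <- x - fc[control_row, mk]
    }
    if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
      data.frame(marker = mk, mean_diff = mean(d),
                 t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 df = length(d) - 1,
                 p = if (mean(d) == 0) 1 else 0,
                 degenerate = TRUE)
    } else {
      tt <- stats::t.test(d)
      data.frame(marker = mk, mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res[c("marker", "mean_diff", "t", "df", "p", "p_holm", "degenerate")]
}

#' Holm-corrected Pearson correlation matrix
#'
#' Pairwise Pearson correlations between marker columns with two-sided
#' p-values from the t transform, Holm-corrected over all unique pairs, and
#' a significance mask at adjusted p < `alpha`. Pairwise-complete
#' observations are used; pairs involving a constant column are undefined
#' and masked with a flag.
#'
#' @param fc fold-change table (samples x markers), >= 4 rows.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return list with matrices `r`, `p`, `p_holm`, logical `significant`, and
#'   `undefined` (constant-column pairs).
#' @export
correlation_matrix <- function(fc, alpha = 0.05) {
  x <- as.matrix(fc)
  stopifnot(nrow(x) >= 4)
  p_mk <- ncol(x)
  r <- stats::cor(x, use = "pairwise.complete.obs")
  pmat <- matrix(NA_real_, p_mk, p_mk, dimnames = dimnames(r))
  und <- matrix(FALSE, p_mk, p_mk, dimnames = dimnames(r))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  praw <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!is.finite(r[i, j])) {
      und[i, j] <- und[j, i] <- TRUE
      praw[k] <- NA_real_
    } else {
      ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
      praw[k] <- ct$p.value
    }
  }
  padj <- rep(NA_real_, length(praw))
  ok <- !is.na(praw)
  padj[ok] <- stats::p.adjust(praw[ok], method = "holm")
  ph <- pmat
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pmat[i, j] <- pmat[j, i] <- praw[k]
    ph[i, j] <- ph[j, i] <- padj[k]
  }
  diag(pmat) <- 0; diag(ph) <- 0
  sig <- !is.na(ph) & ph < alpha
  diag(sig) <- FALSE
  list(r = r, p = pmat, p_holm = ph, significant = sig, undefined = und)
}
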