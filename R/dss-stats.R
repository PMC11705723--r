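#' Two-way ANOVA with Tukey post-hoc tests on a DSS table
#'
#' Models drug sensitivity scores with cell line and culture condition
#' (media/AAF) as crossed factors. The default model is additive with type-II
#' sums of squares — the screen often yields one DSS per condition per drug,
#' leaving no replicates for an interaction term; with replicated scores the
#' full-interaction model can be requested. Tukey HSD pairwise comparisons
#' are reported for the condition factor (AAF vs media and AAF vs AAF), the
#' family-wise-adjusted contrasts used to compare AAF exposure to plain
#' media.
#'
#' @param dss_long data frame with columns `dss`, `cell_line`, `condition`
#'   (>= 2 levels each).
#' @param interaction include the cell line x condition interaction
#'   (requires replicate observations per cell; default `FALSE`).
#' @return list with `anova` (type-II ANOVA table from [car::Anova()]),
#'   `tukey` (data frame of pairwise condition contrasts: `contrast`,
#'   `diff`, `lwr`, `upr`, `p_adj`), `model` (the fitted [stats::aov()]),
#'   and `residual_df`.
#' @export
anova2_tukey <- function(dss_long, interaction = FALSE) {
  stopifnot(all(c("dss", "cell_line", "condition") %in% names(dss_long)))
  d <- dss_long
  d$cell_line <- factor(d$cell_line)
  d$condition <- factor(d$condition)
  if (nlevels(d$cell_line) < 2 || nlevels(d$condition) < 2) {
    stop("anova2_tukey: each factor needs >= 2 levels")
  }
  tab <- table(d$cell_line, d$condition)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("anova2_tukey: empty design cells: ",
         paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  form <- if (interaction) dss ~ cell_line * condition
  else dss ~ cell_line + condition
  fit <- stats::aov(form, data = d)
  an <- car::Anova(fit, type = 2)
  tk <- stats::TukeyHSD(fit, which = "condition")$condition
  tukey <- data.frame(contrast = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  list(anova = an, tukey = tukey, model = fit,
       residual_df = stats::df.residual(fit))
}

#' Ward-D2 hierarchical clustering of a DSS matrix
#'
#' Agglomerative clustering of screen conditions (rows) by their DSS
#' profiles: Euclidean distance, Ward-D2 linkage (squared-distance Ward
#' criterion, as in the heatmap clustering of drug-sensitivity tables).
#' [stats::hclust()] merges are deterministic, breaking ties by lowest
#' observation index. Merge heights and the leaf order are returned for
#' heatmap export, plus a Newick serialization of the dendrogram.
#'
#' @param mat complete numeric matrix (conditions x treatments), >= 2 rows.
#' @return list with `hclust` (the tree), `merge_heights`, `leaf_order`
#'   (labels in dendrogram order), `newick` (text).
#' @export
cluster_ward <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    stop("cluster_ward: matrix has missing values; ",
         "extract a complete-case submatrix first")
  }
  if (nrow(mat) < 2) stop("cluster_ward: need >= 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       merge_heights = hc$height,
       leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Reshape a wide DSS table to long form
#'
#' @param dss_mat matrix or data frame, rows = conditions labelled
#'   `cellline.condition` (separator `sep`), columns = treatments.
#' @param sep separator between cell line and condition in row names.
#' @return long data frame: `cell_line`, `condition`, `treatment`, `dss`.
#' @export
dss_table_long <- function(dss_mat, sep = "\\.") {
  m <- as.matrix(dss_mat)
  parts <- strsplit(rownames(m), sep)
  data.frame(
    cell_line = rep(vapply(parts, `[`, "", 1), ncol(m)),
    condition = rep(vapply(parts, `[`, "", 2), ncol(m)),
    treatment = rep(colnames(m), each = nrow(m)),
    dss = as.vector(m))
}
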