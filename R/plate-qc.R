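#' Z-prime plate quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mu_pos - mu_neg|`, the standard screening
#' window coefficient computed from the raw signal of the negative (untreated,
#' full viability) and positive (full kill) control wells of a plate. Values
#' approach 1 for well-separated, tight controls; plates are conventionally
#' accepted at `Z' >= 0.5`.
#'
#' @param neg_rfu,pos_rfu raw signal in the negative / positive control wells
#'   (each at least 2 values).
#' @return the Z-prime value (always <= 1).
#' @examples
#' z_prime(c(95, 100, 105), c(5, 10, 15))
#' @export
z_prime <- function(neg_rfu, pos_rfu) {
  if (length(neg_rfu) < 2 || length(pos_rfu) < 2) {
    stop("z_prime: need >= 2 wells in each control group")
  }
  mu_n <- mean(neg_rfu); mu_p <- mean(pos_rfu)
  if (mu_n == mu_p) stop("z_prime: control means are equal; unusable plate")
  1 - 3 * (stats::sd(pos_rfu) + stats::sd(neg_rfu)) / abs(mu_p - mu_n)
}

#' Per-plate quality control
#'
#' Computes control statistics and Z-prime for every plate in a long-format
#' well table and flags plates passing the cutoff.
#'
#' @param wells data frame of wells with columns `plate_id`, `role`, `rfu`;
#'   roles `neg_control` and `pos_control` are used.
#' @param cutoff pass threshold on Z-prime (default 0.5, standard HTS
#'   practice).
#' @return data frame with one row per plate: `plate_id`, `mu_neg`, `sd_neg`,
#'   `mu_pos`, `sd_pos`, `z_prime`, `pass_flag`.
#' @export
plate_qc <- function(wells, cutoff = 0.5) {
  stopifnot(all(c("plate_id", "role", "rfu") %in% names(wells)))
  plates <- unique(wells$plate_id)
  out <- lapply(plates, function(p) {
    w <- wells[wells$plate_id == p, ]
    neg <- w$rfu[w$role == "neg_control"]
    pos <- w$rfu[w$role == "pos_control"]
    if (length(neg) < 2 || length(pos) < 2) {
      stop("plate_qc: plate ", p, " lacks >= 2 wells of each control role")
    }
    zp <- z_prime(neg, pos)
    data.frame(plate_id = p,
               mu_neg = mean(neg), sd_neg = stats::sd(neg),
               mu_pos = mean(pos), sd_pos = stats::sd(pos),
               z_prime = zp, pass_flag = zp >= cutoff)
  })
  do.call(rbind, out)
}
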