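#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the mean-squares decomposition of a subjects x repeats matrix:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' where `MS_R`, `MS_C`, `MS_E` are the row (subject), column (repeat) and
#' residual mean squares, `n` subjects and `k` repeats. Used to quantify
#' the repeatability of manual landmark identification; values near 1 mean
#' the rater's repeats agree strongly.
#'
#' @param measurements Numeric matrix, subjects in rows, repeats/raters in
#'   columns; no missing cells.
#' @return ICC value in `[0, 1]` (negative estimates clipped at 0).
#' @export
icc_repeatability <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("missing cells in the repeatability matrix (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 repeats")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_e == 0 && ms_c == 0) return(if (ms_r > 0) 1 else 0)
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  max(0, min(1, icc))
}
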