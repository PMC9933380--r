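## Method-comparison statistics: Bland-Altman bias and 95% limits of
## agreement, Pearson correlation, two-way mixed absolute-agreement ICC, and
## severity reclassification cross-tabulation.

#' Bland-Altman agreement between a method and a reference
#'
#' Differences are `method - reference`; bias is their mean, the 95% limits
#' of agreement `bias +/- 1.96 * SD` with the sample (n-1) standard
#' deviation. Pearson r (and r^2) is computed on the raw pairs; when either
#' sample has zero variance r is returned as `NA` (undefined).
#'
#' @param method,reference Equal-length paired measurement vectors (n >= 2).
#' @return Object of class `la_agreement` with `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pearson_r`, `r_squared`, and the per-pair
#'   `means`/`diffs` needed for a Bland-Altman plot.
#' @export
bland_altman <- function(method, reference) {
  if (length(method) != length(reference)) stop("paired samples must have equal length")
  n <- length(method)
  if (n < 2L) stop("need at least two pairs")
  diffs <- method - reference
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  r <- if (stats::sd(method) == 0 || stats::sd(reference) == 0) NA_real_
       else stats::cor(method, reference)
  structure(list(
    n = n, bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    pearson_r = r, r_squared = r^2,
    means = (method + reference) / 2, diffs = diffs
  ), class = "la_agreement")
}

#' @export
print.la_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, 95%% LOA [%.2f, %.2f], r = %s\n",
              x$n, x$bias, x$loa_low, x$loa_high,
              ifelse(is.na(x$pearson_r), "undefined", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Two-way mixed absolute-agreement ICC, single measures
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an n-subjects x k-raters
#' matrix:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`,
#' with `MS_R` the subject (row), `MS_C` the rater (column) and `MS_E` the
#' residual mean squares.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns, no
#'   missing cells.
#' @return Object of class `la_icc` with `icc`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `n`, `k`, and the model label.
#' @export
icc_absolute_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ms_rows <- k * sum((rm_ - gm)^2) / (n - 1)
  ms_cols <- n * sum((cm - gm)^2) / (k - 1)
  resid <- ratings - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  ms_err <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  if (denom == 0) stop("degenerate ratings: zero total variance")
  structure(list(icc = (ms_rows - ms_err) / denom,
                 ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
                 n = n, k = k,
                 model = "two-way mixed, absolute agreement, single measures (ICC(A,1))"),
            class = "la_icc")
}

#' @export
print.la_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f  [%s; n = %d subjects, k = %d raters]\n",
              x$icc, x$model, x$n, x$k))
  invisible(x)
}

#' Severity reclassification cross-tabulation
#'
#' 4x4 cross-tab of LA-dilation severity categories (reference in rows,
#' method in columns), with the number and percentage of subjects whose
#' category changes and the counts moved by exactly one or by two or more
#' ordinal degrees in each direction.
#'
#' @param reference,method Equal-length vectors of categories (characters or
#'   factors with levels normal, mild, moderate, severe).
#' @return Object of class `la_reclassification`.
#' @export
reclassification <- function(reference, method) {
  if (length(reference) != length(method)) stop("category lists must have equal length")
  lv <- severity_levels()
  as_sev <- function(x) {
    x <- as.character(x)
    bad <- setdiff(unique(x), lv)
    if (length(bad)) stop("unknown category label: ", paste(bad, collapse = ", "))
    factor(x, levels = lv, ordered = TRUE)
  }
  ref <- as_sev(reference); met <- as_sev(method)
  tab <- table(reference = ref, method = met)
  n <- length(ref)
  shift <- as.integer(met) - as.integer(ref)  # >0: method reads more severe
  changed <- sum(shift != 0)
  structure(list(
    table = tab, n = n, n_changed = changed,
    pct_changed = 100 * changed / n,
    up_1 = sum(shift == 1), up_2plus = sum(shift >= 2),
    down_1 = sum(shift == -1), down_2plus = sum(shift <= -2)
  ), class = "la_reclassification")
}

#' @export
print.la_reclassification <- function(x, ...) {
  cat(sprintf("Severity reclassification: %d of %d subjects change category (%.1f%%)\n",
              x$n_changed, x$n, x$pct_changed))
  cat(sprintf("  up 1: %d, up >=2: %d, down 1: %d, down >=2: %d\n",
              x$up_1, x$up_2plus, x$down_1, x$down_2plus))
  print(x$table)
  invisible(x)
}
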