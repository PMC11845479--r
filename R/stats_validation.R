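# Agreement statistics used to validate computed indices against a
# reference system (device or expert): Spearman rank correlation,
# Mann-Whitney U, Shapiro-Wilk, Levene, and two-way mixed-effects
# consistency ICCs. Significance is assessed at alpha = 0.01.

#' Spearman rank correlation between paired measurements
#'
#' Rank correlation with average ranks for ties; the p-value uses the t
#' approximation. Incomplete pairs are dropped (pairwise deletion).
#'
#' @param x,y paired numeric vectors.
#' @return A list with `rho`, `p_value`, `n` and `flag` (`"ok"` or
#'   `"constant_input"`).
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                flag = "constant_input"))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       flag = "ok")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with normal approximation and tie correction.
#'
#' @param a,b numeric samples.
#' @return A list with `u` (the U statistic for sample `a`), `p_value`,
#'   `n_a`, `n_b`.
#' @export
mwu <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample (3 to 5000 values).
#' @return A list with `w`, `p_value`.
#' @export
shapiro <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("shapiro: need at least 3 values")
  st <- stats::shapiro.test(x)
  list(w = unname(st$statistic), p_value = st$p.value)
}

#' Levene's test for homogeneity of variance
#'
#' Centre = median (Brown-Forsythe variant), as is standard for
#' non-normal index distributions.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return A list with `statistic` (F), `p_value`.
#' @export
levene <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("levene: need at least 2 groups")
  lt <- car::leveneTest(values, groups, center = stats::median)
  list(statistic = lt[["F value"]][1], p_value = lt[["Pr(>F)"]][1])
}

#' Two-way mixed-effects consistency ICCs (ICC3, ICC3K)
#'
#' Single-rater ICC3 = (MSR - MSE) / (MSR + (k-1) MSE) and averaged-rater
#' ICC3K = (MSR - MSE) / MSR, from the two-way (subjects x raters) ANOVA
#' mean squares. The F test is MSR/MSE on (n-1, (n-1)(k-1)) degrees of
#' freedom; 95% confidence intervals come from the F bounds. Rows with any
#' missing cell are dropped (complete-case) before the decomposition.
#'
#' @param ratings numeric matrix or data.frame, subjects x raters
#'   (>= 5 rows, >= 2 columns after deletion).
#' @return An `icc_result` list: `icc3`, `icc3k`, `ci95_icc3`,
#'   `ci95_icc3k`, `f_stat`, `df1`, `df2`, `p_value`, `n`, `k`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("icc: need at least 2 raters")
  if (n < 5L) stop("icc: need at least 5 complete subjects")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (mse <= .Machine$double.eps * msr) {
    return(structure(list(icc3 = 1, icc3k = 1, ci95_icc3 = c(1, 1),
                          ci95_icc3k = c(1, 1), f_stat = Inf,
                          df1 = n - 1, df2 = (n - 1) * (k - 1),
                          p_value = 0, n = n, k = k),
                     class = "icc_result"))
  }
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  fl <- f / stats::qf(0.975, df1, df2)
  fu <- f * stats::qf(0.975, df2, df1)
  ci3 <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  ci3k <- c(1 - 1 / fl, 1 - 1 / fu)
  structure(list(icc3 = (msr - mse) / (msr + (k - 1) * mse),
                 icc3k = (msr - mse) / msr,
                 ci95_icc3 = ci3, ci95_icc3k = ci3k,
                 f_stat = f, df1 = df1, df2 = df2, p_value = p,
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc: ICC3 %.3f [%.3f, %.3f], ICC3K %.3f [%.3f, %.3f], F(%d,%d)=%.2f p=%.3g>\n",
              x$icc3, x$ci95_icc3[1], x$ci95_icc3[2],
              x$icc3k, x$ci95_icc3k[1], x$ci95_icc3k[2],
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Compare computed indices against a reference system
#'
#' For each index present in both tables, computes means, mean difference,
#' Spearman rho, Mann-Whitney U, and ICC3/ICC3K between the two methods
#' (pairwise deletion per index).
#'
#' @param computed,reference data.frames with columns `record_id`,
#'   `index`, `value` (as produced by [indices_table()]).
#' @return A data.frame with one row per index: `n`, `mean_computed`,
#'   `mean_reference`, `delta`, `rho`, `rho_p`, `u`, `u_p`, `icc3`,
#'   `icc3k`.
#' @export
validate_indices <- function(computed, reference) {
  idx <- intersect(unique(computed$index), unique(reference$index))
  rows <- lapply(idx, function(ix) {
    a <- computed[computed$index == ix, c("record_id", "value")]
    b <- reference[reference$index == ix, c("record_id", "value")]
    mg <- merge(a, b, by = "record_id", suffixes = c("_c", "_r"))
    mg <- mg[stats::complete.cases(mg), ]
    if (nrow(mg) < 5L) {
      return(data.frame(index = ix, n = nrow(mg), mean_computed = NA,
                        mean_reference = NA, delta = NA, rho = NA,
                        rho_p = NA, u = NA, u_p = NA, icc3 = NA,
                        icc3k = NA))
    }
    sp <- spearman(mg$value_c, mg$value_r)
    mw <- mwu(mg$value_c, mg$value_r)
    ic <- icc(cbind(mg$value_c, mg$value_r))
    data.frame(index = ix, n = nrow(mg),
               mean_computed = mean(mg$value_c),
               mean_reference = mean(mg$value_r),
               delta = mean(mg$value_c) - mean(mg$value_r),
               rho = sp$rho, rho_p = sp$p_value,
               u = mw$u, u_p = mw$p_value,
               icc3 = ic$icc3, icc3k = ic$icc3k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
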