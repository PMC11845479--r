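# Paired comparison of classifiers on a shared test set, via their
# per-item correctness indicators.

#' Cochran's Q test for k paired binary outcomes
#'
#' Tests whether several classifiers (columns) differ in their per-item
#' correctness (rows of 0/1). With all-identical columns the statistic is
#' defined as 0 with p = 1.
#'
#' @param correct matrix or data.frame of 0/1 correctness indicators,
#'   items x classifiers (at least 3 columns).
#' @return A list with `statistic` (Q), `df`, `p_value`.
#' @export
cochran_q <- function(correct) {
  m <- as.matrix(correct)
  storage.mode(m) <- "double"
  k <- ncol(m)
  if (k < 3L) stop("cochran_q: need at least 3 classifiers")
  if (!all(m %in% c(0, 1))) stop("cochran_q: entries must be 0/1")
  G <- colSums(m)
  L <- rowSums(m)
  denom <- k * sum(L) - sum(L^2)
  Q <- if (denom == 0) 0 else (k - 1) * (k * sum(G^2) - sum(G)^2) / denom
  p <- if (denom == 0) 1 else stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  list(statistic = Q, df = k - 1L, p_value = p)
}

#' McNemar's test for two paired binary outcomes
#'
#' Compares two classifiers through their discordant counts b (A correct,
#' B wrong) and c (A wrong, B correct). Uses the chi-squared statistic
#' `(|b-c|-1)^2/(b+c)` with continuity correction (or `(b-c)^2/(b+c)`
#' without); when `b + c < 25` the p-value comes from the exact binomial
#' test instead. With no discordant pairs the statistic is 0 and p = 1.
#'
#' @param correct_a,correct_b 0/1 correctness vectors of equal length.
#' @param continuity_correction apply the continuity correction.
#' @return A list with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar <- function(correct_a, correct_b, continuity_correction = TRUE) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); b_ <- as.logical(correct_b)
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  if (b + cc == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = cc,
                method = "degenerate"))
  stat <- if (continuity_correction) {
    (abs(b - cc) - 1)^2 / (b + cc)
  } else {
    (b - cc)^2 / (b + cc)
  }
  if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    method <- "exact_binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- if (continuity_correction) "chi2_corrected" else "chi2"
  }
  list(statistic = stat, p_value = p, b = b, c = cc, method = method)
}
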