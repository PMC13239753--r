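#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement for paired repeated measurements:
#' differences `d = m1 - m2`, bias `mean(d)`, limits `bias ± 1.96 * SD(d)`
#' (sample SD, n - 1 denominator).
#'
#' @param m1,m2 Paired measurement series (mm), equal length, n >= 2.
#'
#' @return A list of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, `n`, and the per-pair tibble `data` (`mean`, `diff`) used by
#'   [autoplot.bland_altman()].
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2)) abort("series lengths differ.")
  if (length(m1) < 2) abort("need n >= 2 pairs.")
  d <- m1 - m2
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         sd_diff = s, n = length(d),
         data = tibble::tibble(mean = (m1 + m2) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% LoA (%.3f, %.3f), n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper, sd_diff = x$sd_diff, n = x$n)
}

#' Intraclass correlation coefficient for two raters
#'
#' Single-measurement ICC from the standard mean-squares decomposition of a
#' subjects-by-raters table. The default is the two-way, absolute-agreement
#' form ICC(A,1): with n subjects and k raters,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The one-way form ICC(1) `(MSR - MSW) / (MSR + (k-1) MSW)` is available
#' behind `model = "oneway"`.
#'
#' @param m1,m2 Paired measurement series, equal length, n >= 3.
#' @param model `"twoway_agreement"` (default) or `"oneway"`.
#'
#' @return Single numeric ICC value.
#' @export
icc <- function(m1, m2, model = c("twoway_agreement", "oneway")) {
  model <- match.arg(model)
  if (length(m1) != length(m2)) abort("series lengths differ.")
  n <- length(m1)
  if (n < 3) abort("need n >= 3 subjects.")
  mat <- cbind(m1, m2)
  k <- 2
  subj_means <- rowMeans(mat)
  rater_means <- colMeans(mat)
  grand <- mean(mat)
  if (var(subj_means) == 0) abort("zero between-subject variance; ICC undefined.")
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)
  msc <- ss_rater / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (model == "twoway_agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    msw <- (ss_rater + ss_err) / (n * (k - 1))
    (msr - msw) / (msr + (k - 1) * msw)
  }
}

#' Full agreement summary for paired measurements
#'
#' Convenience wrapper combining [bland_altman()] and [icc()].
#'
#' @inheritParams icc
#' @return A `bland_altman` object with `icc` and `icc_model` fields added.
#' @export
agreement_analysis <- function(m1, m2, model = "twoway_agreement") {
  res <- bland_altman(m1, m2)
  res$icc <- icc(m1, m2, model = model)
  res$icc_model <- model
  res
}
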