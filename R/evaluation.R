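#' Pearson correlation with a t-distribution p-value
#'
#' @param xs,ys Numeric vectors of equal length, n >= 3, neither constant.
#' @param variable Label recorded on the result row.
#'
#' @return One-row tibble: `variable`, `r`, `p`, `n`.
#' @export
pearson_with_p <- function(xs, ys, variable = "x") {
  if (length(xs) != length(ys)) abort("series lengths differ.")
  if (length(xs) < 3) abort("need n >= 3 for a correlation p-value.")
  if (sd(xs) == 0 || sd(ys) == 0) abort("correlation undefined for a constant series.")
  ct <- cor.test(xs, ys, method = "pearson")
  tibble::tibble(variable = variable, r = unname(ct$estimate),
                 p = ct$p.value, n = length(xs))
}

#' Residual-correlation profile of a corrected series
#'
#' Correlates a corrected (or BSA-indexed) series against each physiological
#' variable — age, height, weight, BSA and BMI (the last two computed from
#' height and weight) — plus the uncorrected measurements themselves. A
#' successful correction leaves no material correlation with the
#' physiological variables while staying strongly correlated with the
#' uncorrected values.
#'
#' @param values Corrected series, one value per subject.
#' @param data Subject tibble with `age`, `height_cm`, `weight_kg`.
#' @param uncorrected Optional series of uncorrected measurements (mm); when
#'   supplied an `uncorrected` entry is included in the profile.
#'
#' @return Tibble of correlation entries (`variable`, `r`, `p`, `n`) with a
#'   `classification` column from [classify_residual()].
#' @export
residual_profile <- function(values, data, uncorrected = NULL) {
  data <- tibble::as_tibble(data)
  if (length(values) != nrow(data)) abort("one corrected value per subject required.")
  covars <- list(
    age = data$age,
    height = data$height_cm,
    weight = data$weight_kg,
    bsa = bsa_dubois(data$height_cm, data$weight_kg),
    bmi = compute_bmi(data$height_cm, data$weight_kg)
  )
  if (!is.null(uncorrected)) covars <- c(list(uncorrected = uncorrected), covars)
  out <- purrr::imap(covars, function(v, nm) pearson_with_p(v, values, nm))
  out <- dplyr::bind_rows(out)
  out$classification <- classify_residual(out$r, out$p)
  out
}

#' Classify a residual correlation
#'
#' A significant negative residual correlation (r < 0, p < 0.05) marks
#' overcorrection — the indexation reversed the physiological relationship;
#' a significant positive one (r > 0, p < 0.05) marks undercorrection — a
#' residual dependence survived. Anything else is acceptable. This label is
#' independent of the |r| > 0.20 success gate: a correlation can be
#' statistically significant yet biologically negligible.
#'
#' @param r,p Numeric vectors of correlation coefficients and p-values.
#'
#' @return Character vector: `"overcorrected"`, `"undercorrected"` or
#'   `"acceptable"`.
#' @export
classify_residual <- function(r, p) {
  dplyr::case_when(
    r < 0 & p < 0.05 ~ "overcorrected",
    r > 0 & p < 0.05 ~ "undercorrected",
    TRUE ~ "acceptable"
  )
}

#' Assess correction efficacy for one parameter
#'
#' Applies the two predefined success criteria to a corrected series on a
#' validation cohort:
#' \enumerate{
#'   \item no physiological variable shows a residual correlation that is
#'     both biologically (|r| > 0.20) and statistically (p < 0.05)
#'     significant;
#'   \item the corrected values remain significantly correlated (p < 0.05)
#'     with the uncorrected values.
#' }
#' Only when both hold is the correction successful.
#'
#' @param corrected Corrected series (Yc or BSA-indexed values).
#' @param uncorrected Uncorrected measured series (mm).
#' @param data Subject tibble aligned with both series.
#' @param param Aortic parameter label carried on the report.
#' @param population Population label carried on the report.
#' @param method Indexation method label, e.g. `"omam"` or `"bsa"`.
#' @param r_threshold Biological-significance bound on |r| (default 0.20).
#' @param alpha Statistical-significance level (default 0.05).
#'
#' @return A list of class `efficacy_report`: `entries` (the residual
#'   profile), `criterion1_pass`, `criterion2_pass`, `success`, plus the
#'   labels. Supports [tidy()] and [glance()].
#' @export
assess_efficacy <- function(corrected, uncorrected, data,
                            param = NA_character_, population = NA_character_,
                            method = NA_character_,
                            r_threshold = 0.20, alpha = 0.05) {
  entries <- residual_profile(corrected, data, uncorrected = uncorrected)
  phys <- dplyr::filter(entries, .data$variable != "uncorrected")
  unc <- dplyr::filter(entries, .data$variable == "uncorrected")
  criterion1 <- !any(abs(phys$r) > r_threshold & phys$p < alpha)
  criterion2 <- unc$p < alpha
  structure(
    list(param = param, population = population, method = method,
         entries = entries,
         criterion1_pass = criterion1, criterion2_pass = criterion2,
         success = criterion1 && criterion2,
         r_threshold = r_threshold, alpha = alpha),
    class = "efficacy_report"
  )
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat("<efficacy_report> ", x$population, " / ", x$param, " / ", x$method,
      ": ", if (x$success) "SUCCESS" else "failure",
      " (criterion 1 ", if (x$criterion1_pass) "pass" else "FAIL",
      ", criterion 2 ", if (x$criterion2_pass) "pass" else "FAIL", ")\n",
      sep = "")
  invisible(x)
}

#' @rdname assess_efficacy
#' @param x An `efficacy_report`.
#' @param ... Unused.
#' @export
tidy.efficacy_report <- function(x, ...) {
  dplyr::mutate(x$entries, param = x$param, population = x$population,
                method = x$method, .before = 1)
}

#' @rdname assess_efficacy
#' @export
glance.efficacy_report <- function(x, ...) {
  tibble::tibble(
    param = x$param, population = x$population, method = x$method,
    criterion1_pass = x$criterion1_pass, criterion2_pass = x$criterion2_pass,
    success = x$success
  )
}

#' Success rate over a set of efficacy reports
#'
#' @param reports List of [assess_efficacy()] results.
#'
#' @return Percentage of reports with `success = TRUE`, in \[0, 100\].
#' @export
success_rate <- function(reports) {
  if (length(reports) == 0) abort("no reports supplied.")
  ok <- vapply(reports, function(r) {
    stopifnot(inherits(r, "efficacy_report"))
    r$success
  }, logical(1))
  100 * mean(ok)
}

#' Between-gender comparison of corrected values
#'
#' Independent-samples pooled-variance (Student) t-test of corrected values
#' between men and women; Welch's form is available behind a flag.
#'
#' @param values Numeric series.
#' @param gender 0/1 codes aligned with `values` (0 = man, 1 = woman).
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#'
#' @return One-row tibble: `mean_men`, `mean_women`, `statistic`, `p`.
#' @export
gender_difference_test <- function(values, gender, var_equal = TRUE) {
  if (length(values) != length(gender)) abort("series lengths differ.")
  men <- values[gender == 0]
  women <- values[gender == 1]
  if (length(men) < 2 || length(women) < 2) {
    abort("both genders must be represented with n >= 2.")
  }
  tt <- t.test(men, women, var.equal = var_equal)
  tibble::tibble(mean_men = mean(men), mean_women = mean(women),
                 statistic = unname(tt$statistic), p = tt$p.value)
}

#' One-way ANOVA across age groups
#'
#' @param values Numeric series.
#' @param groups Factor (or coercible) of group labels aligned with `values`;
#'   at least two groups with n >= 2 each.
#'
#' @return One-row tibble: `statistic` (F), `p`, `df_between`, `df_within`.
#' @export
age_group_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups)) abort("series lengths differ.")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need at least two groups with n >= 2 each.")
  }
  if (var(values) == 0) {
    # identical groups carry no between-group signal
    return(tibble::tibble(statistic = 0, p = 1,
                          df_between = length(sizes) - 1L,
                          df_within = length(values) - length(sizes)))
  }
  tab <- anova(aov(values ~ groups))
  tibble::tibble(statistic = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Reference interval for corrected values
#'
#' Estimates the central 95% range of corrected values in healthy subjects,
#' used to classify a new subject's corrected ratio as decreased, normal or
#' increased. The default is the empirical 2.5th/97.5th percentile range;
#' `"normal_theory"` uses mean ± 1.96 SD.
#'
#' @param values Corrected series.
#' @param method `"percentile"` (default; requires n >= 40) or
#'   `"normal_theory"` (requires n >= 2).
#'
#' @return A list of class `reference_interval`: `mean`, `sd`, `lower`,
#'   `upper`, `method`, `n`, `degenerate`.
#' @export
reference_interval <- function(values, method = c("percentile", "normal_theory")) {
  method <- match.arg(method)
  n <- length(values)
  if (method == "percentile" && n < 40) {
    abort("percentile reference intervals need n >= 40.")
  }
  if (method == "normal_theory" && n < 2) abort("need n >= 2.")
  m <- mean(values); s <- sd(values)
  if (method == "percentile") {
    q <- unname(quantile(values, c(0.025, 0.975)))
    lower <- q[1]; upper <- q[2]
  } else {
    lower <- m - 1.96 * s
    upper <- m + 1.96 * s
  }
  degenerate <- !(lower < upper)
  if (degenerate) warn("degenerate reference interval (constant series).")
  structure(
    list(mean = m, sd = s, lower = lower, upper = upper,
         method = method, n = n, degenerate = degenerate),
    class = "reference_interval"
  )
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("<reference_interval> mean %.3f ± %.3f, 95%% range %.3f–%.3f (%s, n = %d)\n",
              x$mean, x$sd, x$lower, x$upper, x$method, x$n))
  invisible(x)
}

#' Classify a corrected value against a reference interval
#'
#' Closed-bound convention: values equal to a limit are normal.
#'
#' @param yc Corrected ratio(s).
#' @param interval A [reference_interval()].
#'
#' @return Character vector: `"decreased"`, `"normal"` or `"increased"`.
#' @export
classify_subject <- function(yc, interval) {
  stopifnot(inherits(interval, "reference_interval"))
  dplyr::case_when(
    yc < interval$lower ~ "decreased",
    yc > interval$upper ~ "increased",
    TRUE ~ "normal"
  )
}

#' Format a p-value the way clinical tables print it
#'
#' @param p Numeric p-values.
#' @return Character vector, three decimals with `"<0.001"` flooring.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
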