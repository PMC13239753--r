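#' Build the log-scale regression table for one aortic parameter
#'
#' The multiplicative model `Yu = a * b^gender * age^x * height^y * weight^z * e`
#' is linear after taking logs:
#' `ln(Yu) = ln(a) + gender*ln(b) + x*ln(age) + y*ln(height) + z*ln(weight) + ln(e)`.
#' This builds that design: response `ln_yu`, regressors `gender` (0/1),
#' `ln_age`, `ln_height`, `ln_weight`. BMI and BSA are deliberately never
#' candidate regressors — both are functions of height and weight and would
#' confound the original covariates.
#'
#' @param data Subject tibble with `gender`, `age`, `height_cm`, `weight_kg`
#'   and a measured column `<param>_mm`.
#' @param param Aortic parameter code (`"ao_a"`, `"ao_s"`, `"ao_asc"`).
#'
#' @return Tibble with columns `ln_yu`, `gender`, `ln_age`, `ln_height`,
#'   `ln_weight`.
#' @export
build_log_design <- function(data, param) {
  param <- match.arg(param, AORTIC_PARAMS)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("empty subject table.")
  mcol <- paste0(param, "_mm")
  for (col in c("gender", "age", "height_cm", "weight_kg", mcol)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` required.", col))
  }
  bad <- which(!is.finite(data[[mcol]]) | data[[mcol]] <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive %s for subject(s): %s", mcol,
                  paste(head(data$id[bad] %||% bad, 5), collapse = ", ")))
  }
  for (col in c("age", "height_cm", "weight_kg")) {
    if (any(!is.finite(data[[col]]) | data[[col]] <= 0)) {
      abort(sprintf("non-positive `%s` in subject table.", col))
    }
  }
  tibble::tibble(
    ln_yu = log(data[[mcol]]),
    gender = as.numeric(data$gender),
    ln_age = log(data$age),
    ln_height = log(data$height_cm),
    ln_weight = log(data$weight_kg)
  )
}

#' Ordinary least squares on a chosen term subset
#'
#' Inner solver for the stepwise search: fits `ln_yu` on the selected
#' regressors plus an intercept by OLS and reports the coefficient table
#' with two-sided t-test p-values.
#'
#' @param design Output of [build_log_design()].
#' @param terms Character vector of regressor names (possibly empty for the
#'   intercept-only model).
#'
#' @return List with `coefficients` (tibble: term, estimate, std.error,
#'   statistic, p.value), `sigma` (residual SD), `r.squared`, `n`.
#' @export
fit_ols <- function(design, terms = character()) {
  n <- nrow(design)
  if (n <= length(terms) + 1) abort("too few observations for the model size.")
  fml <- if (length(terms)) {
    stats::reformulate(terms, response = "ln_yu")
  } else {
    ln_yu ~ 1
  }
  fit <- lm(fml, data = design)
  if (fit$rank < length(terms) + 1) abort("rank-deficient design (collinear terms).")
  sm <- summary(fit)
  ct <- sm$coefficients
  list(
    coefficients = tibble::tibble(
      term = rownames(ct),
      estimate = unname(ct[, 1]), std.error = unname(ct[, 2]),
      statistic = unname(ct[, 3]), p.value = unname(ct[, 4])
    ),
    sigma = sm$sigma,
    r.squared = sm$r.squared,
    n = n
  )
}

#' Fit an allometric equation by stepwise log-linear regression
#'
#' Forward selection with backward elimination on the log-transformed model.
#' At each step the candidate whose single-term addition has the smallest
#' coefficient p-value enters if that p-value is below `p_enter`; after each
#' entry any included term with p-value at or above `p_remove` is removed
#' (worst first); the search stops at a fixed point. Ties in p-value break
#' by the fixed candidate order gender, ln_age, ln_height, ln_weight, so
#' fits are deterministic. The intercept is always retained. When only one
#' gender is present the gender candidate is silently dropped.
#'
#' The retained log-scale coefficients back-transform into an
#' [allometric_equation()]: `a = exp(intercept)`, `b = exp(gender
#' coefficient)` (1 if gender not retained), exponents equal to retained
#' log-covariate coefficients (0 if not retained).
#'
#' @param data Subject tibble (see [build_log_design()]).
#' @param param Aortic parameter code.
#' @param p_enter Entry significance threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must satisfy
#'   `p_enter <= p_remove`.
#' @param candidates Candidate regressors, a subset of
#'   `c("gender", "ln_age", "ln_height", "ln_weight")`.
#' @param max_iterations Cycling guard on the enter/remove loop.
#'
#' @return An object of class `allometric_fit` with elements `equation`,
#'   `coefficients` (log-scale table), `sigma`, `r.squared`, `n`, `param`,
#'   `retained`. Supports [tidy()] and [glance()].
#'
#' @examples
#' spec <- default_population_specs()$chinese_like
#' cohort <- generate_population(spec, n = 300, seed = 1)
#' fit <- fit_allometric(cohort, "ao_a")
#' fit$equation
#' @export
fit_allometric <- function(data, param, p_enter = 0.05, p_remove = 0.10,
                           candidates = c("gender", "ln_age", "ln_height",
                                          "ln_weight"),
                           max_iterations = 50L) {
  design <- build_log_design(data, param)
  res <- stepwise_fit(design, p_enter = p_enter, p_remove = p_remove,
                      candidates = candidates,
                      max_iterations = max_iterations)
  res$param <- param
  res$equation <- backtransform_equation(param, res$coefficients)
  res
}

#' Stepwise search on a prepared log design
#'
#' Lower-level interface to the selection loop used by [fit_allometric()];
#' useful when the design table is constructed directly.
#'
#' @inheritParams fit_allometric
#' @param design Output of [build_log_design()].
#' @return As [fit_allometric()] but without `equation`/`param` when called
#'   directly on a design.
#' @export
stepwise_fit <- function(design, p_enter = 0.05, p_remove = 0.10,
                         candidates = c("gender", "ln_age", "ln_height",
                                        "ln_weight"),
                         max_iterations = 50L) {
  if (!(p_enter > 0 && p_enter < 1 && p_enter <= p_remove && p_remove < 1)) {
    abort("need 0 < p_enter <= p_remove < 1.")
  }
  candidates <- match.arg(candidates,
                          c("gender", "ln_age", "ln_height", "ln_weight"),
                          several.ok = TRUE)
  # degenerate cohort: a constant regressor can never be tested
  candidates <- candidates[vapply(candidates,
                                  function(v) var(design[[v]]) > 0, logical(1))]

  term_p <- function(fit, term) {
    tab <- fit$coefficients
    tab$p.value[match(term, tab$term)]
  }

  included <- character()
  for (iter in seq_len(max_iterations)) {
    pool <- setdiff(candidates, included)
    entry <- NULL
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        term_p(fit_ols(design, c(included, v)), v)
      }, numeric(1))
      best <- pool[which.min(pvals)]     # which.min: first = fixed-order tie-break
      if (pvals[[best]] < p_enter) entry <- best
    }
    if (is.null(entry)) break
    included <- c(included, entry)
    # backward elimination to a fixed point
    repeat {
      fit <- fit_ols(design, included)
      pv <- vapply(included, function(v) term_p(fit, v), numeric(1))
      worst <- which.max(pv)
      if (length(pv) == 0 || pv[[worst]] < p_remove) break
      included <- included[-worst]
    }
    if (iter == max_iterations) abort("stepwise selection did not converge.")
  }

  final <- fit_ols(design, included)
  structure(
    list(coefficients = final$coefficients, retained = included,
         sigma = final$sigma, r.squared = final$r.squared, n = final$n,
         p_enter = p_enter, p_remove = p_remove, candidates = candidates),
    class = "allometric_fit"
  )
}

backtransform_equation <- function(param, coefficients) {
  est <- setNames(coefficients$estimate, coefficients$term)
  pick <- function(term) if (term %in% names(est)) est[[term]] else 0
  allometric_equation(
    param,
    a = exp(est[["(Intercept)"]]),
    b = exp(pick("gender")),
    x = pick("ln_age"),
    y = pick("ln_height"),
    z = pick("ln_weight"),
    provenance = "fitted"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("<allometric_fit>")
  if (!is.null(x$param)) cat(" ", format(x$equation), sep = "")
  cat("\n  n = ", x$n, ", R^2 = ", signif(x$r.squared, 3),
      ", residual log-SD = ", signif(x$sigma, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_allometric
#' @param x,object An `allometric_fit`.
#' @param ... Unused.
#' @export
tidy.allometric_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_allometric
#' @export
glance.allometric_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, sigma = x$sigma, n = x$n,
    n_terms = length(x$retained)
  )
}
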