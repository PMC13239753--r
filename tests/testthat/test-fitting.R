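test_that("log design transforms response and regressors correctly", {
  e <- exp(1)
  one <- tibble::tibble(id = "a", gender = 0, age = e, height_cm = e,
                        weight_kg = e, ao_a_mm = e)
  d <- build_log_design(one, "ao_a")
  expect_equal(unname(unlist(d)), c(1, 0, 1, 1, 1))

  # woman flag maps to regressor value 1
  d2 <- build_log_design(dplyr::mutate(one, gender = 1), "ao_a")
  expect_equal(d2$gender, 1)

  expect_error(build_log_design(one[0, ], "ao_a"), "empty")
  expect_error(build_log_design(dplyr::mutate(one, weight_kg = 0), "ao_a"),
               "weight")
  expect_error(build_log_design(dplyr::mutate(one, ao_a_mm = -2), "ao_a"),
               "ao_a_mm")
})

test_that("OLS matches the closed-form simple-regression slope", {
  x <- c(1, 2, 3, 4, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, 11.8)
  d <- tibble::tibble(ln_yu = y, gender = x, ln_age = 0, ln_height = 0,
                      ln_weight = 0)
  fit <- fit_ols(d, "gender")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  est <- fit$coefficients$estimate
  expect_equal(est[fit$coefficients$term == "gender"], slope)
  expect_equal(est[fit$coefficients$term == "(Intercept)"],
               mean(y) - slope * mean(x))

  # exact linear data interpolates with zero residual
  d0 <- dplyr::mutate(d, ln_yu = 1 + 2 * gender)
  fit0 <- suppressWarnings(fit_ols(d0, "gender")) # perfect-fit summary warning
  expect_equal(fit0$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_lt(fit0$sigma, 1e-10)

  # duplicated regressor -> rank error
  ddup <- dplyr::mutate(d, ln_age = gender)
  expect_error(fit_ols(ddup, c("gender", "ln_age")), "rank")
  expect_error(fit_ols(d[1:2, ], "gender"), "too few")
})

test_that("stepwise on pure noise retains nothing and reduces to the log-mean", {
  set.seed(42)
  n <- 200
  s <- tibble::tibble(
    id = as.character(seq_len(n)), gender = rbinom(n, 1, 0.5),
    age = runif(n, 20, 70), height_cm = runif(n, 150, 190),
    weight_kg = runif(n, 50, 90),
    ao_a_mm = exp(rnorm(n, log(21), 0.1))
  )
  fit <- fit_allometric(s, "ao_a")
  expect_length(fit$retained, 0)
  expect_equal(fit$equation$a, exp(mean(log(s$ao_a_mm))))
  expect_equal(fit$equation$b, 1)
  expect_equal(c(fit$equation$x, fit$equation$y, fit$equation$z), c(0, 0, 0))
})

test_that("stepwise recovers the generating equation from simulated data", {
  spec <- default_population_specs()$chinese_like
  cohort <- generate_population(spec, n = 637, seed = 7)
  fit <- fit_allometric(cohort, "ao_a")
  expect_true(all(c("gender", "ln_age", "ln_weight") %in% fit$retained))
  expect_lt(abs(fit$equation$x - 0.054), 0.05)
  expect_lt(abs(fit$equation$z - 0.142), 0.05)
  expect_lt(abs(fit$equation$b - 0.943), 0.02)
  # residual log-SD estimates the generating noise scale
  expect_equal(fit$sigma, 0.11, tolerance = 0.1)
})

test_that("as noise vanishes the recovered exponents converge to the truth", {
  spec <- default_population_specs()$chinese_like
  spec$noise_sigma <- 1e-6
  cohort <- generate_population(spec, n = 300, seed = 3)
  fit <- fit_allometric(cohort, "ao_a")
  expect_lt(abs(fit$equation$x - 0.054), 1e-3)
  expect_lt(abs(fit$equation$z - 0.142), 1e-3)
  expect_lt(abs(fit$equation$b - 0.943), 1e-3)
})

test_that("stepwise fixed point agrees with exhaustive-subset verification", {
  cands <- c("gender", "ln_age", "ln_height", "ln_weight")
  set.seed(11)
  for (rep in 1:12) {
    n <- 60
    d <- tibble::tibble(
      gender = rbinom(n, 1, 0.5),
      ln_age = rnorm(n), ln_height = rnorm(n), ln_weight = rnorm(n)
    )
    # random sparse truth, moderate noise so selection is non-trivial
    beta <- round(runif(4, -0.3, 0.3) * rbinom(4, 1, 0.5), 2)
    d$ln_yu <- 3 + as.matrix(d[cands]) %*% beta + rnorm(n, 0, 0.15)
    d$ln_yu <- as.numeric(d$ln_yu)
    res <- stepwise_fit(d)
    expect_true(is_stepwise_fixed_point(d, res$retained, cands))
  }
})

test_that("back-transform round-trips and the fit is scale-equivariant", {
  spec <- default_population_specs()$chinese_like
  cohort <- generate_population(spec, n = 400, seed = 5)
  fit1 <- fit_allometric(cohort, "ao_s")
  # log of the back-transformed equation reproduces the log-scale fit
  est <- setNames(fit1$coefficients$estimate, fit1$coefficients$term)
  expect_equal(log(fit1$equation$a), unname(est[["(Intercept)"]]))
  if ("gender" %in% names(est)) {
    expect_equal(log(fit1$equation$b), unname(est[["gender"]]))
  }
  fit2 <- fit_allometric(dplyr::mutate(cohort, ao_s_mm = 3 * ao_s_mm), "ao_s")
  expect_equal(fit2$equation$a, 3 * fit1$equation$a)
  expect_equal(fit2$equation$b, fit1$equation$b)
  expect_equal(c(fit2$equation$x, fit2$equation$y, fit2$equation$z),
               c(fit1$equation$x, fit1$equation$y, fit1$equation$z))
})

test_that("training-set corrected values have geometric mean exactly 1", {
  spec <- default_population_specs()$italian_like
  cohort <- generate_population(spec, n = 400, seed = 9)
  fit <- fit_allometric(cohort, "ao_a")
  yc <- correct_yc(cohort$ao_a_mm, predict_yp(fit$equation, cohort))
  expect_equal(mean(log(yc)), 0, tolerance = 1e-10)
})

test_that("single-gender cohorts silently drop the gender candidate", {
  spec <- default_population_specs()$chinese_like
  cohort <- generate_population(spec, n = 400, seed = 13)
  men <- dplyr::filter(cohort, gender == 0)
  fit <- fit_allometric(men, "ao_a")
  expect_false("gender" %in% fit$retained)
  expect_equal(fit$equation$b, 1)
})

test_that("tidy and glance expose the fit in broom style", {
  cohort <- generate_population(default_population_specs()$chinese_like,
                                n = 300, seed = 2)
  fit <- fit_allometric(cohort, "ao_a")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$n, 300)
  expect_equal(gl$n_terms, length(fit$retained))
})
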