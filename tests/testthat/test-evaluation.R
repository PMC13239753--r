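test_that("Pearson correlation with t-based p matches hand computation", {
  xs <- c(1, 2, 3, 4, 5)
  ys <- c(2, 1, 4, 3, 5)
  e <- pearson_with_p(xs, ys)
  expect_equal(e$r, 0.8, tolerance = 1e-6)
  # p from t = r*sqrt(n-2)/sqrt(1-r^2) with n-2 df
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(e$p, 2 * pt(tstat, df = 3, lower.tail = FALSE), tolerance = 1e-6)

  perfect <- pearson_with_p(xs, 2 * xs + 1)
  expect_equal(perfect$r, 1)
  expect_error(pearson_with_p(rep(1, 5), ys), "constant")
  expect_error(pearson_with_p(xs, ys[1:4]), "length")
})

test_that("residual classification follows the sign/significance rule", {
  expect_equal(classify_residual(-0.451, 1e-4), "overcorrected")
  # significant but biologically small: still labelled, but not a
  # criterion-1 failure since |r| < 0.20
  expect_equal(classify_residual(-0.133, 0.028), "overcorrected")
  expect_equal(classify_residual(0.25, 0.001), "undercorrected")
  expect_equal(classify_residual(0.05, 0.40), "acceptable")
  expect_equal(classify_residual(-0.5, 0.30), "acceptable")
})

test_that("residual profile covers the five physiological variables", {
  s <- generate_population(default_population_specs()$chinese_like,
                           n = 273, seed = 31)
  # values equal to age correlate perfectly with the age entry
  prof <- residual_profile(s$age, s)
  expect_setequal(prof$variable, c("age", "height", "weight", "bsa", "bmi"))
  expect_equal(prof$r[prof$variable == "age"], 1)

  # values independent of all covariates: nothing trips the |r|>0.20 gate
  set.seed(32)
  null_vals <- exp(rnorm(273, 0, 0.11))
  prof0 <- residual_profile(null_vals, s)
  expect_false(any(abs(prof0$r) > 0.20 & prof0$p < 0.05))

  # BSA-ratio indexation of a simulated cohort shows overcorrection
  bsa <- bsa_dubois(s$height_cm, s$weight_kg)
  prof_bsa <- residual_profile(index_bsa(s$ao_a_mm, bsa), s,
                               uncorrected = s$ao_a_mm)
  expect_lt(prof_bsa$r[prof_bsa$variable == "bsa"], 0)
  expect_lt(prof_bsa$p[prof_bsa$variable == "bsa"], 0.05)
  expect_error(residual_profile(null_vals[1:10], s), "per subject")
})

test_that("efficacy criteria: self-fit succeeds, BSA fails, criterion 2 guards", {
  spec <- default_population_specs()$chinese_like
  train <- generate_population(spec, n = 637, seed = 41)
  valid <- generate_population(spec, n = 273, seed = 42)
  fit <- fit_allometric(train, "ao_a")
  yu <- valid$ao_a_mm
  yc <- correct_yc(yu, predict_yp(fit$equation, valid))
  rep_omam <- assess_efficacy(yc, yu, valid, param = "ao_a",
                              population = "chinese", method = "omam")
  expect_true(rep_omam$criterion1_pass)
  expect_true(rep_omam$criterion2_pass)
  expect_true(rep_omam$success)

  bsa_vals <- index_bsa(yu, bsa_dubois(valid$height_cm, valid$weight_kg))
  rep_bsa <- assess_efficacy(bsa_vals, yu, valid, method = "bsa")
  expect_false(rep_bsa$criterion1_pass)
  expect_false(rep_bsa$success)

  # corrected series independent of uncorrected: criterion 2 fails
  set.seed(43)
  indep <- exp(rnorm(273, 0, 0.11))
  rep_ind <- assess_efficacy(indep, yu, valid)
  expect_false(rep_ind$criterion2_pass)
  expect_false(rep_ind$success)

  # success <=> criterion1 & criterion2, and glance reports the verdict
  for (r in list(rep_omam, rep_bsa, rep_ind)) {
    expect_equal(r$success, r$criterion1_pass && r$criterion2_pass)
  }
  expect_named(glance(rep_omam),
               c("param", "population", "method", "criterion1_pass",
                 "criterion2_pass", "success"))
})

test_that("success_rate is a bounded permutation-invariant percentage", {
  spec <- default_population_specs()$chinese_like
  s <- generate_population(spec, n = 273, seed = 44)
  yu <- s$ao_a_mm
  yc <- correct_yc(yu, predict_yp(spec$truth$equations$ao_a, s))
  good <- assess_efficacy(yc, yu, s)
  bad <- assess_efficacy(index_bsa(yu, bsa_dubois(s$height_cm, s$weight_kg)), yu, s)
  expect_equal(success_rate(list(good, bad)), 50)
  expect_equal(success_rate(list(bad, good)), 50)
  expect_equal(success_rate(list(good, good)), 100)
  expect_equal(success_rate(list(bad)), 0)
  expect_error(success_rate(list()), "no reports")
})

test_that("pooled t-test matches hand computation and degenerates sensibly", {
  res <- gender_difference_test(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$mean_men, 2)
  expect_equal(res$mean_women, 3)
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)

  same <- gender_difference_test(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$mean_men - same$mean_women, 0)
  expect_equal(same$p, 1)
  expect_error(gender_difference_test(1:5, rep(0, 5)), "both genders")
})

test_that("one-way ANOVA matches the aov decomposition on toy groups", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- age_group_anova(v, g)
  # between mean square 8.0, error mean square 0.5 -> F = 16
  expect_equal(res$statistic, 16)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 3)
  oracle <- anova(aov(v ~ factor(g)))
  expect_equal(res$p, oracle$`Pr(>F)`[1])

  const <- age_group_anova(rep(5, 6), g)
  expect_equal(const$statistic, 0)
  expect_equal(const$p, 1)
  expect_error(age_group_anova(v, rep("a", 6)), "two groups")
})

test_that("uncorrected dimensions vary with age group; corrected ones do not", {
  spec <- default_population_specs()$chinese_like
  s <- generate_population(spec, n = 910, seed = 45)
  grp <- assign_age_group(s$age)
  raw <- age_group_anova(s$ao_asc_mm, grp)
  expect_lt(raw$p, 0.05)
  yc <- correct_yc(s$ao_asc_mm, predict_yp(spec$truth$equations$ao_asc, s))
  cor_res <- age_group_anova(yc, grp)
  expect_gt(cor_res$p, 0.05)
})

test_that("reference intervals bracket the generating lognormal mass", {
  set.seed(46)
  vals <- exp(rnorm(1e5, 0, 0.11))
  iv <- reference_interval(vals, "percentile")
  expect_equal(iv$lower, exp(-1.96 * 0.11), tolerance = 0.01 / exp(-1.96 * 0.11))
  expect_equal(iv$upper, exp(1.96 * 0.11), tolerance = 0.01 / exp(1.96 * 0.11))
  expect_true(iv$lower < iv$mean && iv$mean < iv$upper)

  nt <- reference_interval(rnorm(100, 1.002, 0.112), "normal_theory")
  expect_equal(nt$lower, nt$mean - 1.96 * nt$sd)
  expect_equal(nt$upper, nt$mean + 1.96 * nt$sd)

  expect_warning(deg <- reference_interval(rep(1, 50), "percentile"), "degenerate")
  expect_true(deg$degenerate)
  expect_error(reference_interval(rnorm(10), "percentile"), "n >= 40")
})

test_that("subjects classify against the published interval with closed bounds", {
  iv <- builtin_equation_sets()$chinese$intervals$ao_a
  expect_equal(classify_subject(1.00, iv), "normal")
  expect_equal(classify_subject(1.30, iv), "increased")
  expect_equal(classify_subject(0.70, iv), "decreased")
  expect_equal(classify_subject(iv$lower, iv), "normal")
  expect_equal(classify_subject(iv$upper, iv), "normal")
})

test_that("p-values format like the clinical tables", {
  expect_equal(format_p(c(0.0005, 0.028, 0.24)), c("<0.001", "0.028", "0.240"))
})
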