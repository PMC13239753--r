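#' Read and write subject tables
#'
#' Subject tables are comma-separated UTF-8 files with a header and columns
#' `id, population, gender, age, height_cm, weight_kg, ao_a_mm, ao_s_mm,
#' ao_asc_mm` (optional `sbp`, `dbp`). Gender tokens `0/1`, `m/f`,
#' `man/woman`, `male/female` are normalized to 0 (man) / 1 (woman) on read.
#' In strict mode (default) any row violating the eligibility invariants —
#' age within \[18, 79\], positive height/weight/dimensions, BMI < 30 — is
#' an error naming the row; in lenient mode offending rows are dropped with
#' a warning count.
#'
#' @param path File path.
#' @param strict Error on invalid rows (`TRUE`, default) or drop them.
#'
#' @return `read_subjects()`: subject tibble; `write_subjects()`: `path`,
#'   invisibly.
#' @export
read_subjects <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  required <- c("id", "population", "gender", "age", "height_cm",
                "weight_kg", "ao_a_mm", "ao_s_mm", "ao_asc_mm")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("%s required.", paste(missing, collapse = ", ")))
  }
  raw$gender <- normalize_gender(raw$gender)
  num_cols <- c("age", "height_cm", "weight_kg", "ao_a_mm", "ao_s_mm", "ao_asc_mm")
  for (col in num_cols) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (strict && anyNA(v) && !anyNA(raw[[col]])) {
        abort(sprintf("unparseable numeric in column `%s`.", col))
      }
      raw[[col]] <- v
    }
  }
  ok <- validate_subject_rows(raw)
  if (!all(ok)) {
    if (strict) {
      abort(sprintf("invalid subject rows: %s",
                    paste(head(which(!ok), 10), collapse = ", ")))
    }
    warn(sprintf("dropped %d invalid subject row(s).", sum(!ok)))
    raw <- raw[ok, ]
  }
  raw$id <- as.character(raw$id)
  tibble::as_tibble(raw)
}

validate_subject_rows <- function(data) {
  with(data, {
    ok <- is.finite(age) & age >= 18 & age <= 79 &
      is.finite(height_cm) & height_cm > 0 &
      is.finite(weight_kg) & weight_kg > 0 &
      is.finite(ao_a_mm) & ao_a_mm > 0 &
      is.finite(ao_s_mm) & ao_s_mm > 0 &
      is.finite(ao_asc_mm) & ao_asc_mm > 0 &
      gender %in% c(0, 1)
    ok & compute_bmi(pmax(height_cm, 1e-9), pmax(weight_kg, 0)) < 30
  })
}

normalize_gender <- function(g) {
  if (is.numeric(g)) {
    if (!all(g %in% c(0, 1))) abort("numeric gender codes must be 0 or 1.")
    return(as.integer(g))
  }
  key <- tolower(trimws(as.character(g)))
  map <- c("0" = 0L, "1" = 1L, "m" = 0L, "f" = 1L, "man" = 0L, "woman" = 1L,
           "male" = 0L, "female" = 1L)
  out <- unname(map[key])
  if (anyNA(out)) {
    abort(sprintf("unrecognized gender token(s): %s",
                  paste(unique(key[is.na(out)]), collapse = ", ")))
  }
  out
}

#' @rdname read_subjects
#' @param data Subject tibble.
#' @export
write_subjects <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Correct and classify one subject's aortic dimensions
#'
#' The calculator workflow: given a subject's demographics and measured
#' dimensions, computes the predicted value Yp from an equation set, the
#' corrected ratio Yc = measured/Yp, and — when the equation set carries
#' reference intervals — classifies Yc as decreased/normal/increased.
#'
#' @param eqset An [equation_set()], e.g. one of [builtin_equation_sets()].
#' @param gender 0 (man) or 1 (woman).
#' @param age Age in years.
#' @param height_cm,weight_kg Body size.
#' @param dims Named list/vector of measured dimensions in mm, names among
#'   `ao_a`, `ao_s`, `ao_asc`; only the supplied parameters are evaluated.
#'
#' @return Tibble: `param`, `measured_mm`, `yp_mm`, `yc`, `classification`
#'   (`"unavailable"` when the set has no interval for a parameter).
#'
#' @examples
#' aorta_calculator(builtin_equation_sets()$chinese,
#'                  gender = 0, age = 40, height_cm = 175, weight_kg = 70,
#'                  dims = c(ao_a = 21.4))
#' @export
aorta_calculator <- function(eqset, gender, age, height_cm, weight_kg, dims) {
  stopifnot(inherits(eqset, "equation_set"))
  params <- names(dims)
  if (is.null(params) || !all(params %in% AORTIC_PARAMS)) {
    abort("`dims` must be named with parameters among ao_a, ao_s, ao_asc.")
  }
  covar <- tibble::tibble(gender = gender, age = age,
                          height_cm = height_cm, weight_kg = weight_kg)
  purrr::map_dfr(params, function(p) {
    yu <- dims[[p]]
    check_positive(yu, paste0("dims$", p))
    yp <- predict_yp(eqset$equations[[p]], covar)
    yc <- correct_yc(yu, yp)
    iv <- eqset$intervals[[p]]
    tibble::tibble(
      param = p, measured_mm = yu, yp_mm = yp, yc = yc,
      classification = if (is.null(iv)) "unavailable" else classify_subject(yc, iv)
    )
  })
}

#' Run the full indexation study pipeline on two populations
#'
#' Orchestrates the whole design end to end on two subject tables (usually
#' synthetic, via [generate_population()]): propensity-match the populations
#' on gender and age, pool a combined cohort, split each of the three
#' cohorts 7:3 into construction group A and validation group B, fit one
#' allometric equation per aortic parameter on each group A by stepwise
#' log-linear regression, correct group B with the fitted equations, assess
#' efficacy of the allometric correction and of BSA indexation under the
#' predefined success criteria, and estimate reference intervals of the
#' corrected values per population.
#'
#' @param pop1,pop2 Subject tibbles for the two populations.
#' @param seed Integer seed driving the match order and the three splits.
#' @param ratio Construction-group fraction (default 0.7).
#' @param match Propensity-match the populations first (default `TRUE`;
#'   disable when the inputs are already matched).
#' @param p_enter,p_remove Stepwise thresholds, see [fit_allometric()].
#' @param interval_method Reference-interval method, see
#'   [reference_interval()].
#'
#' @return A list of class `pipeline_result`:
#'   \describe{
#'     \item{fits}{nested list `fits[[population]][[param]]` of
#'       [fit_allometric()] results.}
#'     \item{equation_sets}{fitted [equation_set()] per population, with
#'       reference intervals attached.}
#'     \item{reports}{list of [assess_efficacy()] reports, one per
#'       population x parameter x method (omam/bsa).}
#'     \item{summary}{tibble of per-cell verdicts ([glance()] rows).}
#'     \item{success_rates}{tibble: method, success rate (%).}
#'     \item{splits, match_result, seed}{provenance.}
#'   }
#' @export
run_pipeline <- function(pop1, pop2, seed = 1L, ratio = 0.7, match = TRUE,
                         p_enter = 0.05, p_remove = 0.10,
                         interval_method = "percentile") {
  if (ratio >= 1 || ratio <= 0) abort("`ratio` must be in (0, 1) so the validation group is non-empty.")
  match_result <- NULL
  if (match) {
    match_result <- propensity_match(pop1, pop2, seed = seed)
    pop1 <- pop1[pop1$id %in% match_result$pairs$id1, ]
    pop2 <- pop2[pop2$id %in% match_result$pairs$id2, ]
  }
  cohorts <- list(dplyr::first(pop1$population), dplyr::first(pop2$population))
  combined <- dplyr::bind_rows(pop1, pop2)
  cohort_list <- setNames(list(pop1, pop2, combined),
                          c(cohorts[[1]], cohorts[[2]], "combined"))

  fits <- list(); reports <- list(); splits <- list(); eqsets <- list()
  for (pop_idx in seq_along(cohort_list)) {
    pop_name <- names(cohort_list)[pop_idx]
    cohort <- cohort_list[[pop_idx]]
    sp <- split_ab(cohort, ratio = ratio, seed = seed + pop_idx)
    splits[[pop_name]] <- sp
    grp_a <- cohort[cohort$id %in% sp$a, ]
    grp_b <- cohort[cohort$id %in% sp$b, ]
    bsa_b <- bsa_dubois(grp_b$height_cm, grp_b$weight_kg)

    pop_fits <- list(); intervals <- list()
    for (p in AORTIC_PARAMS) {
      fit <- fit_allometric(grp_a, p, p_enter = p_enter, p_remove = p_remove)
      pop_fits[[p]] <- fit
      yu <- grp_b[[paste0(p, "_mm")]]
      yc <- correct_yc(yu, predict_yp(fit$equation, grp_b))
      reports[[paste(pop_name, p, "omam", sep = ".")]] <-
        assess_efficacy(yc, yu, grp_b, param = p, population = pop_name,
                        method = "omam")
      reports[[paste(pop_name, p, "bsa", sep = ".")]] <-
        assess_efficacy(index_bsa(yu, bsa_b), yu, grp_b, param = p,
                        population = pop_name, method = "bsa")
      yc_all <- correct_yc(cohort[[paste0(p, "_mm")]],
                           predict_yp(fit$equation, cohort))
      intervals[[p]] <- reference_interval(yc_all, method = interval_method)
    }
    fits[[pop_name]] <- pop_fits
    eqsets[[pop_name]] <- equation_set(
      pop_name, purrr::map(pop_fits, "equation"), intervals = intervals
    )
  }

  summary <- dplyr::bind_rows(purrr::map(reports, glance))
  rates <- summary |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(success_rate = 100 * mean(.data$success), .groups = "drop")
  structure(
    list(fits = fits, equation_sets = eqsets, reports = reports,
         summary = summary, success_rates = rates, splits = splits,
         match_result = match_result, seed = seed, ratio = ratio),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> populations:",
      paste(names(x$fits), collapse = ", "), "\n")
  print(x$success_rates)
  invisible(x)
}
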