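#' Construct an allometric scaling equation
#'
#' An allometric equation for one aortic parameter has the multiplicative
#' form `Yp = a * b^gender * age^x * height^y * weight^z` with gender coded
#' as a dummy (man = 0, woman = 1). A covariate excluded from the model is
#' represented by exponent exactly 0 (gender exclusion by `b = 1`), so the
#' corresponding factor is identically 1.
#'
#' @param param Aortic parameter code: one of `"ao_a"`, `"ao_s"`, `"ao_asc"`
#'   (annulus, sinuses of Valsalva, proximal ascending aorta).
#' @param a Scaling constant (mm); must be positive.
#' @param b Gender factor applied as `b^gender`; must be positive. 1 when
#'   gender is not in the model.
#' @param x,y,z Exponents for age (years), height (cm) and weight (kg);
#'   0 when the covariate is not in the model.
#' @param provenance Free-text origin tag, e.g. `"fitted"` or a built-in
#'   set name.
#'
#' @return An object of class `allometric_equation`.
#'
#' @examples
#' eq <- allometric_equation("ao_a", a = 9.593, b = 0.943, x = 0.054, z = 0.142)
#' predict_yp(eq, tibble::tibble(gender = 0, age = 40, height_cm = 175, weight_kg = 70))
#' @export
allometric_equation <- function(param, a, b = 1, x = 0, y = 0, z = 0,
                                provenance = "fitted") {
  param <- match.arg(param, AORTIC_PARAMS)
  for (v in list(a = a, b = b)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort("`a` and `b` must be positive scalars.")
    }
  }
  for (v in list(x = x, y = y, z = z)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort("exponents `x`, `y`, `z` must be finite scalars.")
    }
  }
  structure(
    list(param = param, a = a, b = b, x = x, y = y, z = z,
         provenance = provenance),
    class = "allometric_equation"
  )
}

#' @export
format.allometric_equation <- function(x, ...) {
  covar <- c(
    if (x$b != 1) sprintf("%.3f^gender", x$b),
    if (x$x != 0) sprintf("age^%.3f", x$x),
    if (x$y != 0) sprintf("height^%.3f", x$y),
    if (x$z != 0) sprintf("weight^%.3f", x$z)
  )
  rhs <- paste(c(sprintf("%.3f", x$a), covar), collapse = " × ")
  sprintf("%s = %s", x$param, rhs)
}

#' @export
print.allometric_equation <- function(x, ...) {
  cat("<allometric_equation> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Predict an aortic dimension from an allometric equation
#'
#' Evaluates `Yp = a * b^gender * age^x * height^y * weight^z` for each row
#' of a subject table. Only the covariates with a nonzero exponent (or
#' `b != 1` for gender) are required; absent terms contribute a factor of 1.
#'
#' @param equation An [allometric_equation()].
#' @param data Data frame of subjects with (as needed) columns `gender`
#'   (0 = man, 1 = woman), `age` (years), `height_cm`, `weight_kg`.
#'
#' @return Numeric vector of predicted dimensions in mm, one per row.
#' @export
predict_yp <- function(equation, data) {
  stopifnot(inherits(equation, "allometric_equation"))
  data <- as.data.frame(data)
  need <- function(col, used) {
    if (!used) return(NULL)
    if (!col %in% names(data) || anyNA(data[[col]])) {
      abort(sprintf("equation for %s needs non-missing `%s`.",
                    equation$param, col))
    }
    data[[col]]
  }
  n <- nrow(data)
  yp <- rep(equation$a, n)
  g <- need("gender", equation$b != 1)
  if (!is.null(g)) {
    if (!all(g %in% c(0, 1))) abort("`gender` must be coded 0 (man) / 1 (woman).")
    yp <- yp * equation$b^g
  }
  for (term in list(list("age", equation$x), list("height_cm", equation$y),
                    list("weight_kg", equation$z))) {
    v <- need(term[[1]], term[[2]] != 0)
    if (!is.null(v)) {
      if (any(v <= 0)) abort(sprintf("`%s` must be positive.", term[[1]]))
      yp <- yp * v^term[[2]]
    }
  }
  yp
}

#' Bundle one equation per aortic parameter into a set
#'
#' @param population Population label, e.g. `"chinese"`.
#' @param equations Named list with one [allometric_equation()] for each of
#'   `ao_a`, `ao_s`, `ao_asc`.
#' @param intervals Optional named list of [reference_interval()] results
#'   (one per parameter), used by [aorta_calculator()] for classification.
#'
#' @return An object of class `equation_set`.
#' @export
equation_set <- function(population, equations, intervals = NULL) {
  if (!setequal(names(equations), AORTIC_PARAMS)) {
    abort("`equations` must be a named list covering ao_a, ao_s, ao_asc.")
  }
  for (p in AORTIC_PARAMS) {
    eq <- equations[[p]]
    if (!inherits(eq, "allometric_equation") || eq$param != p) {
      abort(sprintf("`equations$%s` must be an allometric_equation for %s.", p, p))
    }
  }
  structure(
    list(population = population, equations = equations[AORTIC_PARAMS],
         intervals = intervals),
    class = "equation_set"
  )
}

#' @export
print.equation_set <- function(x, ...) {
  cat("<equation_set> population:", x$population, "\n")
  for (eq in x$equations) cat("  ", format(eq), "\n", sep = "")
  if (!is.null(x$intervals)) cat("  (reference intervals attached)\n")
  invisible(x)
}

#' Built-in published equation sets
#'
#' Returns the three published equation sets for the Chinese, Italian and
#' combined Chinese-Italian healthy adult populations, together with the
#' published reference intervals of the corrected values where available
#' (Chinese and Italian populations). These are read-only transcriptions
#' of the reported coefficients; they also serve as generating truths for
#' [default_population_specs()].
#'
#' @return Named list of three [equation_set()] objects:
#'   `chinese`, `italian`, `combined`.
#'
#' @examples
#' builtin_equation_sets()$chinese
#' @export
builtin_equation_sets <- function() {
  eq <- function(param, a, b, x, y, z, prov) {
    allometric_equation(param, a = a, b = b, x = x, y = y, z = z,
                        provenance = prov)
  }
  ri <- function(mean, sd, lower, upper, n) {
    structure(
      list(mean = mean, sd = sd, lower = lower, upper = upper,
           method = "published", n = n, degenerate = FALSE),
      class = "reference_interval"
    )
  }
  list(
    chinese = equation_set(
      "chinese",
      list(
        ao_a   = eq("ao_a",   9.593, 0.943, 0.054, 0,     0.142, "published:chinese"),
        ao_s   = eq("ao_s",   8.085, 0.949, 0.113, 0,     0.210, "published:chinese"),
        ao_asc = eq("ao_asc", 5.028, 0.966, 0.161, 0,     0.261, "published:chinese")
      ),
      intervals = list(
        ao_a   = ri(1.002, 0.112, 0.794, 1.246, 910),
        ao_s   = ri(1.003, 0.105, 0.792, 1.213, 910),
        ao_asc = ri(1.006, 0.122, 0.747, 1.262, 910)
      )
    ),
    italian = equation_set(
      "italian",
      list(
        ao_a   = eq("ao_a",   1.042, 0.944, 0.054, 0.472, 0.081, "published:italian"),
        ao_s   = eq("ao_s",   2.268, 0.925, 0.164, 0.317, 0.090, "published:italian"),
        ao_asc = eq("ao_asc", 6.385, 0.956, 0.204, 0,     0.175, "published:italian")
      ),
      intervals = list(
        ao_a   = ri(1.007, 0.086, 0.854, 1.188, 910),
        ao_s   = ri(1.004, 0.090, 0.834, 1.185, 910),
        ao_asc = ri(1.006, 0.099, 0.802, 1.195, 910)
      )
    ),
    combined = equation_set(
      "combined",
      list(
        ao_a   = eq("ao_a",   2.948, 0.928, 0.060, 0.338, 0,     "published:combined"),
        ao_s   = eq("ao_s",   2.689, 0.950, 0.137, 0.210, 0.198, "published:combined"),
        ao_asc = eq("ao_asc", 4.375, 0.974, 0.180, 0,     0.280, "published:combined")
      )
    )
  )
}

#' Read / write equation sets as JSON
#'
#' Equation sets serialise to a plain JSON document:
#' `{"population": ..., "equations": [{"param","a","b","x","y","z"}...],
#' "intervals": ...}`. The round trip is lossless.
#'
#' @param x An [equation_set()].
#' @param path File path.
#'
#' @return `write_equation_set()` returns `path` invisibly;
#'   `read_equation_set()` returns an [equation_set()].
#' @export
write_equation_set <- function(x, path) {
  stopifnot(inherits(x, "equation_set"))
  eqs <- purrr::map(unname(x$equations), function(e) {
    list(param = e$param, a = e$a, b = e$b, x = e$x, y = e$y, z = e$z,
         provenance = e$provenance)
  })
  doc <- list(population = x$population, equations = eqs)
  if (!is.null(x$intervals)) {
    doc$intervals <- purrr::map(x$intervals, function(iv) {
      list(mean = iv$mean, sd = iv$sd, lower = iv$lower, upper = iv$upper,
           method = iv$method, n = iv$n)
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_equation_set
#' @export
read_equation_set <- function(path) {
  doc <- jsonlite::read_json(path)
  eqs <- purrr::map(doc$equations, function(e) {
    allometric_equation(e$param, a = e$a, b = e$b, x = e$x, y = e$y, z = e$z,
                        provenance = e$provenance %||% "file")
  })
  names(eqs) <- purrr::map_chr(eqs, "param")
  ivs <- NULL
  if (!is.null(doc$intervals)) {
    ivs <- purrr::map(doc$intervals, function(iv) {
      structure(
        list(mean = iv$mean, sd = iv$sd, lower = iv$lower, upper = iv$upper,
             method = iv$method, n = iv$n, degenerate = iv$lower == iv$upper),
        class = "reference_interval"
      )
    })
  }
  equation_set(doc$population, eqs, intervals = ivs)
}

#' Add model predictions and corrected ratios to a subject table
#'
#' For each aortic parameter with a measured column `<param>_mm` present,
#' appends `yp_<param>` (predicted mm) and `yc_<param>` (corrected ratio
#' Yu/Yp) columns.
#'
#' @param data Subject tibble (see [read_subjects()] for the schema).
#' @param eqset An [equation_set()].
#'
#' @return The input tibble with prediction/correction columns appended.
#' @export
add_corrections <- function(data, eqset) {
  stopifnot(inherits(eqset, "equation_set"))
  data <- tibble::as_tibble(data)
  for (p in AORTIC_PARAMS) {
    mcol <- paste0(p, "_mm")
    if (!mcol %in% names(data)) next
    yp <- predict_yp(eqset$equations[[p]], data)
    data[[paste0("yp_", p)]] <- yp
    data[[paste0("yc_", p)]] <- correct_yc(data[[mcol]], yp)
  }
  data
}
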