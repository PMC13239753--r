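#' Propensity-score matching of two populations
#'
#' Pairs subjects across two populations 1:1 by nearest propensity score, to
#' balance gender and age before cross-population comparison. The propensity
#' is the fitted probability of belonging to the second population given
#' gender and age, from a binomial logistic model on the pooled sample;
#' matching is greedy nearest-neighbour on the logit scale, without
#' replacement, with subjects of the smaller population processed in seeded
#' random order.
#'
#' @param pop1,pop2 Subject tibbles; each needs `id`, `gender`, `age`.
#' @param seed Integer seed controlling the processing order.
#' @param caliper `NULL` (default) for no caliper, `"auto"` for the
#'   conventional 0.2 x SD of the logit propensity, or a positive number
#'   (logit-scale width). Pairs whose distance exceeds the caliper are
#'   discarded.
#'
#' @return A list of class `match_result`: `pairs` (tibble: `id1`, `id2`,
#'   `distance`), `unmatched1`, `unmatched2` (character ids), `caliper`,
#'   `seed`.
#' @export
propensity_match <- function(pop1, pop2, seed = 1L, caliper = NULL) {
  for (d in list(pop1, pop2)) {
    if (nrow(d) == 0) abort("both populations must be non-empty.")
    if (anyNA(d$gender) || anyNA(d$age)) abort("gender and age required for all subjects.")
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(pop1[, c("id", "gender", "age")], .grp = 0),
    dplyr::mutate(pop2[, c("id", "gender", "age")], .grp = 1)
  )
  fit <- suppressWarnings(glm(.grp ~ gender + age, family = binomial(), data = pooled))
  lp <- unname(predict(fit, type = "link"))
  prob <- plogis(lp)
  if (any(prob > 1 - 1e-8) || any(prob < 1e-8)) {
    # complete separation: no common support. With a caliper the distances
    # exceed it and zero pairs fall out naturally; without one, nearest
    # neighbour would pair arbitrarily, so refuse.
    if (is.null(caliper)) {
      abort("logistic propensity model separates the populations; use exact matching or a caliper.")
    }
  }
  lp1 <- lp[pooled$.grp == 0]
  lp2 <- lp[pooled$.grp == 1]
  cal <- if (is.null(caliper)) {
    Inf
  } else if (identical(caliper, "auto")) {
    0.2 * sd(lp)
  } else {
    stopifnot(is.numeric(caliper), caliper > 0)
    caliper
  }

  swap <- nrow(pop2) < nrow(pop1)
  small_lp <- if (swap) lp2 else lp1
  large_lp <- if (swap) lp1 else lp2
  small_id <- if (swap) pop2$id else pop1$id
  large_id <- if (swap) pop1$id else pop2$id

  ord <- local_seed(seed, sample.int(length(small_lp)))
  avail <- rep(TRUE, length(large_lp))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (i in ord) {
    d <- abs(large_lp - small_lp[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal) {
      avail[j] <- FALSE
      out_i <- c(out_i, i); out_j <- c(out_j, j); out_d <- c(out_d, d[j])
    }
  }
  pairs <- tibble::tibble(
    id1 = if (swap) large_id[out_j] else small_id[out_i],
    id2 = if (swap) small_id[out_i] else large_id[out_j],
    distance = out_d
  )
  structure(
    list(pairs = pairs,
         unmatched1 = setdiff(pop1$id, pairs$id1),
         unmatched2 = setdiff(pop2$id, pairs$id2),
         caliper = cal, seed = seed),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pairs; unmatched: ",
      length(x$unmatched1), " / ", length(x$unmatched2), "\n", sep = "")
  invisible(x)
}

#' Randomized construction/validation split
#'
#' Randomly partitions a cohort into a construction group A (for fitting the
#' allometric equations) and a validation group B, at a given ratio. The
#' permutation is seeded; group A takes the first `floor(ratio * n)` subjects
#' of the permuted order, so n = 910 at ratio 0.7 gives exactly 637 / 273.
#'
#' @param data Subject tibble with an `id` column.
#' @param ratio Fraction assigned to group A, in (0, 1). Default 0.7.
#' @param seed Integer seed.
#'
#' @return A list of class `split_result`: `a`, `b` (character id vectors),
#'   `ratio`, `seed`.
#' @export
split_ab <- function(data, ratio = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 10) abort("cohort too small to split (n >= 10 required).")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    abort("`ratio` must be in (0, 1).")
  }
  perm <- local_seed(seed, sample.int(n))
  n_a <- floor(ratio * n)
  structure(
    list(a = data$id[perm[seq_len(n_a)]],
         b = data$id[perm[-seq_len(n_a)]],
         ratio = ratio, seed = seed),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> |A| = ", length(x$a), ", |B| = ", length(x$b),
      " (ratio ", x$ratio, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Age-group stratification
#'
#' Maps ages to the three strata used for descriptive comparisons: young
#' (18-40 y), middle-aged (> 40 to 65 y), elderly (> 65 y). Ages are treated
#' as continuous; the open boundaries cover fractional ages between the
#' integer band edges.
#'
#' @param age Numeric vector of ages in years; must lie in \[18, 79\].
#'
#' @return Factor with levels `young`, `middle`, `elderly`.
#' @export
assign_age_group <- function(age) {
  if (anyNA(age) || any(age < 18 | age > 79)) {
    abort("ages must lie within the cohort range [18, 79].")
  }
  cut(age, breaks = c(18, 40, 65, 79), include.lowest = TRUE,
      labels = c("young", "middle", "elderly"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
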