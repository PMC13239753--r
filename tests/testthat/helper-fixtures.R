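# Small deterministic subject table for hand-checkable tests.
toy_subjects <- function(n = 8) {
  set.seed(99)
  tibble::tibble(
    id = sprintf("s%02d", seq_len(n)),
    population = "toy",
    gender = rep(c(0, 1), length.out = n),
    age = seq(25, 70, length.out = n),
    height_cm = seq(155, 185, length.out = n),
    weight_kg = seq(50, 85, length.out = n),
    ao_a_mm = 20 + seq_len(n) / 10,
    ao_s_mm = 28 + seq_len(n) / 10,
    ao_asc_mm = 26 + seq_len(n) / 10
  )
}

chinese_ao_a_eq <- function() {
  allometric_equation("ao_a", a = 9.593, b = 0.943, x = 0.054, z = 0.142)
}

# Brute-force check that a retained term subset is a stepwise fixed point:
# every retained term is significant at p_remove, and no excluded candidate
# would enter below p_enter given the retained set.
is_stepwise_fixed_point <- function(design, retained, candidates,
                                    p_enter = 0.05, p_remove = 0.10) {
  pval <- function(terms, term) {
    tab <- fit_ols(design, terms)$coefficients
    tab$p.value[match(term, tab$term)]
  }
  keep_ok <- all(vapply(retained, function(v) pval(retained, v) < p_remove,
                        logical(1)))
  out <- setdiff(candidates, retained)
  enter_ok <- all(vapply(out, function(v) pval(c(retained, v), v) >= p_enter,
                         logical(1)))
  keep_ok && enter_ok
}
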