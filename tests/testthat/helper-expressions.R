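# shared helpers: fixed seed for randomised property checks, random
# expression generators, and a terse symbolic-equality expectation

PROP_SEED <- 20140708

expect_sym_equal <- function(e1, e2, ...) {
  res <- symbolic_equal(e1, e2, ...)
  expect_true(res$equal,
              info = paste("difference:", res$certificate))
  invisible(res)
}

expect_sym_zero <- function(e) {
  expect_identical(expr_text(e), "0")
}

# random polynomial in x, degree <= deg, small integer coefficients
random_poly <- function(deg = 3) {
  coefs <- sample(-4:4, deg + 1, replace = TRUE)
  e <- hdm_expr("0")
  for (k in 0:deg)
    e <- expr_add(e, expr_mul(hdm_expr(as.character(coefs[k + 1])),
                              hdm_expr(sprintf("x^%d", k))))
  e
}

# random per-order two-field terms for He-polynomial checks
random_terms <- function(orders, deg = 3) {
  lapply(seq_len(orders + 1), function(i)
    list(u = random_poly(deg), rho = random_poly(deg)))
}
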