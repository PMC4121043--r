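make_heat_problem <- function(init = "m*exp(-x^2)") {
  general_problem(
    fields = "u", initial = list(u = init),
    linear = function(prev) list(u = expr_mul("a", expr_deriv(prev$u, "x", 2))))
}

test_that("initial_guess builds the time-Taylor polynomial from initial data", {
  # first-order problems return the initial condition unchanged
  p <- make_heat_problem()
  expect_sym_equal(initial_guess(p)$u, "m*exp(-x^2)")
  # second-order data y0 = x, y1 = 2x gives the two-term Taylor polynomial
  p2 <- general_problem(
    fields = "u", initial = list(u = list("x", "2*x")),
    linear = function(prev) list(u = expr_deriv(prev$u, "x", 2)),
    time_order = 2)
  expect_sym_equal(initial_guess(p2)$u, "x + 2*x*t")
  # zero data gives the zero guess
  p0 <- make_heat_problem(init = "0")
  expect_sym_zero(initial_guess(p0)$u)
  # a missing entry is a specification error naming the index
  expect_error(
    general_problem(fields = "u", initial = list(u = list()),
                    linear = function(prev) list(u = prev$u)),
    "y_0")
  expect_error(
    general_problem(fields = c("u", "rho"), initial = list(u = "x"),
                    linear = function(prev) prev),
    "rho")
})

test_that("the linear operator additivity spot-check rejects non-additive maps", {
  set.seed(PROP_SEED)
  expect_error(
    general_problem(fields = "u", initial = list(u = "x"),
                    linear = function(prev) list(u = expr_mul(prev$u, prev$u))),
    "additivity")
  # and accepts a genuinely linear one
  expect_s3_class(make_heat_problem(), "hdm_problem")
})

test_that("He polynomials: p-extraction matches the defining expansion", {
  set.seed(PROP_SEED)
  sq <- function(f) expr_mul(f$u, f$u)      # N(U) = U^2
  terms <- random_terms(3)
  h0 <- he_polynomial_bruteforce(sq, terms, 0, fields = "u")
  expect_sym_equal(h0, expr_mul(terms[[1]]$u, terms[[1]]$u))
  h1 <- he_polynomial_bruteforce(sq, terms, 1, fields = "u")
  expect_sym_equal(h1, expr_mul("2", expr_mul(terms[[1]]$u, terms[[2]]$u)))
  # completeness: sum of H_0..H_3 reproduces every p-order <= 3 of N(sum p^j U_j)
  p <- hdm_expr("p")
  packed <- hdm_expr("0")
  for (j in 0:3)
    packed <- expr_add(packed, expr_mul(hdm_expr(sprintf("p^%d", j)), terms[[j + 1]]$u))
  full <- expr_mul(packed, packed)
  lhs <- hdm_expr("0")
  for (k in 0:3) lhs <- expr_add(lhs, expr_coeff(full, "p", k))
  rhs <- hdm_expr("0")
  for (k in 0:3) rhs <- expr_add(rhs, he_polynomial_bruteforce(sq, terms, k, fields = "u"))
  expect_sym_equal(lhs, rhs)
  # no occurrence of the embedding parameter survives
  expect_false("p" %in% hdmks:::px_symbols(h1))
})

test_that("convolution and brute-force He constructions agree on product forms", {
  set.seed(PROP_SEED)
  bilinear <- list(list(coef = -1, factors = list(
    list(field = "u", deriv = 1), list(field = "rho", deriv = 1))))
  bi_op <- function(f) expr_mul("-1", expr_mul(expr_deriv(f$u, "x"),
                                               expr_deriv(f$rho, "x")))
  trilinear <- list(list(coef = 1, factors = list(
    list(field = "u", deriv = 0), list(field = "rho", deriv = 1),
    list(field = "rho", deriv = 1))))
  tri_op <- function(f) {
    rx <- expr_deriv(f$rho, "x")
    expr_mul(f$u, expr_mul(rx, rx))
  }
  for (i in 1:20) {
    n <- sample(0:5, 1)
    terms <- random_terms(n)
    expect_sym_equal(he_polynomial_convolution(bilinear, terms, n),
                     he_polynomial_bruteforce(bi_op, terms, n, c("u", "rho")))
    expect_sym_equal(he_polynomial_convolution(trilinear, terms, n),
                     he_polynomial_bruteforce(tri_op, terms, n, c("u", "rho")))
  }
  # single cross term at order 1 of the bilinear form
  terms <- random_terms(1)
  expect_sym_equal(
    he_polynomial_convolution(bilinear, terms, 1),
    expr_add(
      expr_mul("-1", expr_mul(expr_deriv(terms[[1]]$u, "x"),
                              expr_deriv(terms[[2]]$rho, "x"))),
      expr_mul("-1", expr_mul(expr_deriv(terms[[2]]$u, "x"),
                              expr_deriv(terms[[1]]$rho, "x")))))
  # non-product forms are rejected with a pointer to the brute-force path
  expect_error(
    he_polynomial_convolution(list(list(coef = 1, factors = list())), terms, 1),
    "product form")
})

test_that("the quoted-expression He path handles non-polynomial operators", {
  set.seed(PROP_SEED)
  # N(U) = U^2 has the classical quadratic He polynomials
  terms <- list(list(u = "u0x"), list(u = "u1x"), list(u = "u2x"))
  h2 <- he_polynomial_quoted(quote(u^2), terms, 2, fields = "u")
  expect_true(symbolic_equal(h2, quote(u1x^2 + 2 * u0x * u2x))$equal)
  # smooth non-polynomial operator: N(U) = exp(U); H_1 = U1 exp(U0)
  h1 <- he_polynomial_quoted(quote(exp(u)), terms, 1, fields = "u")
  expect_true(symbolic_equal(h1, quote(u1x * exp(u0x)))$equal)
})

test_that("hdm_solve emits contiguous orders with vanishing higher terms at t = 0", {
  # stationary problem: L = 0, N = 0, f = 0 freezes the initial state
  p <- general_problem(fields = "u", initial = list(u = "m*exp(-x^2)"),
                       linear = function(prev) list(u = hdm_expr("0")))
  s <- hdm_solve(p, 3)
  expect_identical(s$truncation, 3L)
  for (k in 1:3) expect_sym_zero(series_term(s, "u", k))
  # heat problem: orders are contiguous, terms vanish at t = 0, order 0 is the datum
  s <- hdm_solve(make_heat_problem(), 4)
  expect_length(s$terms, 5L)
  expect_sym_equal(series_term(s, "u", 0), "m*exp(-x^2)")
  xs <- seq(-2, 2, length.out = 7)
  for (k in 1:4) {
    v <- expr_eval(series_term(s, "u", k), list(a = 0.7, m = 2, x = xs, t = 0))
    expect_identical(unique(v), 0)
  }
  # forcing enters at order 1 only
  pf <- general_problem(fields = "u", initial = list(u = "0"),
                        linear = function(prev) list(u = hdm_expr("0")),
                        forcing = list(u = hdm_expr("x")))
  sf <- hdm_solve(pf, 3)
  expect_sym_equal(series_term(sf, "u", 1), "x*t")
  expect_sym_zero(series_term(sf, "u", 2))
})

test_that("constant-sensitivity u-terms follow the iterated-diffusion closed form", {
  # u_n = a^n t^n / n! * d^(2n) u0 / dx^(2n), provable by induction on the recursion
  s <- hdm_solve(make_heat_problem(), 4)
  u0 <- hdm_expr("m*exp(-x^2)")
  for (n in 1:4) {
    expected <- expr_mul(hdm_expr(sprintf("a^%d*t^%d/%d", n, n, factorial(n))),
                         expr_deriv(u0, "x", 2 * n))
    expect_sym_equal(series_term(s, "u", n), expected)
  }
})

test_that("series partial sums and serialisation helpers are consistent", {
  s <- hdm_solve(make_heat_problem(), 3)
  ps <- partial_sum(s, "u", 2)
  manual <- expr_add(expr_add(series_term(s, "u", 0), series_term(s, "u", 1)),
                     series_term(s, "u", 2))
  expect_sym_equal(ps, manual)
  df <- as.data.frame(s)
  expect_identical(nrow(df), 4L)
  expect_identical(df$expression[1], expr_text(series_term(s, "u", 0)))
})
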