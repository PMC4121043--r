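# Generic homotopy decomposition recursion: initial guess from the time-
# Taylor data, Abel-kernel inversion of the time derivative, He-polynomial
# decomposition of the nonlinearity, and order-by-order term emission.

#' Specify a general evolution problem for the homotopy decomposition solver
#'
#' Describes a (system of) PDE(s) of the form
#' `d^m U / dt^m = L(U) + N(U) + f(x, t)` with time-Taylor initial data.  By
#' the scheme's convention the `(m-1)`-th time derivative at `t = 0` is zero,
#' so for time order `m` each field carries `m - 1` initial functions (one
#' function for `m = 1`); a full list of `m` functions is also accepted.
#'
#' @param fields character vector naming the unknown fields (e.g. `"u"` or
#'   `c("u", "rho")`).
#' @param initial named list: for each field, an expression (or list of
#'   expressions) in `x` giving the initial data `y_0, y_1, ...`.
#' @param linear function of a named list of expressions (the previous-order
#'   terms, one per field) returning a named list: the linear operator
#'   applied fieldwise.  Must be additive; this is spot-checked on random
#'   fields at construction.
#' @param nonlinear `NULL`, or a function `(terms, n)` returning the named
#'   list of order-`n` nonlinear integrand contributions (the He polynomial
#'   of order `n - 1`), where `terms` is the list of per-order named term
#'   lists computed so far (orders `0 .. n-1`).
#' @param forcing `NULL` or a named list of expressions `f(x, t)`; enters the
#'   recursion at order 1 only (it carries no power of the embedding
#'   parameter).
#' @param time_order positive integer `m`.
#' @param check_linearity spot-check additivity of `linear` on 3 random
#'   polynomial fields (default `TRUE`).
#' @return an object of class `hdm_problem`.
#' @export
general_problem <- function(fields, initial, linear, nonlinear = NULL,
                            forcing = NULL, time_order = 1,
                            check_linearity = TRUE) {
  m <- as.integer(time_order)
  stopifnot(m >= 1, is.character(fields), length(fields) >= 1)
  need <- if (m == 1) 1L else m - 1L
  init <- list()
  for (f in fields) {
    if (!f %in% names(initial))
      stop("missing initial data for field '", f, "'")
    yi <- initial[[f]]
    if (px_is(yi) || !is.list(yi)) yi <- list(yi)
    yi <- lapply(yi, as_pexpr)
    if (length(yi) < need)
      stop("field '", f, "': initial data entry y_", length(yi),
           " is missing (time order ", m, " requires ", need, " function(s))")
    if (length(yi) > m)
      stop("field '", f, "': too many initial data entries for time order ", m)
    init[[f]] <- yi
  }
  if (check_linearity) .check_linear(linear, fields)
  if (!is.null(forcing)) forcing <- lapply(forcing, as_pexpr)
  structure(list(fields = fields, time_order = m, initial = init,
                 linear = linear, nonlinear = nonlinear, forcing = forcing),
            class = "hdm_problem")
}

.check_linear <- function(linear, fields) {
  rnd <- function() {
    k <- sample(0:3, 1)
    px_add(px_scale(px_pow(px_sym("x"), k), sample(-5:5, 1)),
           px_scale(px_sym("x"), sample(-5:5, 1)))
  }
  for (rep in 1:3) {
    f1 <- stats::setNames(lapply(fields, function(.) rnd()), fields)
    f2 <- stats::setNames(lapply(fields, function(.) rnd()), fields)
    fs <- stats::setNames(Map(px_add, f1, f2), fields)
    lhs <- linear(fs)
    rhs <- Map(px_add, linear(f1), linear(f2))
    for (f in fields) {
      if (!px_is_zero(px_sub(as_pexpr(lhs[[f]]), as_pexpr(rhs[[f]]))))
        stop("linear operator fails additivity spot-check on field '", f, "'")
    }
  }
  invisible(TRUE)
}

#' Initial guess of the homotopy decomposition scheme
#'
#' Builds the time-Taylor polynomial `T(x,t) = sum_k t^k/k! y_k(x)` from the
#' problem's initial data; this is the order-0 series term.  For time order
#' 1 it returns the initial condition unchanged.
#'
#' @param problem an [general_problem()] object.
#' @return named list of expressions, one per field.
#' @export
initial_guess <- function(problem) {
  stopifnot(inherits(problem, "hdm_problem"))
  out <- list()
  for (f in problem$fields) {
    yi <- problem$initial[[f]]
    T <- px_zero()
    for (k in seq_along(yi)) {
      fac <- q_rat(1, factorial(k - 1))
      T <- px_add(T, px_scale(px_mul(yi[[k]], px_pow(px_sym("t"), k - 1)), fac))
    }
    out[[f]] <- T
  }
  out
}

## ---- He polynomials ------------------------------------------------------

#' He polynomial by the defining p-derivative construction
#'
#' Constructs `N(sum_j p^j U_j)` with the embedding parameter `p` carried as
#' an explicit symbol, and extracts the coefficient of `p^n` — the exact
#' symbolic realisation of `H_n = (1/n!) d^n/dp^n N(.) |_{p=0}` for operators
#' polynomial in the fields and their spatial derivatives.  The result never
#' contains `p`.
#'
#' @param nonlinear_op function of a named list of expressions (one per
#'   field) returning an expression; must be built from the kernel's
#'   operations (products, sums, [expr_deriv()]).
#' @param terms list of named lists of expressions: series terms of orders
#'   `0..n` (at least), as produced by [hdm_solve()].
#' @param n order of the polynomial (nonnegative integer).
#' @param fields field names; defaults to the names of `terms[[1]]`.
#' @return expression: the order-`n` He polynomial.
#' @export
he_polynomial_bruteforce <- function(nonlinear_op, terms, n, fields = NULL) {
  if (is.null(fields)) fields <- names(terms[[1]])
  stopifnot(length(terms) >= n + 1)
  p <- px_sym("p")
  packed <- list()
  for (f in fields) {
    s <- px_zero()
    for (j in 0:n)
      s <- px_add(s, px_mul(px_pow(p, j), as_pexpr(terms[[j + 1]][[f]])))
    packed[[f]] <- s
  }
  full <- as_pexpr(nonlinear_op(packed))
  .px_coeff(full, "p", n)
}

.px_coeff <- function(e, var, k) {
  out <- list()
  for (mo in unclass(e)) {
    kk <- if (!is.null(mo$pow) && var %in% names(mo$pow)) mo$pow[[var]] else 0
    if (kk == k) {
      mo$pow <- mo$pow[names(mo$pow) != var]
      if (length(mo$pow) == 0) mo$pow <- NULL
      out[[length(out) + 1]] <- mo
    }
  }
  px_norm(out)
}

#' He polynomial of a product-form nonlinearity by discrete convolution
#'
#' For a nonlinearity that is a sum of products of at most three field
#' factors (each possibly spatially differentiated), the order-`n` He
#' polynomial is the discrete convolution over term orders: for each product
#' of `k` factors, the sum over all order tuples `(j_1, ..., j_k)` with
#' `j_1 + ... + j_k = n` of the factor products.  No embedding-parameter
#' differentiation is involved, so this is an independent route that must
#' agree with [he_polynomial_bruteforce()].
#'
#' @param spec list of summands; each summand is
#'   `list(coef = <number>, factors = list(list(field = <name>, deriv = <order>), ...))`.
#' @param terms,n,fields as in [he_polynomial_bruteforce()].
#' @return expression: the order-`n` He polynomial.
#' @export
he_polynomial_convolution <- function(spec, terms, n, fields = NULL) {
  stopifnot(length(terms) >= n + 1)
  for (s in spec) {
    if (is.null(s$factors) || length(s$factors) < 1 || length(s$factors) > 3)
      stop("nonlinearity is not in supported product form (1-3 factors per summand)")
  }
  total <- px_zero()
  for (s in spec) {
    k <- length(s$factors)
    combos <- .compositions(n, k)
    part <- px_zero()
    for (ci in seq_len(nrow(combos))) {
      prod <- px_num(1)
      for (fi in seq_len(k)) {
        fac <- s$factors[[fi]]
        term <- as_pexpr(terms[[combos[ci, fi] + 1]][[fac$field]])
        if (!is.null(fac$deriv) && fac$deriv > 0)
          term <- px_deriv(term, "x", fac$deriv)
        prod <- px_mul(prod, term)
      }
      part <- px_add(part, prod)
    }
    total <- px_add(total, px_scale(part, s$coef))
  }
  total
}

# all k-tuples of nonnegative integers summing to n (rows)
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (j in 0:n) {
    rest <- .compositions(n - j, k - 1)
    out <- rbind(out, cbind(j, rest))
  }
  unname(out)
}

#' He polynomial for arbitrary smooth operators via base-R differentiation
#'
#' The fully general construction: builds the quoted R expression
#' `N(sum_j p^j U_j)`, differentiates it `n` times with respect to the
#' embedding parameter `p` using [stats::D()], divides by `n!` and sets
#' `p = 0`.  Works for any operator smooth in the fields (including
#' non-polynomial sensitivity functions such as `log(rho)` or
#' `rho/(rho+1)`); the result is a quoted R expression suitable for numeric
#' evaluation, not necessarily inside the canonical kernel class.
#'
#' @param nonlinear_quote quoted R expression (or string) in the field
#'   symbols named by `fields`; spatial derivatives of the packed fields are
#'   not differentiated here, so express the operator directly in the packed
#'   field symbols (apply spatial derivatives to `terms` beforehand where
#'   needed, or pass fields like `u_x` explicitly).
#' @param terms list of per-order named lists of quoted expressions (or
#'   strings) for each field symbol appearing in `nonlinear_quote`.
#' @param n order (nonnegative integer).
#' @param fields character vector of field symbols to pack.
#' @return quoted R expression free of `p`.
#' @export
he_polynomial_quoted <- function(nonlinear_quote, terms, n, fields) {
  if (is.character(nonlinear_quote)) nonlinear_quote <- str2lang(nonlinear_quote)
  subs <- list()
  for (f in fields) {
    s <- quote(0)
    for (j in 0:n) {
      tj <- terms[[j + 1]][[f]]
      if (px_is(tj)) tj <- str2lang(px_str(tj))
      if (is.character(tj)) tj <- str2lang(tj)
      s <- bquote(.(s) + p^.(j) * (.(tj)))
    }
    subs[[f]] <- s
  }
  packed <- eval(call("substitute", nonlinear_quote, subs))
  dn <- packed
  if (n > 0) for (i in seq_len(n)) dn <- stats::D(dn, "p")
  at0 <- eval(call("substitute", dn, list(p = 0)))
  if ("p" %in% all.vars(at0))
    stop("he_polynomial_quoted: operator not differentiable to order ", n, " in p")
  bquote((.(at0)) / .(factorial(n)))
}

## ---- solver --------------------------------------------------------------

#' Solve a problem by the homotopy decomposition recursion
#'
#' Emits series terms order by order: the order-0 term is the initial guess;
#' for `n >= 1` the order-`n` term is the Abel inverse of
#' `L(term_{n-1}) + H_{n-1} + [n = 1] f`.  If a symbolic step fails at order
#' `k`, the orders `0 .. k-1` computed so far are returned with a diagnostic
#' naming the failing order.
#'
#' @param problem an [general_problem()] object.
#' @param N truncation order (nonnegative integer).
#' @return an object of class `hdm_series` with elements `terms` (list of
#'   per-order named expression lists, orders `0..N`), `truncation`,
#'   `fields`, `problem`, and `diagnostic` (`NULL` on full success).
#' @export
hdm_solve <- function(problem, N = 4) {
  stopifnot(inherits(problem, "hdm_problem"), N >= 0)
  m <- problem$time_order
  terms <- list(initial_guess(problem))
  diagnostic <- NULL
  for (n in seq_len(N)) {
    res <- tryCatch({
      prev <- terms[[n]]
      integrand <- problem$linear(prev)
      integrand <- stats::setNames(lapply(problem$fields, function(f)
        as_pexpr(integrand[[f]])), problem$fields)
      if (!is.null(problem$nonlinear)) {
        nl <- problem$nonlinear(terms, n)
        for (f in names(nl))
          integrand[[f]] <- px_add(integrand[[f]], as_pexpr(nl[[f]]))
      }
      if (n == 1 && !is.null(problem$forcing)) {
        for (f in names(problem$forcing))
          integrand[[f]] <- px_add(integrand[[f]], problem$forcing[[f]])
      }
      stats::setNames(lapply(problem$fields, function(f)
        abel_inverse(integrand[[f]], m)), problem$fields)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      diagnostic <- sprintf("symbolic step failed at order %d: %s", n,
                            conditionMessage(res))
      warning(diagnostic)
      break
    }
    terms[[n + 1]] <- res
  }
  structure(list(terms = terms, truncation = length(terms) - 1L,
                 fields = problem$fields, problem = problem,
                 diagnostic = diagnostic),
            class = "hdm_series")
}

#' Extract one series term
#'
#' @param series an `hdm_series`.
#' @param field field name.
#' @param order term order (0-based).
#' @return expression.
#' @export
series_term <- function(series, field, order) {
  stopifnot(inherits(series, "hdm_series"), order >= 0,
            order <= series$truncation)
  series$terms[[order + 1]][[field]]
}

#' Symbolic partial sum of a series
#'
#' @param series an `hdm_series`.
#' @param field field name.
#' @param N highest order to include (defaults to the truncation).
#' @return expression: `sum_{n=0}^{N} term_n`.
#' @export
partial_sum <- function(series, field, N = series$truncation) {
  stopifnot(N <= series$truncation)
  s <- px_zero()
  for (n in 0:N) s <- px_add(s, as_pexpr(series$terms[[n + 1]][[field]]))
  s
}

#' @export
print.hdm_series <- function(x, ...) {
  cat(sprintf("Homotopy decomposition series (order 0..%d, fields: %s)\n",
              x$truncation, paste(x$fields, collapse = ", ")))
  for (n in 0:x$truncation) {
    for (f in x$fields)
      cat(sprintf("  %s_%d = %s\n", f, n, expr_text(x$terms[[n + 1]][[f]])))
  }
  if (!is.null(x$diagnostic)) cat("  [diagnostic] ", x$diagnostic, "\n")
  invisible(x)
}

#' @export
as.data.frame.hdm_series <- function(x, ...) {
  rows <- list()
  for (n in 0:x$truncation) for (f in x$fields)
    rows[[length(rows) + 1]] <- tibble::tibble(
      order = n, field = f, expression = expr_text(x$terms[[n + 1]][[f]]))
  as.data.frame(do.call(rbind, rows))
}
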