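# Symbolic kernel: canonical sums of monomials of the form
#   q * prod(sym^k) * exp(e1*x + e2*x^2) * sin(x)^s * cos(x)^c
# with q an exact rational (degrading to double only past 2^53).  The class is
# closed under +, *, d/d(sym), and definite integration in t — exactly the
# operations the homotopy decomposition recursion needs.  sin powers are
# reduced with sin^2 = 1 - cos^2 so equal expressions share one normal form.

.MAXI <- 2^53

## ---- rational coefficients ----------------------------------------------
## representation: c(num, den); den = NA marks a plain double held in num.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { r <- a %% b; a <- b; b <- r }
  a
}

q_rat <- function(num, den = 1) {
  if (is.na(den) || den == 0 || abs(num) > .MAXI || abs(den) > .MAXI ||
      num != round(num) || den != round(den)) {
    return(c(num / if (is.na(den)) 1 else den, NA_real_))
  }
  if (num == 0) return(c(0, 1))
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd2(num, den)
  c(num / g, den / g)
}

q_is_rat <- function(q) !is.na(q[2])

q_num <- function(q) if (q_is_rat(q)) q[1] / q[2] else q[1]

q_add <- function(q1, q2) {
  if (q_is_rat(q1) && q_is_rat(q2)) {
    n <- q1[1] * q2[2] + q2[1] * q1[2]; d <- q1[2] * q2[2]
    if (abs(n) <= .MAXI && abs(d) <= .MAXI) return(q_rat(n, d))
  }
  c(q_num(q1) + q_num(q2), NA_real_)
}

q_mul <- function(q1, q2) {
  if (q_is_rat(q1) && q_is_rat(q2)) {
    g1 <- .gcd2(q1[1], q2[2]); g2 <- .gcd2(q2[1], q1[2])
    n <- (q1[1] / g1) * (q2[1] / g2); d <- (q1[2] / g2) * (q2[2] / g1)
    if (abs(n) <= .MAXI && abs(d) <= .MAXI) return(q_rat(n, d))
  }
  c(q_num(q1) * q_num(q2), NA_real_)
}

q_neg <- function(q) { q[1] <- -q[1]; q }

q_inv <- function(q) {
  if (q_is_rat(q)) {
    if (q[1] == 0) stop("division by zero in rational coefficient")
    q_rat(sign(q[1]) * q[2], abs(q[1]))
  } else c(1 / q[1], NA_real_)
}

q_zero <- function(q) q[1] == 0

q_str <- function(q) {
  if (!q_is_rat(q)) return(formatC(q[1], digits = 17, format = "g"))
  if (q[2] == 1) sprintf("%.0f", q[1]) else sprintf("%.0f/%.0f", q[1], q[2])
}

## ---- monomials -----------------------------------------------------------

.mono <- function(q, pow = NULL, eax = 0, eax2 = 0, sp = 0L, cp = 0L) {
  if (!is.null(pow)) {
    pow <- pow[pow != 0]
    if (length(pow) > 1) pow <- pow[order(names(pow))]
    if (length(pow) == 0) pow <- NULL
  }
  list(q = q, pow = pow, eax = eax, eax2 = eax2, sp = as.integer(sp), cp = as.integer(cp))
}

.mono_key <- function(mo) {
  pk <- if (is.null(mo$pow)) "" else
    paste(names(mo$pow), mo$pow, sep = "^", collapse = ",")
  paste(pk,
        formatC(mo$eax, digits = 15, format = "g"),
        formatC(mo$eax2, digits = 15, format = "g"),
        mo$sp, mo$cp, sep = "|")
}

.mono_mul <- function(m1, m2) {
  pow <- m1$pow
  if (!is.null(m2$pow)) {
    if (is.null(pow)) pow <- m2$pow
    else {
      for (s in names(m2$pow)) pow[s] <- (if (s %in% names(pow)) pow[s] else 0) + m2$pow[s]
    }
  }
  .mono(q_mul(m1$q, m2$q), pow, m1$eax + m2$eax, m1$eax2 + m2$eax2,
        m1$sp + m2$sp, m1$cp + m2$cp)
}

## ---- pexpr: canonical expression = list of monomials ---------------------

.px <- function(monos) structure(monos, class = "pexpr")

px_is <- function(x) inherits(x, "pexpr")

#' @export
print.pexpr <- function(x, ...) { cat(px_str(x), "\n"); invisible(x) }

px_zero <- function() .px(list())

px_num <- function(v) {
  q <- q_rat(v)
  if (q_zero(q)) px_zero() else .px(list(.mono(q)))
}

px_sym <- function(name) .px(list(.mono(q_rat(1), stats::setNames(1, name))))

# reduce sin powers (sin^2 -> 1 - cos^2), then merge like monomials
px_norm <- function(monos) {
  out <- list(); i <- 1
  stack <- monos
  while (length(stack) > 0) {
    mo <- stack[[1]]; stack <- stack[-1]
    if (q_zero(mo$q)) next
    if (mo$sp >= 2) {
      m1 <- mo; m1$sp <- mo$sp - 2L
      m2 <- m1; m2$cp <- mo$cp + 2L; m2$q <- q_neg(m2$q)
      stack <- c(list(m1, m2), stack)
      next
    }
    out[[i]] <- mo; i <- i + 1
  }
  if (length(out) == 0) return(px_zero())
  keys <- vapply(out, .mono_key, "")
  merged <- list()
  for (k in sort(unique(keys))) {   # canonical monomial order
    idx <- which(keys == k)
    q <- out[[idx[1]]]$q
    for (j in idx[-1]) q <- q_add(q, out[[j]]$q)
    if (!q_zero(q)) { mo <- out[[idx[1]]]; mo$q <- q; merged[[length(merged) + 1]] <- mo }
  }
  .px(merged)
}

px_add <- function(e1, e2) px_norm(c(unclass(e1), unclass(e2)))

px_neg <- function(e) .px(lapply(unclass(e), function(mo) { mo$q <- q_neg(mo$q); mo }))

px_sub <- function(e1, e2) px_add(e1, px_neg(e2))

px_mul <- function(e1, e2) {
  m1 <- unclass(e1); m2 <- unclass(e2)
  if (length(m1) == 0 || length(m2) == 0) return(px_zero())
  out <- vector("list", length(m1) * length(m2)); k <- 1
  for (a in m1) for (b in m2) { out[[k]] <- .mono_mul(a, b); k <- k + 1 }
  px_norm(out)
}

px_scale <- function(e, v) {
  q <- if (length(v) == 2) v else q_rat(v)
  if (q_zero(q)) return(px_zero())
  .px(lapply(unclass(e), function(mo) { mo$q <- q_mul(mo$q, q); mo }))
}

px_pow <- function(e, k) {
  stopifnot(k == round(k), k >= 0)
  out <- px_num(1)
  while (k > 0) { out <- px_mul(out, e); k <- k - 1 }
  out
}

px_is_zero <- function(e) length(unclass(e)) == 0

px_symbols <- function(e) {
  syms <- unique(unlist(lapply(unclass(e), function(mo) names(mo$pow))))
  extra <- character()
  for (mo in unclass(e)) {
    if (mo$eax != 0 || mo$eax2 != 0 || mo$sp > 0 || mo$cp > 0) extra <- "x"
  }
  sort(unique(c(syms, extra)))
}

## ---- calculus ------------------------------------------------------------

# derivative with respect to one symbol; "x" also drives exp/sin/cos factors
px_deriv <- function(e, var = "x", order = 1) {
  for (i in seq_len(order)) e <- .px_deriv1(e, var)
  e
}

.px_deriv1 <- function(e, var) {
  out <- list()
  add <- function(mo) out[[length(out) + 1]] <<- mo
  for (mo in unclass(e)) {
    k <- if (!is.null(mo$pow) && var %in% names(mo$pow)) mo$pow[[var]] else 0
    if (k != 0) {                       # power-rule part
      m <- mo; m$q <- q_mul(m$q, q_rat(k)); m$pow[var] <- k - 1
      add(.mono(m$q, m$pow, m$eax, m$eax2, m$sp, m$cp))
    }
    if (var == "x") {
      if (mo$eax != 0) {                # chain rule on exp(e1*x + e2*x^2)
        m <- mo
        m$q <- if (mo$eax == round(mo$eax)) q_mul(m$q, q_rat(mo$eax)) else
          c(q_num(m$q) * mo$eax, NA_real_)
        add(m)
      }
      if (mo$eax2 != 0) {
        m <- mo
        v <- 2 * mo$eax2
        m$q <- if (v == round(v)) q_mul(m$q, q_rat(v)) else c(q_num(m$q) * v, NA_real_)
        pw <- m$pow; pw["x"] <- (if (!is.null(pw) && "x" %in% names(pw)) pw[["x"]] else 0) + 1
        add(.mono(m$q, pw, m$eax, m$eax2, m$sp, m$cp))
      }
      if (mo$sp > 0) {                  # sin^s -> s sin^(s-1) cos^(c+1)
        m <- mo; m$q <- q_mul(m$q, q_rat(mo$sp))
        add(.mono(m$q, m$pow, m$eax, m$eax2, mo$sp - 1L, mo$cp + 1L))
      }
      if (mo$cp > 0) {                  # cos^c -> -c cos^(c-1) sin^(s+1)
        m <- mo; m$q <- q_mul(m$q, q_rat(-mo$cp))
        add(.mono(m$q, m$pow, m$eax, m$eax2, mo$sp + 1L, mo$cp - 1L))
      }
    }
  }
  px_norm(out)
}

#' Abel-kernel inverse time operator
#'
#' Applies the single-integral form of `m`-fold time integration,
#' `(1/(m-1)!) \int_0^t (t - tau)^(m-1) f(x, tau) d tau`, to an expression
#' polynomial in `t`.  A monomial `t^k` maps to `k!/(m+k)! * t^(m+k)`, so the
#' result always vanishes at `t = 0`.
#'
#' @param integrand expression (a parsed expression from [hdm_expr()] or a
#'   string) polynomial in `t`.
#' @param time_order positive integer `m`, the order of the time derivative
#'   being inverted.
#' @return the integrated expression.
#' @examples
#' expr_text(abel_inverse("c0", 1))         # "c0*t"
#' expr_text(abel_inverse("1", 2))          # "1/2*t^2"
#' @export
abel_inverse <- function(integrand, time_order = 1) {
  e <- as_pexpr(integrand)
  m <- as.integer(time_order)
  stopifnot(m >= 1)
  out <- lapply(unclass(e), function(mo) {
    k <- if (!is.null(mo$pow) && "t" %in% names(mo$pow)) mo$pow[["t"]] else 0
    if (k != round(k) || k < 0)
      stop("abel_inverse: integrand not polynomial in t: ", px_str(.px(list(mo))))
    # k!/(m+k)! = 1/((k+1)...(k+m))
    fac <- q_rat(1)
    for (j in seq_len(m)) fac <- q_mul(fac, q_rat(1, k + j))
    mo$q <- q_mul(mo$q, fac)
    pw <- mo$pow; pw["t"] <- k + m
    .mono(mo$q, pw, mo$eax, mo$eax2, mo$sp, mo$cp)
  })
  px_norm(out)
}

## ---- numeric evaluation --------------------------------------------------

# env: named list/vector of numeric values (vectors allowed, recycled)
px_eval <- function(e, env) {
  env <- as.list(env)
  need <- px_symbols(e)
  missing <- setdiff(need, names(env))
  if (length(missing) > 0)
    stop("unbound symbol(s) in evaluation: ", paste(missing, collapse = ", "))
  x <- env[["x"]]
  total <- 0
  for (mo in unclass(e)) {
    v <- q_num(mo$q)
    if (!is.null(mo$pow))
      for (s in names(mo$pow)) v <- v * env[[s]]^mo$pow[[s]]
    if (mo$eax != 0 || mo$eax2 != 0) v <- v * exp(mo$eax * x + mo$eax2 * x^2)
    if (mo$sp > 0) v <- v * sin(x)^mo$sp
    if (mo$cp > 0) v <- v * cos(x)^mo$cp
    total <- total + v
  }
  total
}

# bind a subset of symbols to numbers, returning an expression in the rest
px_subst <- function(e, values) {
  values <- as.list(values)
  out <- lapply(unclass(e), function(mo) {
    if (!is.null(mo$pow)) {
      for (s in intersect(names(mo$pow), names(values))) {
        v <- values[[s]]^mo$pow[[s]]
        mo$q <- if (v == round(v) && abs(v) <= .MAXI) q_mul(mo$q, q_rat(v)) else
          c(q_num(mo$q) * v, NA_real_)
        mo$pow <- mo$pow[names(mo$pow) != s]
      }
      if (length(mo$pow) == 0) mo$pow <- NULL
    }
    mo
  })
  px_norm(out)
}

## ---- parsing -------------------------------------------------------------

#' Parse a mathematical expression into the package's symbolic form
#'
#' Accepts products/sums of rational numbers, symbols, integer powers,
#' `exp()` of a polynomial in `x` of degree at most 2, and `sin`/`cos` of
#' integer multiples of `x` (expanded into powers of `sin(x)`, `cos(x)`).
#' This is exactly the closed class of expressions the Keller-Segel series
#' recursions produce.
#'
#' @param text a string, a quoted R expression, or an already-parsed
#'   expression (returned unchanged).
#' @return an object of class `pexpr` in canonical expanded form.
#' @examples
#' e <- hdm_expr("2*a*m*t*exp(-x^2)*(-1 + 2*x^2)")
#' expr_text(e)
#' @export
hdm_expr <- function(text) as_pexpr(text)

as_pexpr <- function(x) {
  if (px_is(x)) return(x)
  if (is.numeric(x)) return(px_num(x))
  if (is.character(x)) x <- str2lang(x)
  .parse_ast(x)
}

.parse_ast <- function(a) {
  if (is.numeric(a)) return(px_num(a))
  if (is.symbol(a)) {
    nm <- as.character(a)
    if (nm == "pi") return(px_num(pi))
    return(px_sym(nm))
  }
  if (!is.call(a)) stop("cannot parse expression component: ", deparse(a))
  op <- as.character(a[[1]])
  if (op == "(") return(.parse_ast(a[[2]]))
  if (op == "+" && length(a) == 2) return(.parse_ast(a[[2]]))
  if (op == "-" && length(a) == 2) return(px_neg(.parse_ast(a[[2]])))
  if (op == "+") return(px_add(.parse_ast(a[[2]]), .parse_ast(a[[3]])))
  if (op == "-") return(px_sub(.parse_ast(a[[2]]), .parse_ast(a[[3]])))
  if (op == "*") return(px_mul(.parse_ast(a[[2]]), .parse_ast(a[[3]])))
  if (op == "/") {
    den <- .parse_ast(a[[3]])
    dm <- unclass(den)
    if (length(dm) != 1 || !is.null(dm[[1]]$pow) || dm[[1]]$eax != 0 ||
        dm[[1]]$eax2 != 0 || dm[[1]]$sp > 0 || dm[[1]]$cp > 0)
      stop("division only supported by nonzero numeric constants: ", deparse(a))
    return(px_scale(.parse_ast(a[[2]]), q_inv(dm[[1]]$q)))
  }
  if (op == "^") {
    k <- a[[3]]
    if (!is.numeric(k) || k != round(k) || k < 0)
      stop("only nonnegative integer powers are supported: ", deparse(a))
    return(px_pow(.parse_ast(a[[2]]), k))
  }
  if (op == "exp") {
    arg <- .parse_ast(a[[2]])
    e1 <- 0; e2 <- 0; c0 <- 0
    for (mo in unclass(arg)) {
      if (mo$eax != 0 || mo$eax2 != 0 || mo$sp > 0 || mo$cp > 0)
        stop("exp() argument must be polynomial in x: ", deparse(a))
      pw <- mo$pow
      if (is.null(pw)) c0 <- c0 + q_num(mo$q)
      else if (identical(names(pw), "x") && pw[["x"]] == 1) e1 <- e1 + q_num(mo$q)
      else if (identical(names(pw), "x") && pw[["x"]] == 2) e2 <- e2 + q_num(mo$q)
      else stop("exp() argument must be a polynomial in x of degree <= 2: ", deparse(a))
    }
    coef <- if (c0 == 0) q_rat(1) else c(exp(c0), NA_real_)
    return(.px(list(.mono(coef, NULL, e1, e2))))
  }
  if (op %in% c("sin", "cos")) {
    arg <- a[[2]]
    k <- .linear_in_x(arg)
    if (is.na(k)) stop(op, "() argument must be an integer multiple of x: ", deparse(a))
    return(.trig_multiple(op, k))
  }
  stop("unsupported operator in expression: ", op)
}

.linear_in_x <- function(a) {
  e <- tryCatch(.parse_ast(a), error = function(e) NULL)
  if (is.null(e)) return(NA_real_)
  mos <- unclass(e)
  if (length(mos) != 1) return(NA_real_)
  mo <- mos[[1]]
  if (mo$eax != 0 || mo$eax2 != 0 || mo$sp > 0 || mo$cp > 0) return(NA_real_)
  if (!identical(names(mo$pow), "x") || mo$pow[["x"]] != 1) return(NA_real_)
  v <- q_num(mo$q)
  if (v != round(v)) return(NA_real_)
  v
}

# sin(kx), cos(kx) as polynomials in sin(x), cos(x) via the angle-addition
# recursion; k any integer
.trig_multiple <- function(fn, k) {
  if (k < 0) {
    e <- .trig_multiple(fn, -k)
    return(if (fn == "sin") px_neg(e) else e)
  }
  if (k == 0) return(if (fn == "sin") px_zero() else px_num(1))
  s1 <- .px(list(.mono(q_rat(1), NULL, 0, 0, 1L, 0L)))
  c1 <- .px(list(.mono(q_rat(1), NULL, 0, 0, 0L, 1L)))
  s <- s1; cc <- c1
  for (i in seq_len(k - 1)) {
    s_new <- px_add(px_mul(s, c1), px_mul(cc, s1))
    c_new <- px_sub(px_mul(cc, c1), px_mul(s, s1))
    s <- s_new; cc <- c_new
  }
  if (fn == "sin") s else cc
}

## ---- rendering -----------------------------------------------------------

.mono_str <- function(mo) {
  parts <- character()
  q <- mo$q
  qa <- q; qa[1] <- abs(qa[1])
  coef <- q_str(qa)
  if (!is.null(mo$pow)) {
    for (s in names(mo$pow)) {
      k <- mo$pow[[s]]
      parts <- c(parts, if (k == 1) s else sprintf("%s^%s", s, format(k)))
    }
  }
  if (mo$eax != 0 || mo$eax2 != 0) {
    at <- character()
    fmt <- function(v, suff) {
      if (v == 0) return(NULL)
      vs <- if (v == round(v)) sprintf("%.0f", abs(v)) else
        formatC(abs(v), digits = 17, format = "g")
      core <- if (abs(v) == 1) suff else paste0(vs, "*", suff)
      paste0(if (v < 0) "-" else "+", core)
    }
    at <- paste0(c(fmt(mo$eax, "x"), fmt(mo$eax2, "x^2")), collapse = " ")
    at <- sub("^\\+", "", at)
    parts <- c(parts, sprintf("exp(%s)", at))
  }
  if (mo$sp > 0) parts <- c(parts, if (mo$sp == 1) "sin(x)" else sprintf("sin(x)^%d", mo$sp))
  if (mo$cp > 0) parts <- c(parts, if (mo$cp == 1) "cos(x)" else sprintf("cos(x)^%d", mo$cp))
  body <- paste(parts, collapse = "*")
  if (body == "") coef else if (coef == "1") body else paste0(coef, "*", body)
}

px_str <- function(e) {
  mos <- unclass(e)
  if (length(mos) == 0) return("0")
  out <- ""
  for (i in seq_along(mos)) {
    neg <- mos[[i]]$q[1] < 0
    piece <- .mono_str(mos[[i]])
    if (i == 1) out <- paste0(if (neg) "-" else "", piece)
    else out <- paste0(out, if (neg) " - " else " + ", piece)
  }
  out
}

#' Render an expression as plain text
#'
#' The rendering is deterministic (monomials in canonical order) and parses
#' back to the identical canonical form with [hdm_expr()].
#'
#' @param e a parsed expression (or string).
#' @return a single string.
#' @export
expr_text <- function(e) px_str(as_pexpr(e))

#' Differentiate an expression
#'
#' @param e expression (string or parsed).
#' @param var symbol name to differentiate by; `"x"` drives the
#'   exponential/trigonometric factors, any other symbol uses the power rule.
#' @param order derivative order (nonnegative integer).
#' @export
expr_deriv <- function(e, var = "x", order = 1) px_deriv(as_pexpr(e), var, order)

#' Expression arithmetic
#'
#' Exact sum, difference and product of parsed expressions (strings are
#' parsed first); results are in canonical expanded form.
#'
#' @param e1,e2 expressions (strings or parsed).
#' @return a parsed expression.
#' @export
expr_add <- function(e1, e2) px_add(as_pexpr(e1), as_pexpr(e2))

#' @rdname expr_add
#' @export
expr_sub <- function(e1, e2) px_sub(as_pexpr(e1), as_pexpr(e2))

#' @rdname expr_add
#' @export
expr_mul <- function(e1, e2) px_mul(as_pexpr(e1), as_pexpr(e2))

#' Coefficient of a power of a symbol
#'
#' Collects the monomials of `e` carrying exactly `sym^k` and strips that
#' factor — e.g. the coefficient of `t^k` when expanding a residual in time.
#'
#' @param e expression (string or parsed).
#' @param sym symbol name.
#' @param k power (nonnegative integer).
#' @return a parsed expression.
#' @export
expr_coeff <- function(e, sym, k) .px_coeff(as_pexpr(e), sym, k)

#' Evaluate an expression numerically
#'
#' @param e expression (string or parsed).
#' @param values named list or vector binding every symbol of `e`
#'   (vector-valued entries are recycled elementwise).
#' @return numeric vector.
#' @export
expr_eval <- function(e, values) px_eval(as_pexpr(e), values)

## ---- symbolic equality ---------------------------------------------------

#' Decide symbolic equality of two expressions, with a certificate
#'
#' Canonicalises the difference of the two expressions; equality holds when
#' it collapses to zero ("symbolic" verdict).  Inputs that cannot be
#' canonicalised (e.g. quoted R expressions with operators outside the
#' kernel's class) fall back to evaluation at random points in declared
#' ranges with relative tolerance `1e-10` ("numeric" verdict).
#'
#' @param e1,e2 expressions: strings, parsed expressions, or quoted R calls.
#' @param ranges optional named list of `c(lo, hi)` ranges per symbol for the
#'   numeric fallback; unlisted symbols default to `c(0.3, 1.7)`.
#' @param n_points number of random evaluation points for the fallback.
#' @param tol relative tolerance for the fallback.
#' @return a list with elements `equal` (logical), `method` (`"symbolic"` or
#'   `"numeric"`) and `certificate` (the canonical difference, or the maximum
#'   relative deviation observed).
#' @examples
#' symbolic_equal("(x+1)^2", "x^2 + 2*x + 1")$equal
#' symbolic_equal("sin(x)^2 + cos(x)^2", "1")$equal
#' @export
symbolic_equal <- function(e1, e2, ranges = NULL, n_points = 20, tol = 1e-10) {
  p1 <- tryCatch(as_pexpr(e1), error = function(e) NULL)
  p2 <- tryCatch(as_pexpr(e2), error = function(e) NULL)
  if (!is.null(p1) && !is.null(p2)) {
    d <- px_sub(p1, p2)
    if (px_is_zero(d))
      return(list(equal = TRUE, method = "symbolic", certificate = "difference simplifies to 0"))
    # residual monomials at floating-point noise level count as zero
    mags <- vapply(unclass(d), function(mo) abs(q_num(mo$q)), 0)
    scale <- max(vapply(c(unclass(p1), unclass(p2)), function(mo) abs(q_num(mo$q)), 0), 1)
    if (all(mags < 1e-12 * scale))
      return(list(equal = TRUE, method = "symbolic",
                  certificate = "difference is floating-point residue"))
    return(.numeric_equal(e1, e2, ranges, n_points, tol, cert = px_str(d)))
  }
  .numeric_equal(e1, e2, ranges, n_points, tol)
}

.expr_symbols <- function(e) {
  if (px_is(e)) return(px_symbols(e))
  if (is.character(e)) e <- str2lang(e)
  sort(setdiff(all.vars(e), "pi"))
}

.raw_eval <- function(e, env) {
  if (px_is(e)) return(px_eval(e, env))
  if (is.character(e)) e <- str2lang(e)
  eval(e, envir = as.list(env), enclos = baseenv())
}

.numeric_equal <- function(e1, e2, ranges, n_points, tol, cert = NULL) {
  s1 <- .expr_symbols(e1); s2 <- .expr_symbols(e2)
  syms <- union(s1, s2)
  if (length(s1) > 0 && length(s2) > 0 && length(intersect(s1, s2)) == 0 &&
      is.null(ranges))
    stop("symbolic_equal: expressions share no symbols and no ranges were declared")
  max_rel <- 0
  for (i in seq_len(max(n_points, 20))) {
    env <- lapply(stats::setNames(syms, syms), function(s) {
      r <- if (!is.null(ranges) && s %in% names(ranges)) ranges[[s]] else c(0.3, 1.7)
      stats::runif(1, r[1], r[2])
    })
    v1 <- .raw_eval(e1, env); v2 <- .raw_eval(e2, env)
    rel <- abs(v1 - v2) / max(1, abs(v1), abs(v2))
    max_rel <- max(max_rel, rel)
  }
  list(equal = max_rel < tol, method = "numeric",
       certificate = if (!is.null(cert)) cert else
         sprintf("max relative deviation %.3e over random points", max_rel))
}
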